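#' Simulate calcium recordings with planted ground truth
#'
#' Builds the two-block stimulation protocol (5HT, ATP, KCl, KCl+GABA, KCl;
#' 9-s stimuli, ~81-s inter-stimulus gaps at the 0.67 Hz scan rate) and
#' generates one trace per cell from four response archetypes: ATP-only,
#' ATP+5HT, 5HT-only, and non-responder, each with its own planted GABA
#' inhibition level.  Transients have an instantaneous rise to
#' `baseline * (1 + dF/F)` at the frame after onset followed by an
#' exponential decay truncated to a 18-frame support, so on noiseless
#' traces the scored peak equals the planted dF/F exactly and baselines are
#' exactly flat.  The KCl+GABA amplitude is `kcl_dff * (1 - inhibition/100)`
#' — the inverse of the inhibition statistic — so planted 100% yields no
#' peak and planted -100% yields twice the flanking KCl amplitude.
#'
#' @param n_cells_per_archetype cells per archetype (default 30).
#' @param noise_sd_over_f additive Gaussian noise sd as a fraction of
#'   baseline fluorescence (default 0.02).
#' @param inhibition_levels planted percent inhibition per archetype, in
#'   the order ATP_only, ATP_5HT, HT5_only, none (values <= 100).
#' @param seed RNG seed.
#' @param atp_dff,ht5_dff,kcl_dff planted response amplitudes (dF/F).
#' @param baseline_f baseline fluorescence in arbitrary units.
#' @param frame_period_s seconds per frame (default 1.5, i.e. 0.67 Hz).
#' @return List with `traces` (list of [calcium_trace()]), `schedule`
#'   (a [stimulus_schedule()]), and `truth` (per-cell archetype,
#'   responds_ATP, responds_5HT, inhibition_percent).
#' @export
simulate_traces <- function(n_cells_per_archetype = 30,
                            noise_sd_over_f = 0.02,
                            inhibition_levels = c(ATP_only = 80,
                                                  ATP_5HT = 50,
                                                  HT5_only = 20,
                                                  none = 0),
                            seed = 1L,
                            atp_dff = 0.5, ht5_dff = 0.5, kcl_dff = 1,
                            baseline_f = 100, frame_period_s = 1.5) {
  if (any(inhibition_levels > 100))
    stop("inhibition levels cannot exceed 100%")
  if (length(inhibition_levels) != 4)
    stop("need one inhibition level per archetype (4)")
  set.seed(seed)
  archetypes <- data.frame(
    name = c("ATP_only", "ATP_5HT", "HT5_only", "none"),
    atp = c(atp_dff, atp_dff, 0, 0),
    ht5 = c(0, ht5_dff, ht5_dff, 0),
    inhibition = as.numeric(inhibition_levels),
    stringsAsFactors = FALSE)

  stim_frames <- ceiling(9 / frame_period_s)
  gap_frames <- ceiling(81 / frame_period_s)           # >= 80 s rinse
  spacing <- stim_frames + gap_frames
  onsets <- 21L + spacing * (0:9)
  schedule <- stimulus_schedule(rep(c("5HT", "ATP", "KCl", "KCl+GABA",
                                      "KCl"), 2),
                                onsets, duration_s = 9)
  n_frames <- max(onsets) + ceiling(180 / frame_period_s) + 30
  if (max(onsets) + ceiling(40 / frame_period_s) > n_frames)
    stop("schedule does not fit the trace length")
  support <- 18L                                        # transient support
  tau_frames <- 8 / frame_period_s                      # 8 s decay constant

  add_transient <- function(f, onset, amp) {
    if (amp == 0) return(f)
    idx <- (onset + 1):(onset + support)
    f[idx] <- f[idx] +
      baseline_f * amp * exp(-(seq_along(idx) - 1) / tau_frames)
    f
  }

  traces <- list()
  truth <- NULL
  n_total <- 4 * n_cells_per_archetype
  width <- max(3, nchar(as.character(n_total)))
  cell_i <- 0
  for (a in seq_len(4)) {
    arch <- archetypes[a, ]
    gaba_amp <- kcl_dff * (1 - arch$inhibition / 100)
    amps <- setNames(c(arch$ht5, arch$atp, kcl_dff, gaba_amp, kcl_dff),
                     c("5HT", "ATP", "KCl", "KCl+GABA", "KCl2"))
    for (cc in seq_len(n_cells_per_archetype)) {
      cell_i <- cell_i + 1
      cid <- sprintf(paste0("roi_%0", width, "d"), cell_i)
      f <- rep(baseline_f, n_frames)
      for (e in seq_len(nrow(schedule)))
        f <- add_transient(f, schedule$onset_frame[e],
                           amps[[(e - 1) %% 5 + 1]])
      if (noise_sd_over_f > 0)
        f <- f + rnorm(n_frames, 0, noise_sd_over_f * baseline_f)
      traces[[cid]] <- calcium_trace(cid, f, frame_period_s)
      truth <- rbind(truth, data.frame(
        cell_id = cid, archetype = arch$name,
        responds_ATP = arch$atp > 0, responds_5HT = arch$ht5 > 0,
        atp_dff = arch$atp, ht5_dff = arch$ht5,
        inhibition_percent = arch$inhibition,
        stringsAsFactors = FALSE))
    }
  }
  list(traces = traces, schedule = schedule, truth = truth)
}
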