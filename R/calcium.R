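#' Calcium fluorescence trace
#'
#' One region of interest's fluorescence time series from GCaMP imaging.
#' Frames are 1-based; the default frame period of 1.5 s corresponds to the
#' 0.67 Hz confocal scan rate.
#'
#' @param cell_id cell/ROI identifier.
#' @param fluorescence numeric vector of raw fluorescence (arbitrary units,
#'   > 0).
#' @param frame_period_s seconds per frame (default 1.5).
#' @return An object of class `calcium_trace`.
#' @export
calcium_trace <- function(cell_id, fluorescence, frame_period_s = 1.5) {
  stopifnot(frame_period_s > 0)
  fluorescence <- as.numeric(fluorescence)
  if (anyNA(fluorescence) || any(fluorescence <= 0))
    stop("fluorescence must be positive and complete for cell ", cell_id)
  structure(list(cell_id = as.character(cell_id),
                 fluorescence = fluorescence,
                 frame_period_s = frame_period_s),
            class = "calcium_trace")
}

#' @exportS3Method base::print
print.calcium_trace <- function(x, ...) {
  cat(sprintf("<calcium_trace> '%s': %d frames @ %.3g s/frame\n",
              x$cell_id, length(x$fluorescence), x$frame_period_s))
  invisible(x)
}

#' Stimulus schedule
#'
#' Ordered bath-application events.  The standard protocol applies each
#' stimulus for 9 s with at least 80 s of rinse in between, in the block
#' order 5HT, ATP, KCl, KCl+GABA, KCl, repeated twice.
#'
#' @param name character vector of stimulus names (one of `"ATP"`, `"5HT"`,
#'   `"GABA"`, `"KCl"`, `"KCl+GABA"`).
#' @param onset_frame 1-based onset frames, strictly increasing.
#' @param duration_s stimulus durations in seconds (default 9, recycled).
#' @return An object of class `stimulus_schedule` (a data.frame).
#' @export
stimulus_schedule <- function(name, onset_frame, duration_s = 9) {
  allowed <- c("ATP", "5HT", "GABA", "KCl", "KCl+GABA")
  bad <- setdiff(name, allowed)
  if (length(bad))
    stop("unknown stimulus name(s): ", paste(bad, collapse = ", "))
  onset_frame <- as.integer(onset_frame)
  if (length(onset_frame) != length(name))
    stop("name and onset_frame lengths differ")
  if (is.unsorted(onset_frame, strictly = TRUE))
    stop("onset frames must be strictly increasing")
  structure(data.frame(name = name, onset_frame = onset_frame,
                       duration_s = rep_len(duration_s, length(name)),
                       stringsAsFactors = FALSE),
            class = c("stimulus_schedule", "data.frame"))
}

#' Baseline statistics before a stimulus
#'
#' Mean and standard deviation of the 10 frames immediately preceding the
#' stimulus onset (frames `onset-10` to `onset-1`); the mean is the F of
#' dF/F.
#'
#' @param trace a [calcium_trace()].
#' @param onset_frame 1-based stimulus onset (>= 11 so that 10 pre-stimulus
#'   frames exist).
#' @return Named numeric vector `c(mean, sd)`.
#' @export
baseline_stats <- function(trace, onset_frame) {
  stopifnot(inherits(trace, "calcium_trace"))
  if (onset_frame < 11)
    stop("need 10 pre-stimulus frames; onset_frame ", onset_frame,
         " is too early")
  if (onset_frame > length(trace$fluorescence) + 1)
    stop("onset_frame beyond end of trace")
  f <- trace$fluorescence[(onset_frame - 10):(onset_frame - 1)]
  c(mean = mean(f), sd = sd(f))
}

#' Peak dF/F after a stimulus
#'
#' `(max F in the post-stimulus window - baseline mean) / baseline mean`,
#' with the window spanning `ceiling(window_s / frame_period_s)` frames
#' starting at the onset frame (40 s, i.e. 27 frames at the default rate).
#'
#' @param trace a [calcium_trace()].
#' @param onset_frame 1-based stimulus onset.
#' @param window_s window length in seconds (default 40).
#' @return Peak dF/F (can be negative if fluorescence falls).
#' @export
peak_dff <- function(trace, onset_frame, window_s = 40) {
  stopifnot(inherits(trace, "calcium_trace"))
  base <- baseline_stats(trace, onset_frame)
  n_win <- ceiling(window_s / trace$frame_period_s)
  last <- onset_frame + n_win - 1
  if (last > length(trace$fluorescence))
    stop("post-stimulus window (frames ", onset_frame, "-", last,
         ") exceeds trace length ", length(trace$fluorescence))
  peak <- max(trace$fluorescence[onset_frame:last])
  (peak - base[["mean"]]) / base[["mean"]]
}

#' Response call from a dF/F peak
#'
#' A response is positive when the peak dF/F strictly exceeds 5 baseline
#' standard deviations (expressed in dF/F units, i.e. sd/F).
#'
#' @param peak peak dF/F.
#' @param baseline_sd_over_f baseline sd divided by baseline mean.
#' @return Logical.
#' @export
call_response <- function(peak, baseline_sd_over_f) {
  if (!is.finite(baseline_sd_over_f))
    stop("baseline sd/F must be finite")
  peak > 5 * baseline_sd_over_f
}

#' Health/quality control of a recording
#'
#' A cell passes when (1) every KCl-alone response exceeds 5 baseline
#' standard deviations, (2) every pre-stimulus baseline mean is within
#' `drift_tolerance` of the first baseline mean (the quantitative reading
#' of "a flat baseline preceded each stimulus"), and (3) fluorescence
#' returns to within `drift_tolerance` of that reference baseline within 3
#' minutes of each stimulus offset.
#'
#' @param trace a [calcium_trace()].
#' @param schedule a [stimulus_schedule()] containing at least one KCl
#'   event.
#' @param drift_tolerance allowed relative deviation (default 0.1).
#' @return List with `pass` (logical) and `reasons` (character vector drawn
#'   from `"kcl_below_5sd"`, `"baseline_drift"`, `"no_recovery"`).
#' @export
qc_trace <- function(trace, schedule, drift_tolerance = 0.1) {
  stopifnot(inherits(trace, "calcium_trace"),
            inherits(schedule, "stimulus_schedule"))
  kcl <- schedule$name == "KCl"
  if (!any(kcl)) stop("schedule contains no KCl event")
  reasons <- character(0)
  ref <- baseline_stats(trace, schedule$onset_frame[1])[["mean"]]

  for (i in which(kcl)) {
    on <- schedule$onset_frame[i]
    base <- baseline_stats(trace, on)
    pk <- peak_dff(trace, on)
    if (!call_response(pk, base[["sd"]] / base[["mean"]])) {
      reasons <- c(reasons, "kcl_below_5sd"); break
    }
  }
  for (i in seq_len(nrow(schedule))) {
    bm <- baseline_stats(trace, schedule$onset_frame[i])[["mean"]]
    if (abs(bm - ref) / ref > drift_tolerance) {
      reasons <- c(reasons, "baseline_drift"); break
    }
  }
  n3min <- ceiling(180 / trace$frame_period_s)
  for (i in seq_len(nrow(schedule))) {
    off <- schedule$onset_frame[i] +
      ceiling(schedule$duration_s[i] / trace$frame_period_s)
    last <- min(off + n3min, length(trace$fluorescence))
    if (off > length(trace$fluorescence)) next
    f <- trace$fluorescence[off:last]
    if (!any(abs(f - ref) / ref <= drift_tolerance)) {
      reasons <- c(reasons, "no_recovery"); break
    }
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' GABA inhibition of the KCl-evoked response
#'
#' `100 * (1 - peak(KCl+GABA) / mean(flanking KCl peaks))`: 100% means the
#' KCl response is abolished under GABA, 0% means no effect, and -100%
#' means a 2-fold increase.  The statistic is bounded above by 100 and
#' unbounded below.
#'
#' @param peak_kcl_gaba peak dF/F of the KCl+GABA event.
#' @param peak_kcl_pre,peak_kcl_post peak dF/F of the flanking KCl-alone
#'   events (their mean must be positive).
#' @return Percent inhibition.
#' @export
gaba_inhibition <- function(peak_kcl_gaba, peak_kcl_pre, peak_kcl_post) {
  flank <- mean(c(peak_kcl_pre, peak_kcl_post))
  if (!is.finite(flank) || flank <= 0)
    stop("mean of flanking KCl peaks must be positive (got ", flank, ")")
  100 * (1 - peak_kcl_gaba / flank)
}

.block_pattern <- c("5HT", "ATP", "KCl", "KCl+GABA", "KCl")

#' Score one cell across the two-block stimulation protocol
#'
#' Expects the 5-stimulus sequence 5HT, ATP, KCl, KCl+GABA, KCl applied
#' twice (10 events).  Per replicate block: dF/F peaks for 5HT and ATP with
#' 5-s.d. response calls, and GABA inhibition from the block's internal
#' KCl, KCl+GABA, KCl triplet.  A transmitter's response flag is `TRUE`
#' only when both replicates are positive; a cell whose replicates disagree
#' for ATP or 5HT is flagged inconsistent (such cells are excluded from
#' functional clustering).
#'
#' @param trace a [calcium_trace()].
#' @param schedule a [stimulus_schedule()] with the two full blocks.
#' @param drift_tolerance passed to [qc_trace()].
#' @return One-row `data.frame` with peaks, means, response flags,
#'   inhibition per replicate and mean, consistency and QC fields.
#' @export
summarize_cell <- function(trace, schedule, drift_tolerance = 0.1) {
  stopifnot(inherits(trace, "calcium_trace"),
            inherits(schedule, "stimulus_schedule"))
  expected <- rep(.block_pattern, 2)
  if (nrow(schedule) != 10 || !all(schedule$name == expected)) {
    have <- table(factor(schedule$name, levels = unique(expected)))
    want <- table(factor(expected, levels = unique(expected)))
    short <- want - pmin(have, want)
    stop("schedule is not two full 5HT/ATP/KCl/KCl+GABA/KCl blocks; ",
         "missing: ", paste(sprintf("%s x%d", names(short)[short > 0],
                                    short[short > 0]), collapse = ", "))
  }
  score <- function(i) {
    on <- schedule$onset_frame[i]
    base <- baseline_stats(trace, on)
    pk <- peak_dff(trace, on)
    list(peak = pk, resp = call_response(pk, base[["sd"]] / base[["mean"]]))
  }
  ev <- lapply(seq_len(10), score)
  blk <- function(b) (b - 1) * 5   # offset of block b
  ht5 <- c(ev[[blk(1) + 1]]$peak, ev[[blk(2) + 1]]$peak)
  atp <- c(ev[[blk(1) + 2]]$peak, ev[[blk(2) + 2]]$peak)
  ht5_r <- c(ev[[blk(1) + 1]]$resp, ev[[blk(2) + 1]]$resp)
  atp_r <- c(ev[[blk(1) + 2]]$resp, ev[[blk(2) + 2]]$resp)
  inh <- vapply(1:2, function(b)
    gaba_inhibition(ev[[blk(b) + 4]]$peak,
                    ev[[blk(b) + 3]]$peak, ev[[blk(b) + 5]]$peak),
    numeric(1))
  qc <- qc_trace(trace, schedule, drift_tolerance)
  consistent <- (ht5_r[1] == ht5_r[2]) && (atp_r[1] == atp_r[2])
  data.frame(cell_id = trace$cell_id,
             ht5_rep1 = ht5[1], ht5_rep2 = ht5[2], ht5_mean = mean(ht5),
             ht5_response = all(ht5_r),
             atp_rep1 = atp[1], atp_rep2 = atp[2], atp_mean = mean(atp),
             atp_response = all(atp_r),
             inhibition_rep1 = inh[1], inhibition_rep2 = inh[2],
             inhibition_mean = mean(inh),
             consistent = consistent, qc_pass = qc$pass,
             qc_reasons = paste(qc$reasons, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Score a set of traces
#'
#' @param traces list of [calcium_trace()]s.
#' @param schedule shared [stimulus_schedule()].
#' @param drift_tolerance passed to [qc_trace()].
#' @return A `data.frame` (class `response_table`), one row per cell.
#' @export
summarize_cells <- function(traces, schedule, drift_tolerance = 0.1) {
  rows <- lapply(traces, summarize_cell, schedule = schedule,
                 drift_tolerance = drift_tolerance)
  structure(do.call(rbind, rows),
            class = c("response_table", "data.frame"))
}

#' Cluster cells by functional response profile
#'
#' UPGMA on Euclidean distances over the feature vector (mean ATP dF/F,
#' mean 5HT dF/F, mean inhibition / 100 — the rescaling puts the inhibition
#' percentage on the same numeric range as dF/F), cut into `k` groups.
#' Rows failing QC or with inconsistent replicates should be excluded
#' before calling (see `run_calcium()`).
#'
#' @param table a [summarize_cells()] result (or data.frame with columns
#'   `cell_id`, `atp_mean`, `ht5_mean`, `inhibition_mean`).
#' @param k number of functional groups (default 4).
#' @return A `cluster_assignment` over the table's cells.
#' @export
cluster_responses <- function(table, k = 4) {
  if (nrow(table) < k)
    stop("fewer rows (", nrow(table), ") than requested clusters (", k, ")")
  feat <- cbind(atp = table$atp_mean, ht5 = table$ht5_mean,
                inh = table$inhibition_mean / 100)
  rownames(feat) <- table$cell_id
  d <- as.matrix(stats::dist(feat))
  if (all(d == 0) && nrow(feat) > 1)
    warning("all response profiles identical; cluster split is arbitrary ",
            "(but deterministic)")
  cut_tree(upgma(d, labels = table$cell_id), k = k)
}

#' Read per-cell traces from CSV
#'
#' Column 1 is the frame index; every further column is one cell's
#' fluorescence, named by cell id.
#'
#' @param path CSV path.
#' @param frame_period_s seconds per frame (default 1.5).
#' @return List of [calcium_trace()]s.
#' @export
read_traces_csv <- function(path, frame_period_s = 1.5) {
  df <- read.table(path, header = TRUE, sep = ",", check.names = FALSE)
  lapply(colnames(df)[-1], function(cid)
    calcium_trace(cid, df[[cid]], frame_period_s))
}

#' Write per-cell traces to CSV
#'
#' @param traces list of [calcium_trace()]s of equal length.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  lens <- vapply(traces, function(t) length(t$fluorescence), integer(1))
  if (length(unique(lens)) != 1) stop("traces differ in length")
  df <- data.frame(frame = seq_len(lens[1]))
  for (t in traces) df[[t$cell_id]] <- t$fluorescence
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stimulus schedule from CSV
#'
#' @param path CSV with columns `name`, `onset_frame`, `duration_s`.
#' @return A [stimulus_schedule()].
#' @export
read_schedule_csv <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  stimulus_schedule(df$name, df$onset_frame, df$duration_s)
}

#' Write a stimulus schedule to CSV
#'
#' @param schedule a [stimulus_schedule()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  write.table(as.data.frame(schedule), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
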