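# Independent oracles and shared fixtures, deliberately written with
# different algorithms than the package internals.

# Naive UPGMA: recomputes every inter-cluster average from the RAW distance
# matrix at each step (no Lance-Williams update).  Returns the cophenetic
# matrix, which pins down topology and merge heights together.
naive_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- NULL; bd <- Inf
    for (a in seq_len(m - 1)) for (b in (a + 1):m) {
      avg <- mean(d[clusters[[a]], clusters[[b]]])
      pick <- FALSE
      if (avg < bd - 1e-15) pick <- TRUE
      else if (abs(avg - bd) <= 1e-15) {
        cur <- sort(c(min(clusters[[a]]), min(clusters[[b]])))
        old <- sort(c(min(clusters[[best[1]]]), min(clusters[[best[2]]])))
        pick <- cur[1] < old[1] || (cur[1] == old[1] && cur[2] < old[2])
      }
      if (pick) { bd <- avg; best <- c(a, b) }
    }
    ia <- clusters[[best[1]]]; ib <- clusters[[best[2]]]
    coph[ia, ib] <- bd; coph[ib, ia] <- bd
    clusters[[best[1]]] <- c(ia, ib)
    clusters[[best[2]]] <- NULL
  }
  coph
}

cophenetic_of <- function(tree) {
  as.matrix(stats::cophenetic(as.hclust(tree)))
}

random_distance_matrix <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 2)
  d + t(d)
}

# small generator configuration used where the full 17k-gene default is
# unnecessary
small_sim_config <- function(seed = 42L) {
  expression_sim_config(
    n_genes = 600,
    group_sizes = c(somatosensory = 8, T1 = 9, T2 = 4, T3 = 6, outlier = 2),
    n_markers_per_group = 10, n_major_markers = 20,
    n_outlier_private = 6, seed = seed)
}

# build a two-block trace with per-event dF/F amplitudes (independent of
# simulate_traces): instantaneous rise, truncated exponential decay
make_two_block_trace <- function(amps_block1, amps_block2, cell_id = "cellA",
                                 baseline_f = 100, frame_period_s = 1.5) {
  onsets <- 21L + 60L * (0:9)
  schedule <- stimulus_schedule(rep(c("5HT", "ATP", "KCl", "KCl+GABA",
                                      "KCl"), 2), onsets, 9)
  f <- rep(baseline_f, 700)
  amps <- c(amps_block1, amps_block2)
  for (e in seq_len(10)) {
    on <- onsets[e]
    idx <- (on + 1):(on + 18)
    f[idx] <- f[idx] + baseline_f * amps[e] * exp(-(seq_along(idx) - 1) /
                                                    (8 / frame_period_s))
  }
  list(trace = calcium_trace(cell_id, f, frame_period_s),
       schedule = schedule)
}
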