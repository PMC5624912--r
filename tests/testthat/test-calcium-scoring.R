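flat_trace <- function(n = 200, f = 100, id = "c1") {
  calcium_trace(id, rep(f, n))
}

test_that("baseline statistics use the 10 frames before onset", {
  tr <- flat_trace()
  expect_equal(baseline_stats(tr, 50), c(mean = 100, sd = 0))
  alt <- calcium_trace("c1", rep(c(90, 110), 50))
  bs <- baseline_stats(alt, 41)
  expect_equal(bs[["mean"]], 100)
  expect_equal(bs[["sd"]], sd(rep(c(90, 110), 5)))
  expect_error(baseline_stats(tr, 5), "too early")
})

test_that("peak dF/F is measured inside the 40-s window only", {
  f <- rep(100, 200); f[61] <- 150
  tr <- calcium_trace("c1", f)
  expect_equal(peak_dff(tr, 60), 0.5)
  expect_equal(peak_dff(flat_trace(), 60), 0)
  # 27-frame window at 1.5 s/frame: a peak 45 s (30 frames) after onset is
  # invisible; the in-window maximum sets the score
  f2 <- rep(100, 200); f2[60 + 30] <- 200; f2[65] <- 100
  tr2 <- calcium_trace("c1", f2)
  expect_equal(peak_dff(tr2, 60), 0)
  expect_error(peak_dff(tr2, 190), "exceeds trace length")
  # invariant to rescaling the whole trace
  tr3 <- calcium_trace("c1", f * 3.7)
  expect_equal(peak_dff(tr3, 60), peak_dff(tr, 60), tolerance = 1e-12)
})

test_that("response calls need the peak strictly above 5 s.d.", {
  expect_true(call_response(0.5, 0.05))
  expect_false(call_response(0.25, 0.05))
  expect_true(call_response(0.001, 0))
  expect_error(call_response(0.5, NaN), "finite")
})

test_that("QC fails weak KCl responses, drifting baselines, and no recovery", {
  tb <- make_two_block_trace(rep(1, 5), rep(1, 5))
  expect_true(qc_trace(tb$trace, tb$schedule)$pass)

  # dead cell: baseline noise but no KCl transient at all
  set.seed(3)
  f <- 100 + rnorm(700, 0, 2)            # sd/F = 0.02 -> 5 s.d. = 0.1
  weak <- calcium_trace("w", f)
  qc <- qc_trace(weak, tb$schedule)
  expect_false(qc$pass)
  expect_true("kcl_below_5sd" %in% qc$reasons)

  # +20% linear drift across the recording at 10% tolerance
  drift <- calcium_trace("d", seq(100, 120, length.out = 700))
  qc2 <- qc_trace(drift, tb$schedule)
  expect_false(qc2$pass)
  expect_true("baseline_drift" %in% qc2$reasons)

  expect_error(qc_trace(tb$trace,
                        stimulus_schedule("ATP", 30)), "no KCl")
})

test_that("GABA inhibition honours its anchors and affine form", {
  expect_identical(gaba_inhibition(0, 0.5, 0.5), 100)
  expect_identical(gaba_inhibition(1.0, 0.5, 0.5), -100)
  expect_identical(gaba_inhibition(0.5, 0.5, 0.5), 0)
  expect_error(gaba_inhibition(0.2, 0, 0), "positive")
  # affine in the test peak with slope -100 / flank mean, always <= 100
  flank <- 0.8
  xs <- c(0, 0.2, 0.4, 1.6, 3)
  got <- vapply(xs, gaba_inhibition, numeric(1), peak_kcl_pre = flank,
                peak_kcl_post = flank)
  expect_equal(got, 100 - 100 / flank * xs)
  expect_true(all(got <= 100))
})

test_that("cell summaries average replicates and flag inconsistency", {
  tb <- make_two_block_trace(c(0.3, 0.5, 1, 0.2, 1),
                             c(0.3, 0.5, 1, 0.2, 1))
  row <- summarize_cell(tb$trace, tb$schedule)
  expect_equal(row$atp_mean, 0.5)
  expect_equal(row$ht5_mean, 0.3)
  expect_equal(row$inhibition_mean, 80)
  expect_true(row$consistent)
  expect_true(row$atp_response && row$ht5_response)

  # replicate responses 0.4 and 0.6 average to 0.5
  tb2 <- make_two_block_trace(c(0, 0.4, 1, 1, 1), c(0, 0.6, 1, 1, 1))
  row2 <- summarize_cell(tb2$trace, tb2$schedule)
  expect_equal(row2$atp_mean, 0.5)
  expect_equal(row2$inhibition_mean, 0)

  # one responsive and one silent replicate -> inconsistent
  tb3 <- make_two_block_trace(c(0, 0.5, 1, 1, 1), c(0, 0, 1, 1, 1))
  expect_false(summarize_cell(tb3$trace, tb3$schedule)$consistent)

  short <- stimulus_schedule(c("5HT", "ATP", "KCl"), c(21, 81, 141))
  expect_error(summarize_cell(tb$trace, short), "missing.*KCl")
})

test_that("functional clustering separates archetypes and is duplication-invariant", {
  tr <- simulate_traces(n_cells_per_archetype = 8, seed = 4)
  tab <- summarize_cells(tr$traces, tr$schedule)
  tab <- tab[tab$qc_pass & tab$consistent, ]
  assign <- cluster_responses(tab, k = 4)
  truth <- cluster_assignment(setNames(tr$truth$archetype,
                                       tr$truth$cell_id))
  expect_equal(adjusted_rand_index(assign, truth), 1)

  dup <- tab
  dup$cell_id <- paste0(dup$cell_id, "_copy")
  both <- rbind(tab, dup)
  a2 <- unclass(cluster_responses(both, k = 4))
  expect_identical(unname(a2[tab$cell_id]),
                   unname(a2[paste0(tab$cell_id, "_copy")]))

  same <- tab[rep(1, 6), ]
  same$cell_id <- paste0("s", 1:6)
  expect_warning(cluster_responses(same, k = 2), "identical")
  expect_error(cluster_responses(tab[1:2, ], k = 4), "fewer rows")
})

test_that("response-call sensitivity and specificity hold at planted noise", {
  tr <- simulate_traces(n_cells_per_archetype = 30, noise_sd_over_f = 0.02,
                        seed = 10)
  tab <- summarize_cells(tr$traces, tr$schedule)
  merged <- merge(tab, tr$truth, by = "cell_id")
  sens_atp <- mean(merged$atp_response[merged$responds_ATP])
  fpr_atp <- mean(merged$atp_response[!merged$responds_ATP])
  sens_ht5 <- mean(merged$ht5_response[merged$responds_5HT])
  fpr_ht5 <- mean(merged$ht5_response[!merged$responds_5HT])
  expect_gte(sens_atp, 0.95); expect_gte(sens_ht5, 0.95)
  expect_lte(fpr_atp, 0.05); expect_lte(fpr_ht5, 0.05)
})

test_that("traces and schedules round-trip through CSV", {
  tr <- simulate_traces(n_cells_per_archetype = 2, seed = 2)
  dir <- withr::local_tempdir()
  tp <- file.path(dir, "traces.csv"); sp <- file.path(dir, "sched.csv")
  write_traces_csv(tr$traces, tp)
  write_schedule_csv(tr$schedule, sp)
  back <- read_traces_csv(tp)
  expect_length(back, length(tr$traces))
  expect_equal(back[[1]]$fluorescence, tr$traces[[1]]$fluorescence,
               tolerance = 1e-10)
  sched <- read_schedule_csv(sp)
  expect_equal(as.data.frame(sched), as.data.frame(tr$schedule))
})
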