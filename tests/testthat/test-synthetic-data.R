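test_that("the expression generator is reproducible and plants stated sizes", {
  s1 <- simulate_expression(small_sim_config(seed = 9))
  s2 <- simulate_expression(small_sim_config(seed = 9))
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_identical(s1$truth$cell_labels, s2$truth$cell_labels)
  s3 <- simulate_expression(small_sim_config(seed = 10))
  expect_false(identical(s1$matrix$values, s3$matrix$values))

  full <- simulate_expression()
  expect_identical(length(full$matrix$cell_ids), 96L)
  expect_identical(as.integer(table(full$truth$cell_labels)[
    c("somatosensory", "T1", "T2", "T3", "outlier")]),
    c(37L, 33L, 6L, 18L, 2L))
  # marker sets are disjoint across groups
  mk <- full$truth$marker_genes
  expect_identical(anyDuplicated(unlist(mk)), 0L)
})

test_that("planted marker fold matches the configured log2 shift", {
  sim <- simulate_expression()
  m <- sim$matrix
  truth <- sim$truth
  lab <- truth$cell_labels
  for (grp in c("T1", "T3", "gustatory")) {
    inside <- if (grp == "gustatory") {
      lab %in% c("T1", "T2", "T3", "outlier")
    } else lab == grp
    genes <- truth$marker_genes[[grp]]
    ratio <- rowMeans(m$values[genes, inside, drop = FALSE]) /
      rowMeans(m$values[genes, !inside, drop = FALSE])
    planted <- 2^truth$marker_shifts[[grp]]
    expect_lt(abs(mean(ratio) / planted - 1), 0.25)
  }
})

test_that("noiseless traces score back to the planted parameters exactly", {
  tr <- simulate_traces(n_cells_per_archetype = 3, noise_sd_over_f = 0)
  tab <- summarize_cells(tr$traces, tr$schedule)
  merged <- merge(tab, tr$truth, by = "cell_id")
  expect_lt(max(abs(merged$atp_mean - merged$atp_dff)), 1e-9)
  expect_lt(max(abs(merged$ht5_mean - merged$ht5_dff)), 1e-9)
  expect_lt(max(abs(merged$inhibition_mean - merged$inhibition_percent)),
            1e-9)
  expect_true(all(merged$qc_pass))
})

test_that("planted inhibition extremes produce the stated KCl+GABA peaks", {
  tr <- simulate_traces(n_cells_per_archetype = 1, noise_sd_over_f = 0,
                        inhibition_levels = c(100, -100, 0, 50))
  tab <- summarize_cells(tr$traces, tr$schedule)
  tab <- tab[order(tab$cell_id), ]
  # archetype 1 planted at 100%: no KCl+GABA response at all
  sched <- tr$schedule
  gaba_peak <- peak_dff(tr$traces[[tab$cell_id[1]]], sched$onset_frame[4])
  kcl_peak <- peak_dff(tr$traces[[tab$cell_id[1]]], sched$onset_frame[3])
  expect_equal(gaba_peak, 0, tolerance = 1e-12)
  # archetype 2 planted at -100%: KCl+GABA peak is twice the KCl peak
  gaba_peak2 <- peak_dff(tr$traces[[tab$cell_id[2]]], sched$onset_frame[4])
  kcl_peak2 <- peak_dff(tr$traces[[tab$cell_id[2]]], sched$onset_frame[3])
  expect_equal(gaba_peak2, 2 * kcl_peak2, tolerance = 1e-9)
  expect_equal(tab$inhibition_mean, c(100, -100, 0, 50), tolerance = 1e-9)
})

test_that("fixture bundles regenerate byte-identically and detect tampering", {
  cfg <- small_sim_config(seed = 3)
  ta <- list(n_cells_per_archetype = 2, seed = 3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- write_fixture_bundle(d1, cfg, ta)
  m2 <- write_fixture_bundle(d2, cfg, ta)
  for (i in seq_along(m1$files)) {
    expect_identical(m1$files[[i]]$md5, m2$files[[i]]$md5)
  }
  expect_true(verify_fixture_bundle(d1))
  # manifest lists every written file
  listed <- vapply(m1$files, `[[`, "", "name")
  expect_setequal(listed, c("matrix.tsv", "labels.csv", "truth.json",
                            "traces.csv", "schedule.csv"))
  # tampering is caught by checksum
  cat("tamper\n", file = file.path(d1, "labels.csv"), append = TRUE)
  expect_error(verify_fixture_bundle(d1), "checksum mismatch.*labels.csv")
  file.remove(file.path(d2, "traces.csv"))
  expect_error(verify_fixture_bundle(d2), "missing")
})
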