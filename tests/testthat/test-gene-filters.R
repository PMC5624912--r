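make_mat <- function(v, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(v)))
  if (is.null(cells)) cells <- paste0("c", seq_len(ncol(v)))
  expression_matrix(v, gene_ids = genes, cell_ids = cells)
}

test_that("high-expression filter is inclusive at the threshold", {
  v <- rbind(rep(250, 4), rep(199.9, 4), rep(200, 4))
  m <- make_mat(v)
  expect_identical(filter_high_expression(m, 200), c("g1", "g3"))
  expect_identical(filter_high_expression(make_mat(matrix(0, 3, 4)), 200),
                   character(0))
})

test_that("group-selective filter applies all three criteria", {
  spec <- filter_spec(min_mean_fpkm = 1, min_cells_detected = 2,
                      min_fold = 5, pseudocount = 0.01)
  # in-mean 5.0 detected in 3/4, out-mean 0.5 -> kept
  # detected in exactly 1 in-group cell -> excluded by criterion (i)
  # fold exactly 1 -> excluded by criterion (iii)
  v <- rbind(c(8, 6, 6, 0, 1, 0), c(20, 0, 0, 0, 0, 0), c(5, 5, 5, 5, 5, 5))
  m <- make_mat(v)
  got <- filter_group_selective(m, paste0("c", 1:4), paste0("c", 5:6), spec)
  expect_identical(got, "g1")
  expect_error(filter_group_selective(m, c("c1", "c2"), c("c2", "c5"), spec),
               "overlap")
})

test_that("detection filter honours the strict/inclusive dialects", {
  v <- rbind(c(10, 10, 9, 0))
  m <- make_mat(v)
  expect_identical(filter_detected(m, min_fpkm = 10, min_cells = 2), "g1")
  expect_identical(filter_detected(m, min_fpkm = 10, min_cells = 2,
                                   strict = TRUE), character(0))
  expect_error(filter_detected(m, min_fpkm = 10, min_cells = 5),
               "exceeds number of cells")
})

test_that("list restriction intersects then applies the mean filter", {
  v <- rbind(B = c(2, 2), C = c(0.1, 0.1))
  m <- expression_matrix(v, cell_ids = c("c1", "c2"))
  expect_message(got <- restrict_to_list(m, c("A", "B"), min_mean_fpkm = 1),
                 "1 listed symbol")
  expect_identical(got, "B")
  expect_warning(restrict_to_list(m, c("X", "Y")), "no listed gene")
})

test_that("a 2407-symbol list with 976 planted expressed genes returns 976", {
  set.seed(7)
  n_in <- 1776                      # listed genes present in the matrix
  genes <- sprintf("tf%04d", 1:n_in)
  listed <- c(genes, sprintf("absent%03d", 1:(2407 - n_in)))
  expressed <- genes[1:976]         # planted at mean >= 1
  v <- matrix(0.05, n_in, 12, dimnames = list(genes, paste0("c", 1:12)))
  v[expressed, ] <- 2 + matrix(runif(976 * 12), 976)
  m <- expression_matrix(v)
  got <- suppressMessages(restrict_to_list(m, listed, min_mean_fpkm = 1))
  expect_length(got, 976)
  expect_setequal(got, expressed)
})

test_that("raising any threshold never grows the selected set", {
  sim <- simulate_expression(small_sim_config())
  m <- sim$matrix
  lab <- sim$truth$major_split
  taste <- names(lab)[lab == "gustatory"]
  somato <- names(lab)[lab == "somatosensory"]
  prev <- NULL
  for (fold in c(0, 2, 5, 10, 50)) {
    cur <- filter_group_selective(m, taste, somato,
                                  filter_spec(min_fold = fold))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  for (thr in c(1, 10, 100, 200)) {
    cur <- filter_high_expression(m, thr)
    expect_true(all(filter_high_expression(m, thr * 2) %in% cur))
  }
})

test_that("a fully permissive selective filter keeps all in-group detected genes", {
  sim <- simulate_expression(small_sim_config())
  m <- sim$matrix
  lab <- sim$truth$major_split
  taste <- names(lab)[lab == "gustatory"]
  somato <- names(lab)[lab == "somatosensory"]
  got <- filter_group_selective(
    m, taste, somato,
    filter_spec(min_mean_fpkm = 0, min_cells_detected = 1, min_fold = 0))
  expect_setequal(got, m$gene_ids[rowSums(m$values[, taste] > 0) >= 1])
  everything <- filter_group_selective(
    m, taste, somato,
    filter_spec(min_mean_fpkm = 0, min_cells_detected = 0, min_fold = 0))
  expect_setequal(everything, m$gene_ids)
})

test_that("filter results are independent of gene and cell order", {
  sim <- simulate_expression(small_sim_config())
  m <- sim$matrix
  set.seed(1)
  perm <- subset_matrix(m, genes = sample(m$gene_ids),
                        cells = sample(m$cell_ids))
  expect_setequal(filter_high_expression(m, 200),
                  filter_high_expression(perm, 200))
  lab <- sim$truth$major_split
  taste <- names(lab)[lab == "gustatory"]
  somato <- names(lab)[lab == "somatosensory"]
  expect_setequal(filter_group_selective(m, taste, somato),
                  filter_group_selective(perm, sample(taste),
                                         sample(somato)))
})
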