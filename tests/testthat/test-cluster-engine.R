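test_that("log transform maps FPKM onto log2(x + 1)", {
  v <- matrix(c(0, 1, 255, 7), 2, 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  lt <- log_transform(expression_matrix(v))
  expect_equal(unname(lt$values), matrix(c(0, 1, 8, 3), 2, 2))
})

test_that("pairwise PCC matches the direct covariance formula", {
  set.seed(11)
  v <- matrix(rexp(120), 20, 6,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:6)))
  m <- expression_matrix(v)
  r <- pairwise_pcc(m)
  x <- log2(v + 1)
  manual <- matrix(NA_real_, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    xi <- x[, i] - mean(x[, i]); xj <- x[, j] - mean(x[, j])
    manual[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  expect_equal(unname(r$values), manual, tolerance = 1e-12)
  expect_equal(diag(r$values), setNames(rep(1, 6), paste0("c", 1:6)))

  # identical profiles correlate at 1; anti-correlated centered profiles at -1
  v2 <- cbind(a = c(1, 5, 9), b = c(1, 5, 9), d = c(9, 5, 1))
  rownames(v2) <- paste0("g", 1:3)
  r2 <- pairwise_pcc(expression_matrix(v2), log2 = FALSE)
  expect_equal(r2$values["a", "b"], 1)
  expect_equal(r2$values["a", "d"], -1)

  # PCC is invariant to positive rescaling of one cell's profile
  v3 <- v2; v3[, "a"] <- v3[, "a"] * 7
  r3 <- pairwise_pcc(expression_matrix(v3), log2 = FALSE)
  expect_equal(r3$values["a", "d"], r2$values["a", "d"], tolerance = 1e-12)

  v4 <- v2; v4[, "a"] <- 3
  expect_error(pairwise_pcc(expression_matrix(v4), log2 = FALSE),
               "zero variance.*a")
})

test_that("UPGMA matches the naive re-averaging oracle on random inputs", {
  set.seed(1234)
  for (rep in 1:50) {
    n <- sample(2:7, 1)
    d <- random_distance_matrix(n)
    tree <- upgma(d)
    expect_false(is.unsorted(tree$height))          # UPGMA height guarantee
    expect_equal(unname(cophenetic_of(tree)), naive_upgma_cophenetic(d),
                 tolerance = 1e-12)
  }
})

test_that("UPGMA agrees with stats::hclust average linkage", {
  set.seed(99)
  for (n in c(5, 12, 40)) {
    d <- random_distance_matrix(n)
    tree <- upgma(d)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(tree$height, hc$height, tolerance = 1e-12)
    expect_equal(cophenetic_of(tree),
                 as.matrix(stats::cophenetic(hc)), tolerance = 1e-12)
  }
})

test_that("two leaves merge at their distance and ties break lexicographically", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  tree <- upgma(d, labels = c("a", "b"))
  expect_equal(tree$height, 0.4)
  expect_equal(tree$merge, matrix(c(-1L, -2L), 1))

  # two tied minimal pairs: (1,2) and (3,4); (1,2) must merge first
  d4 <- matrix(0.9, 4, 4); diag(d4) <- 0
  d4[1, 2] <- d4[2, 1] <- 0.2
  d4[3, 4] <- d4[4, 3] <- 0.2
  t4 <- upgma(d4)
  expect_equal(t4$merge[1, ], c(-1L, -2L))
  expect_equal(t4$merge[2, ], c(-3L, -4L))

  expect_error(upgma(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("tree cutting recovers planted blocks and relabels small branches", {
  sim <- simulate_expression(small_sim_config())
  m <- sim$matrix
  genes1 <- filter_high_expression(m, 200)
  tree <- upgma(pcc_distance(pairwise_pcc(m, genes1)), labels = m$cell_ids)
  assign <- cut_tree(tree, 2)
  expect_equal(adjusted_rand_index(assign,
                                   cluster_assignment(sim$truth$major_split)),
               1)
  # k = leaves: every cell its own cluster
  solo <- cut_tree(tree, length(m$cell_ids))
  expect_length(unique(unclass(solo)), length(m$cell_ids))
  expect_error(cut_tree(tree, length(m$cell_ids) + 1), "k must be")
})

test_that("ARI reproduces hand-computed contingency values", {
  # identical partitions under renamed labels
  a <- cluster_assignment(c(x1 = "A", x2 = "A", x3 = "B", x4 = "B"))
  b <- cluster_assignment(c(x1 = "left", x2 = "left", x3 = "right",
                            x4 = "right"))
  expect_equal(adjusted_rand_index(a, b), 1)
  # {AB|CD} vs {AC|BD}: ARI = -0.5 from the contingency formula
  b2 <- cluster_assignment(c(x1 = "p", x3 = "p", x2 = "q", x4 = "q"))
  expect_equal(adjusted_rand_index(a, b2), -0.5)
  # all singletons vs one block on n = 6: ARI = 0
  s <- cluster_assignment(setNames(letters[1:6], paste0("y", 1:6)))
  one <- cluster_assignment(setNames(rep("all", 6), paste0("y", 1:6)))
  expect_equal(adjusted_rand_index(s, one), 0)

  expect_error(adjusted_rand_index(a, cluster_assignment(c(z9 = "A"))),
               "share no cells")
  # unassigned cells are excluded pairwise
  a2 <- cluster_assignment(c(x1 = "A", x2 = "A", x3 = "B", x4 = "unassigned"))
  b3 <- cluster_assignment(c(x1 = "A", x2 = "A", x3 = "B", x4 = "B"))
  expect_equal(adjusted_rand_index(a2, b3), 1)
})

test_that("ARI agrees with mclust on random partitions", {
  skip_if_not_installed("mclust")
  set.seed(5)
  ids <- paste0("c", 1:40)
  for (rep in 1:20) {
    p1 <- setNames(sample(letters[1:4], 40, replace = TRUE), ids)
    p2 <- setNames(sample(letters[1:3], 40, replace = TRUE), ids)
    expect_equal(adjusted_rand_index(cluster_assignment(p1),
                                     cluster_assignment(p2)),
                 mclust::adjustedRandIndex(p1, p2), tolerance = 1e-12)
  }
})

test_that("shuffled labels give near-zero ARI at n = 96", {
  set.seed(8)
  ids <- paste0("c", 1:96)
  ref <- cluster_assignment(setNames(rep(c("A", "B"), c(59, 37)), ids))
  aris <- replicate(100, {
    adjusted_rand_index(ref, cluster_assignment(setNames(
      sample(rep(c("A", "B"), c(59, 37))), ids)))
  })
  expect_true(all(abs(aris) < 0.2))
})

test_that("PCA satisfies its variance, invariance and reconstruction properties", {
  # variation along a single gene axis -> PC1 carries all variance
  v <- rbind(g1 = c(1, 3, 7, 15), g2 = rep(2, 4), g3 = rep(5, 4))
  colnames(v) <- paste0("c", 1:4)
  p <- run_pca(expression_matrix(v), n_components = 2)
  expect_equal(p$explained_variance_fraction[1], 1)
  expect_error(run_pca(expression_matrix(v), n_components = 5),
               "n_components")

  set.seed(21)
  v2 <- matrix(rexp(5 * 4, 0.2), 5, 4,
               dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  m2 <- expression_matrix(v2)
  p2 <- run_pca(m2, n_components = 3)
  # gene-order permutation leaves scores unchanged
  perm <- sample(rownames(v2))
  p2p <- run_pca(subset_matrix(m2, genes = perm), genes = perm,
                 n_components = 3)
  expect_equal(p2$scores, p2p$scores, tolerance = 1e-10)
  # full-rank reconstruction returns the centered data
  x <- t(log2(v2 + 1))
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(unname(p2$scores %*% t(p2$loadings[colnames(x), ])),
               unname(xc), tolerance = 1e-8)
})

test_that("PCA concordance is perfect on planted blocks and NA for k = 1", {
  sim <- simulate_expression(small_sim_config())
  m <- sim$matrix
  genes <- filter_high_expression(m, 200)
  tree <- upgma(pcc_distance(pairwise_pcc(m, genes)), labels = m$cell_ids)
  hca <- cut_tree(tree, 2)
  detected <- filter_detected(m, min_fpkm = 0, min_cells = 1, strict = TRUE)
  pca <- run_pca(m, detected, 2)
  rep2 <- concordance_report(hca, pca, k = 2)
  expect_equal(rep2$ari, 1)
  expect_true(rep2$centroid_separation > 0)
  expect_warning(rep1 <- concordance_report(hca, pca, k = 1), "k = 1")
  expect_true(is.na(rep1$ari))
})

test_that("the dendrogram serializes to Newick with all leaves", {
  d <- random_distance_matrix(6)
  tree <- upgma(d, labels = paste0("leaf", 1:6))
  nwk <- write_newick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, paste0("leaf", 1:6))
})
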