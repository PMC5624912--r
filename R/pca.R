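#' Principal component analysis of cells in gene space
#'
#' PCA of the cells over a selected gene set, on log2(FPKM + 1) values
#' mean-centered per gene (no unit-variance scaling by default, so highly
#' expressed genes keep their weight in the loadings; both choices are
#' exposed).  Component signs are fixed so that the gene with the largest
#' absolute loading on each component loads positively, making score plots
#' reproducible across platforms.
#'
#' @param mat an [expression_matrix()].
#' @param genes gene ids to use (default all).
#' @param n_components number of components to keep.
#' @param log2 analyze log2(FPKM + 1) (default `TRUE`).
#' @param scale. divide each centered gene by its standard deviation
#'   (default `FALSE`).
#' @return An object of class `pca_result`: `scores` (cells x components),
#'   `loadings` (genes x components), `explained_variance_fraction`,
#'   `cell_ids`, `gene_ids`, `center`.
#' @export
run_pca <- function(mat, genes = mat$gene_ids, n_components = 2,
                    log2 = TRUE, scale. = FALSE) {
  stopifnot(inherits(mat, "expression_matrix"))
  miss <- setdiff(genes, mat$gene_ids)
  if (length(miss))
    stop("unknown gene id(s): ", paste(utils::head(miss, 5), collapse = ", "))
  n_cells <- length(mat$cell_ids)
  if (n_cells < 2) stop("need at least 2 cells for PCA")
  if (n_components > min(length(genes), n_cells))
    stop("n_components (", n_components, ") exceeds min(genes, cells) = ",
         min(length(genes), n_cells))
  x <- t(mat$values[genes, , drop = FALSE])      # cells x genes
  if (log2) x <- log2(x + 1)
  if (scale.) {                                   # drop zero-variance genes
    sds <- apply(x, 2, sd)
    x <- x[, sds > 0, drop = FALSE]
    genes <- colnames(x)
  }
  p <- prcomp(x, center = TRUE, scale. = scale., rank. = n_components)
  total_var <- sum(p$sdev^2)
  scores <- p$x[, seq_len(n_components), drop = FALSE]
  loadings <- p$rotation[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {              # deterministic sign
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- mat$cell_ids
  rownames(loadings) <- genes
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction =
                   p$sdev[seq_len(n_components)]^2 / total_var,
                 cell_ids = mat$cell_ids, gene_ids = genes,
                 center = p$center),
            class = "pca_result")
}

#' @exportS3Method base::print
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d cells x %d components; explained: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
                    collapse = ", ")))
  invisible(x)
}

#' Concordance between hierarchical clustering and PCA groupings
#'
#' Clusters the top-2 principal-component scores (UPGMA on Euclidean
#' distances, plain k-cut) and compares the result to a hierarchical
#' cluster assignment via the adjusted Rand index — the quantitative
#' version of "the two independent analyses produce the same groupings".
#'
#' @param hca a `cluster_assignment` from correlation-based clustering.
#' @param pca a [run_pca()] result (>= 2 components).
#' @param k number of groups to cut the PCA scores into.
#' @return List with `ari`, the PCA-space `assignment`, and
#'   `centroid_separation` (smallest between-centroid Euclidean distance in
#'   top-2 score space; `NA` when k = 1).
#' @export
concordance_report <- function(hca, pca, k = 2) {
  stopifnot(inherits(pca, "pca_result"))
  if (ncol(pca$scores) < 2) stop("need at least 2 PCA components")
  s <- pca$scores[, 1:2, drop = FALSE]
  d <- as.matrix(stats::dist(s))
  tree <- upgma(d, labels = pca$cell_ids)
  assign <- cut_tree(tree, k = k)
  if (k == 1) {
    warning("k = 1: ARI against a single block is undefined")
    ari <- NA_real_
  } else {
    ari <- adjusted_rand_index(hca, assign)
  }
  cents <- do.call(rbind, lapply(split(as.data.frame(s),
                                       unclass(assign)[rownames(s)]),
                                 colMeans))
  sep <- if (nrow(cents) < 2) NA_real_ else min(stats::dist(cents))
  list(ari = ari, assignment = assign, centroid_separation = sep)
}
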