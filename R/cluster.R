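#' Log-transform an expression matrix
#'
#' Applies `log2(FPKM + 1)` elementwise.  All correlation and PCA steps in
#' the pipeline operate on this transform by default so that fold changes,
#' not absolute FPKM differences, drive cell-cell similarity.
#'
#' @param mat an [expression_matrix()].
#' @return An [expression_matrix()] of log2(FPKM + 1) values.
#' @export
log_transform <- function(mat) {
  stopifnot(inherits(mat, "expression_matrix"))
  mat$values <- log2(mat$values + 1)
  mat
}

#' Cell-to-cell Pearson correlation matrix
#'
#' Pearson correlation coefficients (PCCs) between cell expression profiles
#' over a selected gene set, computed on log2(FPKM + 1) by default (set
#' `log2 = FALSE` for raw FPKM).
#'
#' @param mat an [expression_matrix()].
#' @param genes gene ids to correlate over (>= 2); default all.
#' @param log2 correlate log2(FPKM + 1) profiles (default `TRUE`).
#' @return An object of class `correlation_matrix`: list with `values`
#'   (symmetric, unit diagonal) and `cell_ids`.
#' @export
pairwise_pcc <- function(mat, genes = mat$gene_ids, log2 = TRUE) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (length(genes) < 2)
    stop("need at least 2 genes to correlate cells (got ", length(genes), ")")
  miss <- setdiff(genes, mat$gene_ids)
  if (length(miss))
    stop("unknown gene id(s): ", paste(utils::head(miss, 5), collapse = ", "))
  v <- mat$values[genes, , drop = FALSE]
  if (log2) v <- log2(v + 1)
  sds <- apply(v, 2, sd)
  flat <- mat$cell_ids[sds == 0]
  if (length(flat))
    stop("cell(s) with zero variance over the gene set: ",
         paste(flat, collapse = ", "))
  r <- cor(v)
  r[cbind(seq_len(ncol(v)), seq_len(ncol(v)))] <- 1
  structure(list(values = r, cell_ids = mat$cell_ids),
            class = "correlation_matrix")
}

#' Correlation distance
#'
#' Maps a correlation matrix to the clustering distance `1 - PCC`.
#'
#' @param corr a [pairwise_pcc()] result.
#' @return Square symmetric distance matrix with zero diagonal.
#' @export
pcc_distance <- function(corr) {
  stopifnot(inherits(corr, "correlation_matrix"))
  d <- 1 - corr$values
  diag(d) <- 0
  d
}

#' UPGMA hierarchical clustering
#'
#' Agglomerative clustering with average linkage (unweighted pair-group
#' method with arithmetic mean): at every step the two clusters with the
#' smallest average inter-cluster distance merge, at a height equal to that
#' average.  Ties are broken deterministically by the lexicographically
#' smallest pair of minimum original leaf indices, so results are identical
#' across platforms.
#'
#' @param dist square symmetric numeric matrix with zero diagonal (e.g.
#'   [pcc_distance()] output), or a `stats::dist` object.
#' @param labels leaf labels; default from `dimnames`.
#' @return An object of class `gg_dendrogram`: list with hclust-style
#'   `merge` (n-1 x 2, negative entries = leaves), `height`, `labels`,
#'   `order`.  Convert with [as.hclust.gg_dendrogram()].
#' @export
upgma <- function(dist, labels = NULL) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (n != ncol(dist) || any(abs(dist - t(dist)) > 1e-12))
    stop("distance matrix must be square and symmetric")
  if (any(abs(diag(dist)) > 1e-12)) stop("distance diagonal must be zero")
  if (is.null(labels)) labels <- rownames(dist)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n < 2) stop("need at least 2 leaves")

  D <- dist
  active <- seq_len(n)            # columns of D still live
  size <- rep(1L, n)
  code <- -seq_len(n)             # hclust merge codes
  minleaf <- seq_len(n)           # tie-break representative
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    best <- NULL
    bd <- Inf
    na <- length(active)
    for (a in seq_len(na - 1)) {
      i <- active[a]
      for (b in (a + 1):na) {
        j <- active[b]
        dij <- D[i, j]
        if (dij < bd - 1e-15) {
          bd <- dij; best <- c(i, j)
        } else if (abs(dij - bd) <= 1e-15) {
          # tie: smallest (min leaf of first, min leaf of second)
          cur <- sort(c(minleaf[i], minleaf[j]))
          old <- sort(c(minleaf[best[1]], minleaf[best[2]]))
          if (cur[1] < old[1] || (cur[1] == old[1] && cur[2] < old[2])) {
            bd <- dij; best <- c(i, j)
          }
        }
      }
    }
    i <- best[1]; j <- best[2]
    ci <- code[i]; cj <- code[j]
    # hclust convention: singletons (by leaf index) before earlier merges
    first <- if (ci < 0 && cj < 0) abs(ci) <= abs(cj)
             else if (ci < 0) TRUE
             else if (cj < 0) FALSE
             else ci <= cj
    merge[step, ] <- if (first) c(ci, cj) else c(cj, ci)
    height[step] <- bd
    # Lance-Williams average-linkage update, stored in slot i
    ni <- size[i]; nj <- size[j]
    rest <- setdiff(active, c(i, j))
    D[i, rest] <- (ni * D[i, rest] + nj * D[j, rest]) / (ni + nj)
    D[rest, i] <- D[i, rest]
    size[i] <- ni + nj
    code[i] <- step
    minleaf[i] <- min(minleaf[i], minleaf[j])
    active <- setdiff(active, j)
  }

  structure(list(merge = merge, height = height, labels = labels,
                 order = .dendro_order(merge, n)),
            class = "gg_dendrogram")
}

# leaf ordering making each merge contiguous (for hclust validity)
.dendro_order <- function(merge, n) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(merge[node, 1]), rec(merge[node, 2]))
  }
  rec(n - 1L)
}

#' @exportS3Method base::print
print.gg_dendrogram <- function(x, ...) {
  cat(sprintf("<gg_dendrogram> %d leaves, merge heights %.4g .. %.4g\n",
              length(x$labels), min(x$height), max(x$height)))
  invisible(x)
}

#' @rdname upgma
#' @param x a `gg_dendrogram`.
#' @param ... unused.
#' @export
as.hclust.gg_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "1 - PCC"),
            class = "hclust")
}

#' @export
plot.gg_dendrogram <- function(x, ...) plot(as.hclust(x), ...)

#' Serialize a dendrogram as Newick
#'
#' Branch lengths are height differences between nested merges.
#'
#' @param tree a [upgma()] result.
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "gg_dendrogram"))
  phy <- ape::as.phylo(as.hclust(tree))
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Cut a dendrogram into clusters
#'
#' Cuts at the smallest number of branches `k' >= k` such that exactly `k`
#' clusters contain at least `min_cluster_size` cells; all cells in smaller
#' clusters are relabeled `"unassigned"`.  With `min_cluster_size = 1` this
#' is the plain k-group cut.  Retained clusters are named `"C1"`, `"C2"`,
#' ... by decreasing size (ties by first leaf appearance).  This is how two
#' stray cells that "do not cluster well" drop out of the sub-cluster cut
#' while the three populated sub-clusters keep their identity.
#'
#' @param tree a [upgma()] result.
#' @param k number of retained clusters.
#' @param min_cluster_size minimum size for a cluster to be retained.
#' @return An object of class `cluster_assignment`: named character vector
#'   mapping every cell to a cluster name or `"unassigned"`.
#' @export
cut_tree <- function(tree, k, min_cluster_size = 1) {
  stopifnot(inherits(tree, "gg_dendrogram"))
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k must be between 1 and ", n, " (got ", k, ")")
  hc <- as.hclust(tree)
  for (kp in k:n) {
    cl <- cutree(hc, k = kp)
    sizes <- table(cl)
    big <- names(sizes)[sizes >= min_cluster_size]
    if (length(big) == k) {
      lab <- ifelse(cl %in% as.integer(big), paste0("grp", cl), "unassigned")
      names(lab) <- tree$labels
      return(.name_clusters(lab))
    }
    if (length(big) < k && kp > k && all(sizes < min_cluster_size)) break
  }
  stop("no cut yields ", k, " clusters of size >= ", min_cluster_size)
}

# rename retained clusters C1..Ck by decreasing size (ties: first appearance)
.name_clusters <- function(lab) {
  keep <- lab != "unassigned"
  u <- unique(lab[keep])
  sizes <- vapply(u, function(g) sum(lab == g), integer(1))
  u <- u[order(-sizes, match(u, lab[keep]))]
  new <- setNames(paste0("C", seq_along(u)), u)
  out <- ifelse(keep, new[lab], "unassigned")
  names(out) <- names(lab)
  structure(out, class = "cluster_assignment")
}

#' Build a cluster assignment from labels
#'
#' @param labels named character vector (names = cell ids); `"unassigned"`
#'   is the reserved label for cells outside every cluster.
#' @return A `cluster_assignment`.
#' @export
cluster_assignment <- function(labels) {
  if (is.null(names(labels))) stop("labels must be named by cell id")
  structure(setNames(as.character(labels), names(labels)),
            class = "cluster_assignment")
}

#' @exportS3Method base::print
print.cluster_assignment <- function(x, ...) {
  tab <- sort(table(unclass(x)), decreasing = TRUE)
  cat("<cluster_assignment>",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement from the contingency table, computed over the
#' cells present in both assignments; cells labeled `"unassigned"` in either
#' partition are excluded first.
#'
#' @param a,b `cluster_assignment`s (or named label vectors).
#' @return ARI in \[-1, 1\]; `NA` (with a warning) when fewer than 2 cells
#'   remain or either partition is a single block covering all cells.
#' @export
adjusted_rand_index <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  common <- intersect(names(a), names(b))
  if (!length(common)) stop("assignments share no cells")
  a <- a[common]; b <- b[common]
  keep <- a != "unassigned" & b != "unassigned"
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2) {
    warning("fewer than 2 jointly assigned cells; ARI undefined")
    return(NA_real_)
  }
  tab <- table(a, b)
  if (nrow(tab) == 1 && ncol(tab) == 1) {
    warning("both partitions are a single block; ARI undefined")
    return(NA_real_)
  }
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  expected <- ai * bj / nn
  maxi <- (ai + bj) / 2
  if (maxi == expected) {
    warning("degenerate contingency table; ARI undefined")
    return(NA_real_)
  }
  (nij - expected) / (maxi - expected)
}
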