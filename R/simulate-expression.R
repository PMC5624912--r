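#' Configuration for the synthetic expression generator
#'
#' Defaults emulate the geniculate-ganglion study conditions: 96 cells in
#' two major classes (59 gustatory including 2 poorly clustering outliers,
#' 37 somatosensory), with the gustatory class split 33/6/18 into
#' sub-groups T1/T2/T3; ~17k expressed genes with lognormal baselines,
#' log-scale group shifts for planted markers, multiplicative per-cell
#' noise, and threshold dropout.
#'
#' Marker architecture: highly expressed major-class markers separate the
#' gustatory and somatosensory classes (in-class ~2^9 FPKM, 2^4-fold lower
#' out-of-class, so they pass the mean >= 200 FPKM first-level filter);
#' sub-cluster markers sit near 2 FPKM outside and `marker_log2_shift`
#' log2 units higher inside their sub-cluster.  The default shift of 7
#' (~256 FPKM in-group) keeps even T2 markers (6 of 59 gustatory cells)
#' above a 10-fold gustatory-vs-somatosensory enrichment after dilution by
#' the other 53 gustatory cells, which is what makes the fold-threshold
#' sweep (2/5/10) land on identical sub-clusters; it also matches the
#' dynamic range of the study's exemplar markers (tens to ~1000 FPKM).  A
#' fraction of T2 markers is additionally expressed in the somatosensory
#' class at a reduced level (the Mafb pattern).  The two outlier cells
#' carry gustatory major markers but no sub-cluster markers, plus private
#' high shifts on their own disjoint gene sets.
#'
#' @param n_genes number of background + planted genes (panel genes P2rx2,
#'   P2rx3, Htr3a, Gabra1 are appended on top).
#' @param group_sizes named integer vector of cells per planted group.
#' @param n_markers_per_group sub-cluster markers per T group.
#' @param n_major_markers major-class markers per major class.
#' @param marker_log2_shift in-group minus out-group log2 level for
#'   sub-cluster markers.
#' @param major_log2_level in-class log2 level of major markers.
#' @param major_log2_shift in-class minus out-class log2 level of major
#'   markers.
#' @param marker_base_log2 out-group log2 level of sub-cluster markers.
#' @param baseline_log2_mean_sd length-2 vector: mean and sd of the
#'   per-gene baseline log2-FPKM prior.
#' @param cell_noise_log2_sd per-cell multiplicative noise, log2 scale.
#' @param dropout_rate dropout probability for values below
#'   `dropout_threshold_fpkm`.
#' @param dropout_threshold_fpkm FPKM below which dropout can occur.
#' @param t2_shared_fraction fraction of T2 markers also elevated in the
#'   somatosensory class.
#' @param t2_shared_reduction_log2 how much lower (log2) the shared T2
#'   markers sit in the somatosensory class than in T2.
#' @param n_outlier_private private genes per outlier cell.
#' @param outlier_log2_shift private shift for outlier genes.
#' @param seed RNG seed; the generator is fully reproducible from it.
#' @return An object of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes = 17000,
                                  group_sizes = c(somatosensory = 37,
                                                  T1 = 33, T2 = 6, T3 = 18,
                                                  outlier = 2),
                                  n_markers_per_group = 25,
                                  n_major_markers = 60,
                                  marker_log2_shift = 7,
                                  major_log2_level = 9,
                                  major_log2_shift = 4,
                                  marker_base_log2 = 1,
                                  baseline_log2_mean_sd = c(3, 2),
                                  cell_noise_log2_sd = 1,
                                  dropout_rate = 0.3,
                                  dropout_threshold_fpkm = 0.5,
                                  t2_shared_fraction = 0.3,
                                  t2_shared_reduction_log2 = 3,
                                  n_outlier_private = 30,
                                  outlier_log2_shift = 10,
                                  seed = 1L) {
  stopifnot(all(c("somatosensory", "T1", "T2", "T3", "outlier") %in%
                  names(group_sizes)),
            all(group_sizes >= 0), n_genes > 0,
            dropout_rate >= 0, dropout_rate <= 1,
            is.finite(marker_log2_shift), is.finite(major_log2_shift),
            length(baseline_log2_mean_sd) == 2)
  structure(as.list(environment()), class = "expression_sim_config")
}

#' Simulate an expression matrix with planted ground truth
#'
#' See [expression_sim_config()] for the generative model.  Cells are laid
#' out grouped (somatosensory, T1, T2, T3, outliers); every downstream
#' stage is invariant to cell order, which the test-suite verifies by
#' permutation.
#'
#' @param config an [expression_sim_config()].
#' @return List with `matrix` (an [expression_matrix()] carrying the true
#'   sub-group labels) and `truth` (cell labels, major split, marker gene
#'   sets with planted shifts, panel genes, config).
#' @export
simulate_expression <- function(config = expression_sim_config()) {
  stopifnot(inherits(config, "expression_sim_config"))
  cf <- config
  set.seed(cf$seed)
  gs <- cf$group_sizes
  n_cells <- sum(gs)
  width <- max(2, nchar(as.character(n_cells)))
  cell_ids <- sprintf(paste0("cell_%0", width, "d"), seq_len(n_cells))
  cell_group <- rep(names(gs), gs)
  names(cell_group) <- cell_ids
  gustatory <- cell_group %in% c("T1", "T2", "T3", "outlier")

  gene_ids <- sprintf("gene%05d", seq_len(cf$n_genes))
  base <- rnorm(cf$n_genes, cf$baseline_log2_mean_sd[1],
                cf$baseline_log2_mean_sd[2])
  # log2-level matrix, genes x cells
  L <- matrix(base, cf$n_genes, n_cells)

  n_special <- 2 * cf$n_major_markers + 3 * cf$n_markers_per_group +
    gs[["outlier"]] * cf$n_outlier_private
  if (n_special > cf$n_genes)
    stop("n_genes too small for the requested marker structure")
  special <- sample.int(cf$n_genes, n_special)
  take <- function(n) {
    idx <- special[seq_len(n)]
    special <<- special[-seq_len(n)]
    idx
  }
  markers <- list()
  shifts <- c(gustatory = cf$major_log2_shift,
              somatosensory = cf$major_log2_shift,
              T1 = cf$marker_log2_shift, T2 = cf$marker_log2_shift,
              T3 = cf$marker_log2_shift)

  # major-class markers: high in-class, major_log2_shift lower out-of-class
  for (cls in c("gustatory", "somatosensory")) {
    idx <- take(cf$n_major_markers)
    inside <- if (cls == "gustatory") gustatory else !gustatory
    L[idx, ] <- cf$major_log2_level - cf$major_log2_shift
    L[idx, inside] <- cf$major_log2_level
    markers[[cls]] <- gene_ids[idx]
  }
  # sub-cluster markers: low everywhere, shifted up in their sub-cluster
  t2_shared <- character(0)
  for (grp in c("T1", "T2", "T3")) {
    idx <- take(cf$n_markers_per_group)
    L[idx, ] <- cf$marker_base_log2
    L[idx, cell_group == grp] <- cf$marker_base_log2 + cf$marker_log2_shift
    if (grp == "T2" && cf$t2_shared_fraction > 0) {
      nsh <- round(cf$t2_shared_fraction * length(idx))
      if (nsh > 0) {
        sh <- idx[seq_len(nsh)]
        L[sh, !gustatory] <- cf$marker_base_log2 + cf$marker_log2_shift -
          cf$t2_shared_reduction_log2
        t2_shared <- gene_ids[sh]
      }
    }
    markers[[grp]] <- gene_ids[idx]
  }
  # outlier private genes: high in exactly one cell
  out_cols <- which(cell_group == "outlier")
  out_cells <- cell_ids[out_cols]
  for (i in seq_along(out_cols)) {
    idx <- take(cf$n_outlier_private)
    L[idx, ] <- cf$marker_base_log2
    L[idx, out_cols[i]] <- cf$marker_base_log2 + cf$outlier_log2_shift
    markers[[paste0("outlier_", i)]] <- gene_ids[idx]
    shifts[paste0("outlier_", i)] <- cf$outlier_log2_shift
  }

  # neurotransmitter-receptor panel genes, appended by symbol
  hi <- 8; lo <- -2
  panel <- rbind(
    P2rx2 = ifelse(cell_group %in% c("T1", "T3", "outlier"), hi, lo),
    P2rx3 = ifelse(gustatory, hi, lo),
    Htr3a = ifelse(cell_group %in% c("T2", "T3"), hi, lo),
    Gabra1 = rep(6, n_cells))
  L <- rbind(L, panel)
  gene_ids <- c(gene_ids, rownames(panel))

  noise <- matrix(rnorm(length(L), 0, cf$cell_noise_log2_sd),
                  nrow(L), ncol(L))
  fpkm <- 2^(L + noise)
  if (cf$dropout_rate > 0) {
    low <- fpkm < cf$dropout_threshold_fpkm
    drop <- low & (matrix(runif(length(fpkm)), nrow(fpkm)) < cf$dropout_rate)
    fpkm[drop] <- 0
  }
  rownames(fpkm) <- gene_ids
  colnames(fpkm) <- cell_ids

  major <- ifelse(gustatory, "gustatory", "somatosensory")
  names(major) <- cell_ids
  truth <- list(cell_labels = cell_group, major_split = major,
                marker_genes = markers, marker_shifts = shifts,
                t2_shared_markers = t2_shared,
                panel_genes = rownames(panel), config = cf)
  list(matrix = expression_matrix(fpkm, cell_labels = cell_group),
       truth = truth)
}
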