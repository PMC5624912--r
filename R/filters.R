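#' Gene-filter settings
#'
#' Bundles the thresholds of the second-level ("taste-selective") gene filter:
#' a gene is kept when it is (i) detected in at least `min_cells_detected`
#' in-group cells (detection = FPKM strictly above `detect_threshold_fpkm`,
#' default 0, the weakest reading of "expression in at least 2 neurons"),
#' (ii) expressed at in-group mean FPKM of at least `min_mean_fpkm`, and
#' (iii) enriched in-group by at least `min_fold`, with a small pseudocount
#' added to both group means so the ratio is defined when the out-group mean
#' is zero.
#'
#' @param min_mean_fpkm minimum in-group mean FPKM (default 1).
#' @param min_cells_detected minimum number of in-group cells with detectable
#'   expression (default 2).
#' @param detect_threshold_fpkm detection cut-off; a cell counts as detecting
#'   a gene when FPKM > this value (default 0).
#' @param min_fold minimum (in mean + eps) / (out mean + eps) ratio
#'   (default 5).
#' @param pseudocount eps added to both means before the ratio (default 0.01,
#'   far below FPKM = 1 so it cannot demote a truly selective gene).
#' @param scope bookkeeping tag: `"all_cells"`, `"group"` or
#'   `"group_vs_rest"`.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(min_mean_fpkm = 1, min_cells_detected = 2,
                        detect_threshold_fpkm = 0, min_fold = 5,
                        pseudocount = 0.01,
                        scope = c("group_vs_rest", "group", "all_cells")) {
  scope <- match.arg(scope)
  stopifnot(pseudocount > 0, is.finite(min_mean_fpkm), is.finite(min_fold),
            min_mean_fpkm >= 0, min_fold >= 0, min_cells_detected >= 0,
            detect_threshold_fpkm >= 0)
  structure(list(min_mean_fpkm = min_mean_fpkm,
                 min_cells_detected = as.integer(min_cells_detected),
                 detect_threshold_fpkm = detect_threshold_fpkm,
                 min_fold = min_fold, pseudocount = pseudocount,
                 scope = scope),
            class = "filter_spec")
}

#' Select highly expressed genes
#'
#' Keeps genes whose mean FPKM across all cells meets the threshold
#' (inclusive); the first-level clustering of the geniculate data set keeps
#' genes averaging 200 FPKM or higher across all 96 cells.
#'
#' @param mat an [expression_matrix()].
#' @param min_mean_fpkm inclusive mean-FPKM threshold.
#' @return Character vector of gene ids (matrix order), possibly empty.
#' @export
filter_high_expression <- function(mat, min_mean_fpkm) {
  stopifnot(inherits(mat, "expression_matrix"), length(mat$cell_ids) > 0)
  mat$gene_ids[rowMeans(mat$values) >= min_mean_fpkm]
}

#' Select group-selective genes
#'
#' The three-criterion filter used to pick taste-selective genes for
#' second-level clustering: detection in enough in-group cells, sufficient
#' in-group mean expression, and in/out fold enrichment (see
#' [filter_spec()]).  Ratios are computed on means of raw FPKM.
#'
#' @param mat an [expression_matrix()].
#' @param in_group,out_group disjoint, non-empty sets of cell ids.
#' @param spec a [filter_spec()].
#' @return Character vector of gene ids passing all three criteria.
#' @export
filter_group_selective <- function(mat, in_group, out_group,
                                   spec = filter_spec()) {
  stopifnot(inherits(mat, "expression_matrix"),
            inherits(spec, "filter_spec"),
            length(in_group) > 0, length(out_group) > 0)
  if (length(intersect(in_group, out_group)))
    stop("in_group and out_group overlap: ",
         paste(utils::head(intersect(in_group, out_group), 5),
               collapse = ", "))
  .check_cells(mat, c(in_group, out_group))
  vin <- mat$values[, in_group, drop = FALSE]
  vout <- mat$values[, out_group, drop = FALSE]
  n_det <- rowSums(vin > spec$detect_threshold_fpkm)
  in_mean <- rowMeans(vin)
  out_mean <- rowMeans(vout)
  keep <- n_det >= spec$min_cells_detected &
    in_mean >= spec$min_mean_fpkm &
    (in_mean + spec$pseudocount) / (out_mean + spec$pseudocount) >=
      spec$min_fold
  mat$gene_ids[keep]
}

#' Select genes detected in a minimum number of cells
#'
#' Detection filter with both threshold dialects: `strict = FALSE` keeps a
#' gene when FPKM >= `min_fpkm` in at least `min_cells` of the given cells
#' (the "FPKM >= 10 in at least 3 taste neurons" filter); `strict = TRUE`
#' requires FPKM > `min_fpkm` (the "FPKM > 10 in at least 3 neurons"
#' variant).
#'
#' @param mat an [expression_matrix()].
#' @param cells cell ids to consider.
#' @param min_fpkm detection threshold.
#' @param min_cells minimum number of detecting cells.
#' @param strict use strict inequality for detection.
#' @return Character vector of gene ids.
#' @export
filter_detected <- function(mat, cells = mat$cell_ids, min_fpkm, min_cells,
                            strict = FALSE) {
  stopifnot(inherits(mat, "expression_matrix"))
  .check_cells(mat, cells)
  if (min_cells > length(cells))
    stop("min_cells (", min_cells, ") exceeds number of cells (",
         length(cells), ")")
  v <- mat$values[, cells, drop = FALSE]
  n <- if (strict) rowSums(v > min_fpkm) else rowSums(v >= min_fpkm)
  mat$gene_ids[n >= min_cells]
}

#' Restrict a matrix to a gene list, then filter by mean expression
#'
#' Intersects a curated list (e.g. merged transcription-factor databases)
#' with the genes present in the matrix and keeps those whose mean FPKM over
#' the given cells meets the threshold — the step that reduced 2407 listed
#' TFs to the 976 expressed in gustatory neurons.
#'
#' @param mat an [expression_matrix()].
#' @param genes a [load_gene_list()] result or character vector of symbols.
#' @param cells cell ids over which the mean is taken (default: all).
#' @param min_mean_fpkm inclusive mean threshold (default 1).
#' @return Character vector of gene ids (matrix order).
#' @export
restrict_to_list <- function(mat, genes, cells = mat$cell_ids,
                             min_mean_fpkm = 1) {
  stopifnot(inherits(mat, "expression_matrix"))
  .check_cells(mat, cells)
  syms <- if (inherits(genes, "gene_list")) genes$symbols else
    as.character(genes)
  present <- intersect(mat$gene_ids, syms)
  absent <- length(syms) - length(present)
  if (absent > 0)
    message(absent, " listed symbol(s) absent from the matrix")
  if (!length(present)) {
    warning("no listed gene present in the matrix")
    return(character(0))
  }
  means <- rowMeans(mat$values[present, cells, drop = FALSE])
  present[means >= min_mean_fpkm]
}
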