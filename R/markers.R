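#' Rank cluster-selective marker genes
#'
#' Candidate markers for one cluster are the genes passing the
#' group-selective filter (cluster vs. all other assigned cells); they are
#' ranked by `log2(fold) * fraction detected in-cluster`, a score monotone
#' in both selectivity and prevalence, so the exemplars at the top are both
#' strongly enriched and consistently expressed.  Fold uses the filter's
#' pseudocount.  Score ties are broken alphabetically by gene id.
#'
#' @param mat an [expression_matrix()].
#' @param assign a `cluster_assignment` over (a subset of) the matrix cells.
#' @param cluster cluster label to rank markers for.
#' @param spec a [filter_spec()].
#' @return A `data.frame` (class `marker_table`) with columns `gene_id`,
#'   `in_mean_fpkm`, `out_mean_fpkm`, `fold`, `fraction_detected_in`,
#'   `fraction_detected_out`, `score`, sorted by decreasing score.
#' @export
rank_markers <- function(mat, assign, cluster, spec = filter_spec()) {
  stopifnot(inherits(mat, "expression_matrix"))
  assign <- unclass(assign)
  in_cells <- names(assign)[assign == cluster]
  if (!length(in_cells))
    stop("cluster '", cluster, "' not present in the assignment")
  if (length(in_cells) < 2)
    stop("cluster '", cluster, "' has fewer than 2 cells")
  out_cells <- names(assign)[assign != cluster & assign != "unassigned"]
  if (!length(out_cells)) stop("no out-group cells to compare against")
  genes <- filter_group_selective(mat, in_cells, out_cells, spec)
  vin <- mat$values[genes, in_cells, drop = FALSE]
  vout <- mat$values[genes, out_cells, drop = FALSE]
  in_mean <- rowMeans(vin)
  out_mean <- rowMeans(vout)
  fold <- (in_mean + spec$pseudocount) / (out_mean + spec$pseudocount)
  fin <- rowMeans(vin > spec$detect_threshold_fpkm)
  fout <- rowMeans(vout > spec$detect_threshold_fpkm)
  score <- log2(fold) * fin
  ord <- order(-score, genes)
  structure(data.frame(gene_id = genes, in_mean_fpkm = in_mean,
                       out_mean_fpkm = out_mean, fold = fold,
                       fraction_detected_in = fin,
                       fraction_detected_out = fout, score = score,
                       row.names = NULL,
                       stringsAsFactors = FALSE)[ord, , drop = FALSE],
            class = c("marker_table", "data.frame"))
}

#' Call marker presence from an FPKM value
#'
#' @param fpkm FPKM value(s).
#' @param threshold inclusive presence threshold; the default of 20 FPKM is
#'   the level at which Htr3a expression was called "significant", use 1 for
#'   ordinary markers.
#' @return Character vector, `"present"` or `"absent"`.
#' @export
call_marker_presence <- function(fpkm, threshold = 20) {
  stopifnot(threshold >= 0)
  ifelse(fpkm >= threshold, "present", "absent")
}

#' Default marker-panel rules
#'
#' The post-hoc rules mapping a P2rx2 / P2rx3 / Htr3a presence profile to a
#' transcriptomic class: cells lacking both ATP receptors are somatosensory;
#' P2rx3 without P2rx2 marks sub-cluster T2; P2rx2 without Htr3a marks T1;
#' P2rx2 with Htr3a could be either T1 or T3 (the panel cannot separate
#' them, so the joint label `"T1-or-T3"` is deliberate); anything else is
#' `"ambiguous"`.
#'
#' @return An object of class `panel_rule`: ordered list of rules, each with
#'   `require_present`, `require_absent`, `label`; first match wins.
#' @export
default_panel_rules <- function() {
  panel_rules(list(
    list(require_present = character(0),
         require_absent = c("P2rx2", "P2rx3"), label = "somatosensory"),
    list(require_present = "P2rx3",
         require_absent = "P2rx2", label = "T2"),
    list(require_present = "P2rx2",
         require_absent = "Htr3a", label = "T1"),
    list(require_present = c("P2rx2", "Htr3a"),
         require_absent = character(0), label = "T1-or-T3")
  ))
}

#' Build an ordered marker-panel rule set
#'
#' @param rules list of rules (`require_present`, `require_absent`,
#'   `label`); evaluated in order, first match wins, with an implicit
#'   terminal catch-all yielding `"ambiguous"`.
#' @return A `panel_rule` object.
#' @export
panel_rules <- function(rules) {
  for (r in rules) {
    if (is.null(r$label)) stop("every rule needs a label")
  }
  structure(rules, class = "panel_rule")
}

#' Classify a cell from marker presence calls
#'
#' Pure function: identical calls always yield the identical label.
#'
#' @param calls named character vector of `"present"` / `"absent"` covering
#'   every gene referenced by the rules.
#' @param rules a [panel_rules()] object (default [default_panel_rules()]).
#' @return The first matching rule's label, or `"ambiguous"`.
#' @export
classify_by_panel <- function(calls, rules = default_panel_rules()) {
  stopifnot(inherits(rules, "panel_rule"))
  needed <- unique(unlist(lapply(rules, function(r)
    c(r$require_present, r$require_absent))))
  miss <- setdiff(needed, names(calls))
  if (length(miss))
    stop("missing presence call(s) for: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(calls), c("present", "absent"))
  if (length(bad)) stop("calls must be 'present' or 'absent'")
  for (r in rules) {
    if (all(calls[r$require_present] == "present") &&
        all(calls[r$require_absent] == "absent"))
      return(r$label)
  }
  "ambiguous"
}

#' Classify every cell of a matrix by a marker panel
#'
#' Convenience wrapper: presence calls are made per cell with a per-gene
#' threshold (default FPKM >= 20 for Htr3a, >= 1 otherwise), then
#' [classify_by_panel()] is applied.
#'
#' @param mat an [expression_matrix()] containing the panel genes.
#' @param rules a [panel_rules()] object.
#' @param thresholds named numeric vector of presence thresholds per panel
#'   gene; genes not named get `default_threshold`.
#' @param default_threshold fallback presence threshold (FPKM, default 1).
#' @return A `cluster_assignment` of panel labels.
#' @export
classify_cells_by_panel <- function(mat, rules = default_panel_rules(),
                                    thresholds = c(Htr3a = 20),
                                    default_threshold = 1) {
  stopifnot(inherits(mat, "expression_matrix"))
  genes <- unique(unlist(lapply(rules, function(r)
    c(r$require_present, r$require_absent))))
  miss <- setdiff(genes, mat$gene_ids)
  if (length(miss))
    stop("panel gene(s) absent from matrix: ", paste(miss, collapse = ", "))
  thr <- setNames(rep(default_threshold, length(genes)), genes)
  thr[intersect(names(thresholds), genes)] <-
    thresholds[intersect(names(thresholds), genes)]
  labs <- vapply(mat$cell_ids, function(cell) {
    calls <- call_marker_presence(mat$values[genes, cell], thr[genes])
    classify_by_panel(setNames(calls, genes), rules)
  }, character(1))
  cluster_assignment(labs)
}

#' Extract a log2 heat-map submatrix
#'
#' Returns `log2(FPKM + 1)` for the requested genes and cells, in exactly
#' the requested order, ready for rendering (e.g. `pheatmap` or `image`).
#'
#' @param mat an [expression_matrix()].
#' @param genes ordered gene ids.
#' @param cell_order ordered cell ids (default: stored order).
#' @return Numeric matrix of log2(FPKM + 1), rows = `genes`, columns =
#'   `cell_order`.
#' @export
heatmap_matrix <- function(mat, genes, cell_order = mat$cell_ids) {
  stopifnot(inherits(mat, "expression_matrix"))
  miss <- setdiff(genes, mat$gene_ids)
  if (length(miss))
    stop("unknown gene id(s): ", paste(utils::head(miss, 5), collapse = ", "))
  .check_cells(mat, cell_order)
  log2(mat$values[genes, cell_order, drop = FALSE] + 1)
}
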