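#' Pipeline run configuration
#'
#' All inputs and thresholds for the two end-to-end workflows.  Inputs may
#' be file paths (read with the package readers) or in-memory objects.
#' Serializable to JSON via [write_run_config()] / [read_run_config()];
#' unknown keys are rejected on construction and on load.
#'
#' @param matrix expression matrix: path or [expression_matrix()].
#' @param labels optional cell labels: path or named vector.
#' @param tf_lists optional transcription-factor list file path(s).
#' @param traces calcium traces: path or list of [calcium_trace()]s.
#' @param schedule stimulus schedule: path or [stimulus_schedule()].
#' @param level1_min_mean_fpkm first-level high-expression threshold
#'   (default 200 FPKM).
#' @param level1_k,level1_min_cluster_size first-level cut parameters.
#' @param level2_min_mean_fpkm,level2_min_cells_detected,level2_detect_threshold_fpkm,level2_min_fold,level2_pseudocount
#'   second-level selective-filter thresholds (see [filter_spec()]).
#' @param level2_k,level2_min_cluster_size second-level cut parameters
#'   (default: 3 sub-clusters of at least 3 cells; the cut deepens until 3
#'   such clusters exist, smaller branches become `"unassigned"`).
#' @param target_cluster second-level target cluster name; `NULL` picks
#'   the larger first-level cluster.
#' @param pca_detect_min_fpkm,pca_detect_min_cells detection filter for
#'   the second-level PCA gene set (default FPKM >= 10 in >= 3 cells).
#' @param drift_tolerance calcium QC baseline tolerance.
#' @param calcium_k number of functional response groups.
#' @param frame_period_s calcium frame period.
#' @param seed seed recorded in reports (the pipeline itself is
#'   deterministic).
#' @param out_dir optional output directory for result files.
#' @return An object of class `run_config`.
#' @export
run_config <- function(matrix = NULL, labels = NULL, tf_lists = NULL,
                       traces = NULL, schedule = NULL,
                       level1_min_mean_fpkm = 200, level1_k = 2,
                       level1_min_cluster_size = 1,
                       level2_min_mean_fpkm = 1,
                       level2_min_cells_detected = 2,
                       level2_detect_threshold_fpkm = 0,
                       level2_min_fold = 5, level2_pseudocount = 0.01,
                       level2_k = 3, level2_min_cluster_size = 3,
                       target_cluster = NULL,
                       pca_detect_min_fpkm = 10, pca_detect_min_cells = 3,
                       drift_tolerance = 0.1, calcium_k = 4,
                       frame_period_s = 1.5, seed = 1L, out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file of configuration keys; unknown keys are an error.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown))
    stop("unknown run_config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Write a run configuration to JSON
#'
#' Only serializable (non-object) fields are written; in-memory inputs
#' must be re-supplied on load.
#'
#' @param config a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- Filter(function(x) is.null(x) || is.atomic(x), unclass(config))
  writeLines(as.character(jsonlite::toJSON(plain, auto_unbox = TRUE,
                                           digits = NA, null = "null")),
             path)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

.level2_spec <- function(config) {
  filter_spec(min_mean_fpkm = config$level2_min_mean_fpkm,
              min_cells_detected = config$level2_min_cells_detected,
              detect_threshold_fpkm = config$level2_detect_threshold_fpkm,
              min_fold = config$level2_min_fold,
              pseudocount = config$level2_pseudocount)
}

#' Run the two-level transcriptome classification workflow
#'
#' First level: high-expression gene filter, Pearson/UPGMA clustering of
#' all cells, k-group cut, and a PCA concordance check over all detected
#' genes.  Second level: the larger first-level cluster (or
#' `target_cluster`) is re-clustered on group-selective genes, cut into
#' sub-clusters with small branches unassigned, cross-checked by PCA on a
#' detection-filtered gene set (and on a transcription-factor list when
#' supplied), and per-sub-cluster marker tables are ranked.
#'
#' @param config a [run_config()] with at least `matrix` set.
#' @return List with `report` (all counts, sizes and ARIs, plus config
#'   hash, seed and package version), `level1` / `level2` result bundles
#'   (assignment, tree, pca, concordance), and `markers` (per sub-cluster
#'   [rank_markers()] tables).  When `out_dir` is set, assignments, gene
#'   sets, Newick trees, PCA scores, marker tables and `report.json` are
#'   also written there.
#' @export
run_transcriptome <- function(config) {
  stopifnot(inherits(config, "run_config"))
  mat <- .stage("read", {
    m <- config$matrix
    if (is.null(m)) stop("no matrix supplied")
    if (is.character(m)) m <- read_expression_matrix(m)
    if (!inherits(m, "expression_matrix")) stop("matrix is not readable")
    if (length(m$gene_ids) == 0 || length(m$cell_ids) == 0)
      stop("matrix is empty")
    if (!is.null(config$labels)) {
      lab <- config$labels
      if (is.character(lab) && length(lab) == 1 && file.exists(lab))
        lab <- read_labels(lab)
      m <- attach_labels(m, lab)
    }
    m
  })

  genes1 <- .stage("level1_filter",
                   filter_high_expression(mat, config$level1_min_mean_fpkm))
  l1 <- .stage("level1_cluster", {
    tree <- upgma(pcc_distance(pairwise_pcc(mat, genes1)),
                  labels = mat$cell_ids)
    assign <- cut_tree(tree, config$level1_k, config$level1_min_cluster_size)
    list(tree = tree, assignment = assign)
  })
  detected <- .stage("level1_pca_filter",
                     filter_detected(mat, mat$cell_ids, min_fpkm = 0,
                                     min_cells = 1, strict = TRUE))
  l1$pca <- .stage("level1_pca", run_pca(mat, detected, 2))
  l1$concordance <- .stage("level1_concordance",
                           concordance_report(l1$assignment, l1$pca,
                                              config$level1_k))

  target <- config$target_cluster
  if (is.null(target)) target <- "C1"      # clusters are size-named
  a1 <- unclass(l1$assignment)
  in_cells <- names(a1)[a1 == target]
  out_cells <- names(a1)[a1 != target & a1 != "unassigned"]
  if (!length(in_cells))
    stop("stage 'level2_select': target cluster '", target, "' is empty")

  genes2 <- .stage("level2_filter",
                   filter_group_selective(mat, in_cells, out_cells,
                                          .level2_spec(config)))
  sub <- subset_matrix(mat, cells = in_cells)
  l2 <- .stage("level2_cluster", {
    tree <- upgma(pcc_distance(pairwise_pcc(sub, genes2)),
                  labels = sub$cell_ids)
    assign <- cut_tree(tree, config$level2_k, config$level2_min_cluster_size)
    list(tree = tree, assignment = assign)
  })
  pca2_genes <- .stage("level2_pca_filter",
                       filter_detected(mat, in_cells,
                                       config$pca_detect_min_fpkm,
                                       config$pca_detect_min_cells))
  l2$pca <- .stage("level2_pca", run_pca(sub, pca2_genes, 2))
  l2$concordance <- .stage("level2_concordance",
                           concordance_report(l2$assignment, l2$pca,
                                              config$level2_k))

  tf <- NULL
  if (!is.null(config$tf_lists)) {
    tf <- .stage("tf_pca", {
      lst <- load_gene_list(config$tf_lists)
      keep <- restrict_to_list(mat, lst, in_cells, min_mean_fpkm = 1)
      list(n_listed = length(lst$symbols), n_used = length(keep),
           genes = keep,
           pca = if (length(keep) >= 2) run_pca(sub, keep, 2) else NULL)
    })
  }

  a2 <- unclass(l2$assignment)
  markers <- .stage("markers", {
    labs <- setdiff(unique(a2), "unassigned")
    setNames(lapply(labs, function(lb)
      rank_markers(sub, l2$assignment, lb, .level2_spec(config))), labs)
  })

  report <- list(
    n_genes = length(mat$gene_ids), n_cells = length(mat$cell_ids),
    n_genes_detected = length(detected),
    level1 = list(n_genes = length(genes1),
                  cluster_sizes = as.list(table(a1)),
                  pca_concordance_ari = l1$concordance$ari),
    level2 = list(target_cluster = target, n_cells = length(in_cells),
                  n_genes = length(genes2),
                  cluster_sizes = as.list(table(a2)),
                  n_unassigned = sum(a2 == "unassigned"),
                  pca_concordance_ari = l2$concordance$ari),
    tf = if (!is.null(tf)) list(n_listed = tf$n_listed,
                                n_used = tf$n_used),
    config_hash = .object_hash(Filter(is.atomic, unclass(config))),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("gangliotype")))

  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    dir.create(od, showWarnings = FALSE, recursive = TRUE)
    write_labels(c(a1[setdiff(names(a1), names(a2))], a2),
                 file.path(od, "assignments.csv"))
    writeLines(genes1, file.path(od, "genes_level1.txt"))
    writeLines(genes2, file.path(od, "genes_level2.txt"))
    write_newick(l1$tree, file.path(od, "tree_level1.nwk"))
    write_newick(l2$tree, file.path(od, "tree_level2.nwk"))
    write.table(data.frame(cell_id = rownames(l1$pca$scores),
                           l1$pca$scores, check.names = FALSE),
                file.path(od, "pca_scores.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    for (lb in names(markers))
      write.table(markers[[lb]], file.path(od,
                                           paste0("markers_", lb, ".csv")),
                  sep = ",", quote = FALSE, row.names = FALSE)
    writeLines(as.character(jsonlite::toJSON(report, auto_unbox = TRUE,
                                             digits = NA, pretty = TRUE,
                                             null = "null")),
               file.path(od, "report.json"))
  }
  list(report = report, level1 = l1, level2 = l2, tf = tf,
       markers = markers)
}

#' Run the calcium-imaging scoring workflow
#'
#' Scores every trace over the two-block protocol, applies health QC and
#' the replicate-consistency requirement, clusters the passing cells by
#' functional profile, and reports QC pass counts and cluster sizes.
#'
#' @param config a [run_config()] with `traces` and `schedule` set.
#' @return List with `report`, the full `response_table`, and the
#'   functional `assignment` over included cells.  When `out_dir` is set,
#'   `response_table.csv`, `functional_clusters.csv` and
#'   `calcium_report.json` are written there.
#' @export
run_calcium <- function(config) {
  stopifnot(inherits(config, "run_config"))
  traces <- .stage("read_traces", {
    tr <- config$traces
    if (is.null(tr)) stop("no traces supplied")
    if (is.character(tr)) tr <- read_traces_csv(tr, config$frame_period_s)
    tr
  })
  schedule <- .stage("read_schedule", {
    s <- config$schedule
    if (is.null(s)) stop("no schedule supplied")
    if (is.character(s)) s <- read_schedule_csv(s)
    if (!any(s$name == "KCl")) stop("no KCl event in schedule")
    s
  })
  table <- .stage("score", summarize_cells(traces, schedule,
                                           config$drift_tolerance))
  include <- table$qc_pass & table$consistent
  assign <- .stage("cluster",
                   cluster_responses(table[include, , drop = FALSE],
                                     config$calcium_k))
  report <- list(
    n_cells = nrow(table), n_qc_pass = sum(table$qc_pass),
    n_consistent = sum(table$consistent), n_clustered = sum(include),
    cluster_sizes = as.list(table(unclass(assign))),
    config_hash = .object_hash(Filter(is.atomic, unclass(config))),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("gangliotype")))
  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    dir.create(od, showWarnings = FALSE, recursive = TRUE)
    write.table(table, file.path(od, "response_table.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    write_labels(unclass(assign), file.path(od, "functional_clusters.csv"))
    writeLines(as.character(jsonlite::toJSON(report, auto_unbox = TRUE,
                                             digits = NA, pretty = TRUE)),
               file.path(od, "calcium_report.json"))
  }
  list(report = report, response_table = table, assignment = assign)
}

#' Recompute the study's filter and cluster counts from a matrix
#'
#' Convenience helper for replication against a deposited FPKM matrix:
#' returns the number of detected genes, the high-expression (>= 200
#' FPKM) gene count, the taste-selective gene counts at fold thresholds
#' 2/5/10, the two detection-filter counts (FPKM >= 10 in >= 3 taste
#' cells; FPKM > 10 in >= 3 of all cells), the transcription-factor count
#' when lists are given, and the cluster sizes at both levels.
#'
#' @param mat an [expression_matrix()] (e.g. a deposited FPKM table read
#'   with [read_expression_matrix()]).
#' @param tf_lists optional transcription-factor list file paths.
#' @return Named list of counts and sizes.
#' @export
replicate_counts <- function(mat, tf_lists = NULL) {
  res <- run_transcriptome(run_config(matrix = mat, tf_lists = tf_lists))
  a1 <- unclass(res$level1$assignment)
  target_cells <- names(a1)[a1 == res$report$level2$target_cluster]
  folds <- vapply(c(2, 5, 10), function(f)
    length(filter_group_selective(mat, target_cells,
                                  names(a1)[a1 != res$report$level2$target_cluster],
                                  filter_spec(min_fold = f))), numeric(1))
  list(n_detected = res$report$n_genes_detected,
       n_high_200 = res$report$level1$n_genes,
       n_selective_fold2 = folds[1], n_selective_fold5 = folds[2],
       n_selective_fold10 = folds[3],
       n_detected_10_in_3_taste =
         length(filter_detected(mat, target_cells, 10, 3)),
       n_detected_gt10_in_3_all =
         length(filter_detected(mat, mat$cell_ids, 10, 3, strict = TRUE)),
       n_tf_used = if (!is.null(res$tf)) res$tf$n_used,
       level1_sizes = res$report$level1$cluster_sizes,
       level2_sizes = res$report$level2$cluster_sizes)
}
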