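# md5 of an R object via its canonical JSON serialization
.object_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                           digits = NA, force = TRUE)),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Write a complete synthetic fixture bundle
#'
#' Generates the default synthetic expression matrix and calcium
#' recordings and writes them, plus ground truth and a manifest, to a
#' directory: `matrix.tsv`, `labels.csv`, `truth.json`, `traces.csv`,
#' `schedule.csv`, `manifest.json`.  The manifest records the seed, a hash
#' of the configuration, and an md5 checksum for every written file, so a
#' bundle can be re-generated byte-identically and verified with
#' [verify_fixture_bundle()].
#'
#' @param outdir output directory (created if needed).
#' @param expr_config an [expression_sim_config()].
#' @param trace_args list of arguments for [simulate_traces()].
#' @return The manifest, invisibly.
#' @export
write_fixture_bundle <- function(outdir,
                                 expr_config = expression_sim_config(),
                                 trace_args = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_expression(expr_config)
  tr <- do.call(simulate_traces, trace_args)

  files <- c(matrix = "matrix.tsv", labels = "labels.csv",
             truth = "truth.json", traces = "traces.csv",
             schedule = "schedule.csv")
  paths <- file.path(outdir, files)
  names(paths) <- names(files)
  write_expression_matrix(sim$matrix, paths[["matrix"]], format = "tsv")
  write_labels(sim$truth$cell_labels, paths[["labels"]])
  truth_out <- sim$truth
  truth_out$config <- unclass(truth_out$config)
  truth_out$trace_truth <- tr$truth
  writeLines(as.character(jsonlite::toJSON(truth_out, auto_unbox = TRUE,
                                           digits = NA)),
             paths[["truth"]])
  write_traces_csv(tr$traces, paths[["traces"]])
  write_schedule_csv(tr$schedule, paths[["schedule"]])

  manifest <- list(
    seed = expr_config$seed,
    config_hash = .object_hash(list(expr = unclass(expr_config),
                                    traces = trace_args)),
    package_version = as.character(utils::packageVersion("gangliotype")),
    files = lapply(seq_along(paths), function(i)
      list(name = unname(files[i]),
           md5 = unname(tools::md5sum(paths[i])))))
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE)),
             file.path(outdir, "manifest.json"))
  invisible(manifest)
}

#' Verify a fixture bundle against its manifest
#'
#' @param dir bundle directory containing `manifest.json`.
#' @return `TRUE` when every checksum matches; otherwise an error naming
#'   the first mismatching or missing file.
#' @export
verify_fixture_bundle <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::fromJSON(mf, simplifyVector = FALSE)
  for (f in manifest$files) {
    p <- file.path(dir, f$name)
    if (!file.exists(p)) stop("bundle file missing: ", f$name)
    got <- unname(tools::md5sum(p))
    if (!identical(got, f$md5))
      stop("checksum mismatch for ", f$name, " (expected ", f$md5,
           ", got ", got, ")")
  }
  TRUE
}
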