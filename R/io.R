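#' Read an expression matrix from disk
#'
#' Supported layouts: delimited text (`tsv`/`csv`; first column gene ids,
#' first row cell ids, numeric body) and MatrixMarket triplets
#' (`mtx-triplet`; 1-based indices, with companion files `genes.txt` and
#' `cells.txt` next to the `.mtx` file, one identifier per line).  Row and
#' column order are preserved exactly as stored.
#'
#' @param path file path (for `mtx-triplet`, the `.mtx` file).
#' @param format one of `"tsv"`, `"csv"`, `"mtx-triplet"`; default guessed
#'   from the file extension.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, format = c("auto", "tsv", "csv",
                                                    "mtx-triplet")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", csv = "csv",
                     mtx = "mtx-triplet",
                     stop("cannot guess format from extension of ", path))
  }
  if (format == "mtx-triplet") {
    dir <- dirname(path)
    gfile <- file.path(dir, "genes.txt")
    cfile <- file.path(dir, "cells.txt")
    if (!file.exists(gfile)) stop("companion file not found: ", gfile)
    if (!file.exists(cfile)) stop("companion file not found: ", cfile)
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gfile)
    cells <- readLines(cfile)
    return(expression_matrix(m, gene_ids = genes, cell_ids = cells))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, row.names = NULL,
                   check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "")
  gene_ids <- as.character(df[[1]])
  body <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(body)) stop("non-numeric entries in matrix body of ", path)
  expression_matrix(body, gene_ids = gene_ids, cell_ids = colnames(df)[-1])
}

#' Write an expression matrix
#'
#' Inverse of [read_expression_matrix()]; `read(write(M)) == M` for every
#' supported format (MatrixMarket stores full double precision).
#'
#' @param mat an [expression_matrix()].
#' @param path output path (`.mtx` for the triplet format).
#' @param format as in [read_expression_matrix()].
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path,
                                    format = c("auto", "tsv", "csv",
                                               "mtx-triplet")) {
  stopifnot(inherits(mat, "expression_matrix"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", csv = "csv",
                     mtx = "mtx-triplet",
                     stop("cannot guess format from extension of ", path))
  }
  if (format == "mtx-triplet") {
    v <- mat$values
    nz <- which(v != 0)
    rows <- ((nz - 1) %% nrow(v)) + 1
    cols <- ((nz - 1) %/% nrow(v)) + 1
    con <- file(path, "w")
    writeLines(c("%%MatrixMarket matrix coordinate real general",
                 sprintf("%d %d %d", nrow(v), ncol(v), length(nz))), con)
    writeLines(sprintf("%d %d %.17g", rows, cols, v[nz]), con)
    close(con)
    writeLines(mat$gene_ids, file.path(dirname(path), "genes.txt"))
    writeLines(mat$cell_ids, file.path(dirname(path), "cells.txt"))
    return(invisible(path))
  }
  sep <- if (format == "tsv") "\t" else ","
  # %.17g keeps doubles exact across a write/read round trip
  body <- vapply(seq_len(nrow(mat$values)), function(i)
    paste(c(mat$gene_ids[i], sprintf("%.17g", mat$values[i, ])),
          collapse = sep), character(1))
  writeLines(c(paste(c("gene_id", mat$cell_ids), collapse = sep), body),
             path)
  invisible(path)
}

#' Load and merge gene lists
#'
#' Each file holds one gene symbol per line; blank lines and lines starting
#' with `#` are ignored.  Symbols are matched case-sensitively and the union
#' across files is deduplicated, mirroring the merge of transcription-factor
#' database lists.
#'
#' @param paths one or more file paths.
#' @param name name for the merged list (default: basename of first file).
#' @return An object of class `gene_list`: list with `name` and `symbols`.
#' @export
load_gene_list <- function(paths, name = NULL) {
  stopifnot(length(paths) >= 1)
  syms <- character(0)
  for (p in paths) {
    if (!file.exists(p)) stop("file not found: ", p)
    lines <- trimws(readLines(p))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    syms <- c(syms, lines)
  }
  syms <- unique(syms)
  if (!length(syms)) stop("gene list union is empty")
  message(sprintf("loaded %d unique symbols from %d file(s)",
                  length(syms), length(paths)))
  structure(list(name = if (is.null(name)) basename(paths[[1]]) else name,
                 symbols = syms),
            class = "gene_list")
}

#' @exportS3Method base::print
print.gene_list <- function(x, ...) {
  cat(sprintf("<gene_list> '%s': %d symbols\n", x$name, length(x$symbols)))
  invisible(x)
}

#' Read a two-column cell label file
#'
#' @param path CSV with header `cell_id,label`.
#' @return Named character vector of labels.
#' @export
read_labels <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Write cell labels to a two-column CSV
#'
#' @param labels named character vector (names = cell ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(cell_id = names(labels), label = unname(labels),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
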