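#' Construct an expression matrix
#'
#' The canonical container shared by all pipeline stages: a dense, non-negative
#' genes x cells matrix of FPKM values with unique gene and cell identifiers
#' and an optional per-cell label map.  FPKM (fragments per kilobase of exon
#' per million mapped reads) is already length- and depth-normalized, so no
#' further library-size normalization is applied anywhere in the package.
#'
#' @param values numeric matrix, rows = genes, columns = cells; no negative
#'   entries, no missing values.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   `rownames(values)`).
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   `colnames(values)`).
#' @param cell_labels optional named character vector mapping a subset of
#'   `cell_ids` to group labels.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `gene_ids`, `cell_ids`, `cell_labels`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              cell_labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene_ids and cell_ids are required (or set dimnames on 'values')")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length (", length(gene_ids), ") != number of rows (",
         nrow(values), ")")
  if (length(cell_ids) != ncol(values))
    stop("cell_ids length (", length(cell_ids), ") != number of columns (",
         ncol(values), ")")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stop("duplicate gene identifier(s): ", paste(unique(dup), collapse = ", "))
  dup <- cell_ids[duplicated(cell_ids)]
  if (length(dup))
    stop("duplicate cell identifier(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(values))
    stop("missing values are not permitted in an FPKM matrix")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative FPKM value %g at gene '%s', cell '%s'",
                 values[neg[1, 1], neg[1, 2]],
                 gene_ids[neg[1, 1]], cell_ids[neg[1, 2]]))
  dimnames(values) <- list(gene_ids, cell_ids)
  obj <- structure(list(values = values, gene_ids = gene_ids,
                        cell_ids = cell_ids, cell_labels = NULL),
                   class = "expression_matrix")
  if (!is.null(cell_labels)) obj <- attach_labels(obj, cell_labels)
  obj
}

#' @exportS3Method base::print
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d cells\n",
              length(x$gene_ids), length(x$cell_ids)))
  if (!is.null(x$cell_labels)) {
    tab <- table(x$cell_labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        sprintf("(%d unlabeled)\n",
                length(x$cell_ids) - length(x$cell_labels)))
  }
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Attach (or merge) cell labels
#'
#' Labels already present are kept unless overridden; when a label is
#' overwritten the change is reported via `message()` so silent relabeling
#' cannot occur (last write wins).
#'
#' @param mat an [expression_matrix()].
#' @param labels named character vector, names are cell ids.
#' @return The matrix with labels merged in.
#' @export
attach_labels <- function(mat, labels) {
  stopifnot(inherits(mat, "expression_matrix"))
  labels <- setNames(as.character(labels), names(labels))
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop("labels must be a named vector (names = cell ids)")
  unknown <- setdiff(names(labels), mat$cell_ids)
  if (length(unknown))
    stop("unknown cell id(s) in labels: ", paste(unknown, collapse = ", "))
  old <- mat$cell_labels
  if (!is.null(old)) {
    clash <- intersect(names(labels), names(old))
    changed <- clash[old[clash] != labels[clash]]
    if (length(changed))
      message("overriding label(s) for: ", paste(changed, collapse = ", "))
    old[names(labels)] <- labels
    labels <- old
  }
  mat$cell_labels <- labels[order(match(names(labels), mat$cell_ids))]
  mat
}

#' Subset an expression matrix by genes and/or cells
#'
#' @param mat an [expression_matrix()].
#' @param genes,cells identifiers to keep (default: all, in stored order).
#' @return An [expression_matrix()] restricted to the requested rows/columns.
#' @export
subset_matrix <- function(mat, genes = mat$gene_ids, cells = mat$cell_ids) {
  stopifnot(inherits(mat, "expression_matrix"))
  miss <- setdiff(genes, mat$gene_ids)
  if (length(miss))
    stop("unknown gene id(s): ", paste(utils::head(miss, 5), collapse = ", "))
  miss <- setdiff(cells, mat$cell_ids)
  if (length(miss))
    stop("unknown cell id(s): ", paste(utils::head(miss, 5), collapse = ", "))
  lab <- mat$cell_labels
  if (!is.null(lab)) lab <- lab[intersect(names(lab), cells)]
  expression_matrix(mat$values[genes, cells, drop = FALSE],
                    gene_ids = genes, cell_ids = cells,
                    cell_labels = if (length(lab)) lab else NULL)
}

.check_cells <- function(mat, cells) {
  miss <- setdiff(cells, mat$cell_ids)
  if (length(miss))
    stop("unknown cell id(s): ", paste(utils::head(miss, 5), collapse = ", "))
  invisible(TRUE)
}
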