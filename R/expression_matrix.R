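#' Construct an expression matrix (cells x genes)
#'
#' The shared container for all pipeline stages: a numeric cells-by-genes
#' matrix with ordered, unique cell and gene identifiers and a layer tag
#' recording which transform has been applied.  Matrices denser than 50%
#' are stored dense, sparser ones as `dgCMatrix`; every operation in the
#' package accepts either representation.
#'
#' @param values numeric matrix or `Matrix` sparse matrix, cells in rows.
#' @param cell_ids character vector of unique cell identifiers (rows).
#' @param gene_ids character vector of unique gene identifiers (columns).
#' @param layer one of `"raw_counts"`, `"normalized"`, `"standardized"`.
#'   The `raw_counts` layer must contain non-negative integer values.
#' @return an object of class `ExpressionMatrix`.
#' @export
ExpressionMatrix <- function(values, cell_ids = rownames(values),
                             gene_ids = colnames(values),
                             layer = c("raw_counts", "normalized", "standardized")) {
  layer <- match.arg(layer)
  if (is.null(cell_ids) || is.null(gene_ids))
    stop("cell_ids and gene_ids are required (or supply dimnames)")
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != length(cell_ids))
    stop("number of rows (", nrow(values), ") != number of cell_ids (",
         length(cell_ids), ")")
  if (ncol(values) != length(gene_ids))
    stop("number of columns (", ncol(values), ") != number of gene_ids (",
         length(gene_ids), ")")
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    stop("duplicate gene IDs: ", paste(head(dup_g, 10L), collapse = ", "))
  dup_c <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup_c))
    stop("duplicate cell IDs: ", paste(head(dup_c, 10L), collapse = ", "))
  if (min_value(values) < 0 && layer != "standardized")
    stop("negative entries are not allowed in layer '", layer, "'")
  if (layer == "raw_counts" && !all_integral(values))
    stop("raw_counts layer must contain integer values")
  values <- choose_storage(values)
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 layer = layer),
            class = "ExpressionMatrix")
}

# density-driven storage: sparse below 50% nonzeros
choose_storage <- function(values) {
  if (is(values, "sparseMatrix")) {
    values <- as(as(values, "CsparseMatrix"), "generalMatrix")
    dens <- Matrix::nnzero(values) / max(1, prod(dim(values)))
    if (dens >= 0.5) values <- as.matrix(values)
    return(values)
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dens <- sum(values != 0) / max(1, length(values))
  if (dens < 0.5) values <- as(as(Matrix::Matrix(values, sparse = TRUE),
                                  "CsparseMatrix"), "generalMatrix")
  values
}

min_value <- function(values) {
  if (is(values, "sparseMatrix")) {
    x <- values@x
    if (length(x) == 0) 0 else min(0, min(x))
  } else min(values)
}

all_integral <- function(values) {
  x <- if (is(values, "sparseMatrix")) values@x else as.numeric(values)
  length(x) == 0 || all(abs(x - round(x)) < 1e-8)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$layer,
              if (is(x$values, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

#' Dense numeric view of an expression matrix
#' @param m an `ExpressionMatrix`.
#' @return base numeric matrix with dimnames.
#' @export
as_dense <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  as.matrix(m$values)
}

# internal: replace values, keep ids, set layer
with_values <- function(m, values, layer) {
  ExpressionMatrix(values, m$cell_ids, m$gene_ids, layer = layer)
}

#' Construct a labeled reference atlas
#'
#' Couples a raw-count expression matrix with one categorical cell-state
#' label per cell.  The label vocabulary is the lexicographically sorted set
#' of observed states; its order fixes class indices throughout training.
#'
#' @param matrix an `ExpressionMatrix` with layer `raw_counts`.
#' @param labels character vector, one state label per cell, in matrix cell
#'   order.
#' @return an object of class `ReferenceAtlas`.
#' @export
ReferenceAtlas <- function(matrix, labels) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$layer != "raw_counts")
    stop("ReferenceAtlas requires a raw_counts matrix")
  labels <- as.character(labels)
  if (length(labels) != length(matrix$cell_ids))
    stop("need exactly one label per cell (", length(matrix$cell_ids),
         " cells, ", length(labels), " labels)")
  if (anyNA(labels)) stop("labels contain NA")
  vocab <- sort(unique(labels))
  structure(list(matrix = matrix, labels = labels,
                 label_vocabulary = vocab),
            class = "ReferenceAtlas")
}

#' @export
print.ReferenceAtlas <- function(x, ...) {
  cat(sprintf("ReferenceAtlas: %d cells x %d genes, %d states\n",
              nrow(x$matrix$values), ncol(x$matrix$values),
              length(x$label_vocabulary)))
  tab <- table(x$labels)
  cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)), collapse = "\n"),
      "\n")
  invisible(x)
}
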