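MODEL_FORMAT_VERSION <- "cellstateR-model-1"

#' Read an expression matrix from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`mtx`}{Matrix Market triplet file with co-located
#'     `features.tsv[.gz]` (or `genes.tsv[.gz]`) and `barcodes.tsv[.gz]`
#'     sidecars.  On-disk orientation is assumed genes x cells (the
#'     CellRanger convention) unless `cells_rows = TRUE`.}
#'   \item{`dense_tsv`}{delimited text, header row = gene IDs, first
#'     column = cell IDs.  Tab or comma separated (auto-detected).}
#'   \item{`h5sc`}{HDF5 single-cell container with an h5ad-compatible
#'     layout (`X`, `obs`, `var`); requires the `rhdf5` package.}
#' }
#' Whatever the on-disk orientation, the returned matrix is cells x genes
#' with `layer = "raw_counts"`; sparse inputs stay sparse.
#'
#' @param path file path.
#' @param format `"mtx"`, `"dense_tsv"` or `"h5sc"`.
#' @param cells_rows for `mtx` only: set `TRUE` if the file already stores
#'   cells in rows.
#' @return an [ExpressionMatrix].
#' @export
read_matrix <- function(path, format = c("mtx", "dense_tsv", "h5sc"),
                        cells_rows = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         mtx = read_mtx(path, cells_rows = cells_rows),
         dense_tsv = read_dense(path),
         h5sc = read_h5sc(path))
}

read_mtx <- function(path, cells_rows = FALSE) {
  header <- readLines(path, n = 1L)
  if (!grepl("^%%MatrixMarket[ \t]+matrix[ \t]+coordinate", header))
    stop("malformed MatrixMarket header at line 1: '", header, "'")
  m <- Matrix::readMM(path)
  if (!cells_rows) m <- Matrix::t(m)
  if (nrow(m) == 0L) stop("no cells: matrix '", path, "' has zero cells")
  if (ncol(m) == 0L) stop("no genes: matrix '", path, "' has zero genes")
  dir <- dirname(path)
  genes <- read_sidecar(dir, c("features.tsv", "features.tsv.gz",
                               "genes.tsv", "genes.tsv.gz"), "gene")
  cells <- read_sidecar(dir, c("barcodes.tsv", "barcodes.tsv.gz"), "barcode")
  if (length(genes) != ncol(m))
    stop("gene sidecar has ", length(genes), " entries but matrix has ",
         ncol(m), " genes")
  if (length(cells) != nrow(m))
    stop("barcode sidecar has ", length(cells), " entries but matrix has ",
         nrow(m), " cells")
  ExpressionMatrix(m, cells, genes, layer = "raw_counts")
}

read_sidecar <- function(dir, candidates, what) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) {
      tab <- data.table::fread(p, header = FALSE, sep = "\t",
                               colClasses = "character")
      return(tab[[1L]])
    }
  }
  stop("no ", what, " sidecar found next to the .mtx file (looked for ",
       paste(candidates, collapse = ", "), ")")
}

read_dense <- function(path) {
  tab <- data.table::fread(path, header = TRUE)
  cells <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (nrow(m) == 0L) stop("no cells: '", path, "' has zero data rows")
  ExpressionMatrix(m, cells, colnames(m), layer = "raw_counts")
}

read_h5sc <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("reading h5sc files requires the 'rhdf5' package")
  on.exit(rhdf5::H5close(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  x_entry <- contents[contents$group == "/" & contents$name == "X", ]
  if (nrow(x_entry) == 0L) stop("no 'X' entry in ", path)
  genes <- as.character(rhdf5::h5read(path, "var/_index"))
  cells <- as.character(rhdf5::h5read(path, "obs/_index"))
  if (x_entry$otype == "H5I_GROUP") {
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    # CSR over cells x genes (anndata convention)
    m <- Matrix::sparseMatrix(j = indices + 1L, p = indptr, x = data,
                              dims = c(length(cells), length(genes)))
  } else {
    # h5py writes C-order; h5read yields the transposed array
    m <- t(rhdf5::h5read(path, "X"))
    if (nrow(m) != length(cells)) m <- t(m)
  }
  ExpressionMatrix(m, cells, genes, layer = "raw_counts")
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_matrix]; `write_matrix` then `read_matrix` reproduces
#' values and identifiers exactly.  For `mtx` the matrix is written
#' genes x cells with `features.tsv`/`barcodes.tsv` sidecars.
#'
#' @param m an [ExpressionMatrix].
#' @param path output path (for `mtx`, the `.mtx` file; sidecars are
#'   placed next to it).
#' @param format `"mtx"`, `"dense_tsv"` or `"h5sc"`.
#' @export
write_matrix <- function(m, path, format = c("mtx", "dense_tsv", "h5sc")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  format <- match.arg(format)
  if (format == "mtx") {
    sp <- as(as(Matrix::Matrix(m$values, sparse = TRUE), "CsparseMatrix"),
             "generalMatrix")
    Matrix::writeMM(Matrix::t(sp), path)
    dir <- dirname(path)
    writeLines(m$gene_ids, file.path(dir, "features.tsv"))
    writeLines(m$cell_ids, file.path(dir, "barcodes.tsv"))
  } else if (format == "dense_tsv") {
    dense <- as_dense(m)
    tab <- data.table::data.table(cell_id = m$cell_ids)
    tab <- cbind(tab, data.table::as.data.table(dense))
    data.table::setnames(tab, c("cell_id", m$gene_ids))
    data.table::fwrite(tab, path, sep = "\t")
  } else {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("writing h5sc files requires the 'rhdf5' package")
    on.exit(rhdf5::H5close(), add = TRUE)
    if (file.exists(path)) file.remove(path)
    rhdf5::h5createFile(path)
    sp <- as(as(Matrix::Matrix(m$values, sparse = TRUE), "CsparseMatrix"),
             "generalMatrix")
    csr <- as(Matrix::t(sp), "CsparseMatrix")  # column-compressed transpose == CSR
    rhdf5::h5createGroup(path, "X")
    rhdf5::h5write(csr@x, path, "X/data")
    rhdf5::h5write(csr@i, path, "X/indices")
    rhdf5::h5write(csr@p, path, "X/indptr")
    rhdf5::h5createGroup(path, "obs")
    rhdf5::h5write(m$cell_ids, path, "obs/_index")
    rhdf5::h5createGroup(path, "var")
    rhdf5::h5write(m$gene_ids, path, "var/_index")
  }
  invisible(path)
}

#' Read per-cell state labels and align them to a matrix
#'
#' Expects a two-column delimited file (cell_id, label); a header row is
#' detected automatically.  Labels are returned in the matrix's cell order.
#' Rows for cells absent from the matrix are ignored with a warning; cells
#' missing from the file are an error.
#'
#' @param path label file path.
#' @param cell_ids cell identifiers of the matrix the labels belong to.
#' @return character vector of labels, one per `cell_ids` entry.
#' @export
read_labels <- function(path, cell_ids) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- data.table::fread(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("label file must have two columns (cell_id, label)")
  tab <- tab[, 1:2]
  data.table::setnames(tab, c("cell_id", "label"))
  if (nrow(tab) > 0L && !(tab$cell_id[1L] %in% cell_ids))
    tab <- tab[-1L] # header row
  dup <- tab[, .N, by = c("cell_id", "label")][, .N, by = "cell_id"]
  conflicts <- dup$cell_id[dup$N > 1L]
  if (length(conflicts))
    stop("conflicting labels for cell(s): ",
         paste(head(conflicts, 10L), collapse = ", "))
  tab <- unique(tab)
  extra <- setdiff(tab$cell_id, cell_ids)
  if (length(extra))
    warning(length(extra), " label row(s) for cells absent from the matrix ",
            "were ignored")
  idx <- match(cell_ids, tab$cell_id)
  if (anyNA(idx)) {
    missing <- cell_ids[is.na(idx)]
    stop("no label for cell(s): ", paste(head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) sprintf(" (and %d more)", length(missing) - 10L))
  }
  tab$label[idx]
}

#' Save a trained model bundle
#'
#' Serializes the full model (gene panel, reference statistics, per-class
#' weights, calibrators, vocabulary, training report) together with a
#' format-version string.  `load_model(save_model(m))` reproduces
#' predictions bitwise.
#'
#' @param model a `TrainedModel`.
#' @param path output path (conventionally `.rds`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "TrainedModel"))
  bundle <- list(format_version = MODEL_FORMAT_VERSION,
                 package_version = as.character(packageVersion("cellstateR")),
                 model = model)
  saveRDS(bundle, path)
  invisible(path)
}

#' Load a trained model bundle
#' @param path path written by [save_model].
#' @return the `TrainedModel`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bundle <- tryCatch(readRDS(path),
                     error = function(e)
                       stop("corrupt or truncated model bundle '", path,
                            "': ", conditionMessage(e), call. = FALSE))
  if (!is.list(bundle) || is.null(bundle$format_version))
    stop("not a cellstateR model bundle: ", path)
  if (!identical(bundle$format_version, MODEL_FORMAT_VERSION))
    stop("model format version mismatch: file has '", bundle$format_version,
         "', this build reads '", MODEL_FORMAT_VERSION, "'")
  bundle$model
}
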