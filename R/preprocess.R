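#' Library-size normalize and log-transform raw counts
#'
#' Each cell's counts are scaled to sum to `target_sum`, then `log1p` is
#' applied — the field-standard shift-log transform.  Cells with zero total
#' counts are left all-zero (one warning per call).
#'
#' @param m an [ExpressionMatrix] with layer `raw_counts`.
#' @param target_sum per-cell total after scaling (default `1e4`).
#' @return an [ExpressionMatrix] with layer `normalized`.
#' @export
normalize_counts <- function(m, target_sum = 1e4) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "raw_counts")
    stop("normalize_counts expects layer 'raw_counts', got '", m$layer, "'")
  if (!is.numeric(target_sum) || length(target_sum) != 1L || target_sum <= 0)
    stop("target_sum must be a positive number")
  totals <- if (is(m$values, "sparseMatrix")) Matrix::rowSums(m$values)
            else rowSums(m$values)
  zero <- totals == 0
  if (any(zero))
    warning(sum(zero), " cell(s) with zero total counts left all-zero")
  scale <- ifelse(zero, 0, target_sum / totals)
  if (is(m$values, "sparseMatrix")) {
    out <- Matrix::Diagonal(x = scale) %*% m$values
    out@x <- log1p(out@x)
  } else {
    out <- log1p(m$values * scale)
  }
  with_values(m, out, "normalized")
}

#' Flag highly variable genes
#'
#' Ranks genes by dispersion (variance / mean) of the normalized layer and
#' flags the top `n_top`; genes with zero mean are never flagged.  Ties are
#' broken lexicographically by gene ID so the flag set is platform
#' independent.  HVG status is an annotation carried through reports — it
#' does not remove genes from any stage.
#'
#' @param m an [ExpressionMatrix] with layer `normalized`.
#' @param n_top number of genes to flag (default 2000).
#' @return named logical vector over genes.
#' @export
flag_hvgs <- function(m, n_top = 2000) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "normalized")
    stop("flag_hvgs expects layer 'normalized', got '", m$layer, "'")
  if (nrow(m$values) < 2L) stop("flag_hvgs requires at least 2 cells")
  if (n_top < 0) stop("n_top must be non-negative")
  mu <- col_means(m$values)
  v <- col_vars(m$values, mu)
  dispersion <- ifelse(mu > 0, v / mu, -Inf)
  flags <- stats::setNames(logical(length(mu)), m$gene_ids)
  if (n_top == 0) return(flags)
  if (n_top > length(mu)) {
    warning("n_top (", n_top, ") exceeds gene count (", length(mu),
            "); flagging all genes")
    n_top <- length(mu)
  }
  ord <- order(-dispersion, m$gene_ids)
  flags[ord[seq_len(n_top)]] <- TRUE
  flags
}

col_means <- function(values) {
  if (is(values, "sparseMatrix")) Matrix::colMeans(values) else colMeans(values)
}

col_vars <- function(values, mu = col_means(values)) {
  n <- nrow(values)
  if (is(values, "sparseMatrix")) {
    sq <- Matrix::colMeans(values^2)
  } else {
    sq <- colMeans(values^2)
  }
  (sq - mu^2) * n / max(1, n - 1)
}

#' Per-gene reference statistics for standardization
#'
#' Mean and standard deviation of each gene in the reference's normalized
#' layer, plus its HVG flag.  Genes with zero standard deviation are
#' non-informative: standardization leaves them at 0.
#'
#' @param m an [ExpressionMatrix] with layer `normalized`.
#' @param n_top_hvg HVG count passed to [flag_hvgs].
#' @return an object of class `GeneStats`.
#' @export
compute_gene_stats <- function(m, n_top_hvg = 2000) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "normalized")
    stop("compute_gene_stats expects layer 'normalized'")
  mu <- col_means(m$values)
  sd <- sqrt(pmax(0, col_vars(m$values, mu)))
  structure(list(gene_ids = m$gene_ids,
                 mean = unname(mu), sd = unname(sd),
                 hvg = unname(flag_hvgs(m, n_top_hvg))),
            class = "GeneStats")
}

#' Restrict GeneStats to a gene subset, preserving the subset's order
#' @param stats a `GeneStats`.
#' @param genes character vector, subset of `stats$gene_ids`.
#' @return a `GeneStats` over `genes`.
#' @export
subset_gene_stats <- function(stats, genes) {
  stopifnot(inherits(stats, "GeneStats"))
  idx <- match(genes, stats$gene_ids)
  if (anyNA(idx)) stop("genes absent from GeneStats: ",
                       paste(head(genes[is.na(idx)], 10L), collapse = ", "))
  structure(list(gene_ids = genes, mean = stats$mean[idx],
                 sd = stats$sd[idx], hvg = stats$hvg[idx]),
            class = "GeneStats")
}

#' Align a query matrix to a reference gene space
#'
#' Reorders query genes to match `reference_genes` exactly; genes missing
#' from the query become zero columns, extra query genes are dropped.
#' Refuses when the missing-gene fraction exceeds `max_missing`, since a
#' model applied to a mostly-empty feature space produces meaningless
#' scores.
#'
#' @param query an [ExpressionMatrix].
#' @param reference_genes ordered character vector of gene IDs.
#' @param max_missing maximum tolerated fraction of reference genes absent
#'   from the query (default 0.5).
#' @return an [ExpressionMatrix] over `reference_genes`; attribute
#'   `missing_fraction` records the zero-filled fraction.
#' @export
harmonize_genes <- function(query, reference_genes, max_missing = 0.5) {
  stopifnot(inherits(query, "ExpressionMatrix"))
  reference_genes <- as.character(reference_genes)
  idx <- match(reference_genes, query$gene_ids)
  missing_frac <- mean(is.na(idx))
  if (missing_frac > max_missing)
    stop(sprintf(paste0("%.0f%% of the %d reference genes are missing from ",
                        "the query (threshold %.0f%%); check that both use ",
                        "the same gene identifier scheme"),
                 100 * missing_frac, length(reference_genes),
                 100 * max_missing))
  sparse <- is(query$values, "sparseMatrix")
  n <- nrow(query$values)
  out <- if (sparse)
    Matrix::Matrix(0, n, length(reference_genes), sparse = TRUE)
  else matrix(0, n, length(reference_genes))
  present <- !is.na(idx)
  out[, present] <- query$values[, idx[present], drop = FALSE]
  res <- ExpressionMatrix(out, query$cell_ids, reference_genes,
                          layer = query$layer)
  attr(res, "missing_fraction") <- missing_frac
  res
}

#' Standardize a normalized matrix with reference statistics
#'
#' Per gene: `(x - mean) / sd` using the *reference* mean and sd (never the
#' query's own), clipped to `[-clip, clip]`.  Zero-sd genes map to 0.
#' Standardizing queries with reference statistics keeps the feature space
#' the classifier was trained in, and avoids leaking query batch structure
#' into the decision function.
#'
#' @param m an [ExpressionMatrix] with layer `normalized`.
#' @param stats a `GeneStats` over exactly `m`'s genes, in order.
#' @param clip symmetric clipping bound in reference standard deviations
#'   (default 10).
#' @return an [ExpressionMatrix] with layer `standardized` (dense).
#' @export
standardize <- function(m, stats, clip = 10) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(stats, "GeneStats"))
  if (m$layer != "normalized")
    stop("standardize expects layer 'normalized', got '", m$layer, "'")
  if (!identical(m$gene_ids, stats$gene_ids))
    stop("gene order mismatch between matrix and GeneStats")
  x <- as_dense(m)
  sd_safe <- ifelse(stats$sd > 0, stats$sd, 1)
  z <- sweep(sweep(x, 2L, stats$mean, "-"), 2L, sd_safe, "/")
  z[, stats$sd == 0] <- 0
  z <- pmin(pmax(z, -clip), clip)
  # standardized matrices are dense by nature; bypass density heuristics
  dimnames(z) <- list(m$cell_ids, m$gene_ids)
  structure(list(values = z, cell_ids = m$cell_ids, gene_ids = m$gene_ids,
                 layer = "standardized"),
            class = "ExpressionMatrix")
}
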