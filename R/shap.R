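#' Exact Shapley attributions for a linear classifier
#'
#' For a linear decision function the Shapley value of gene `g` for cell
#' `i` and class `c` has the closed form
#' `phi[i, g, c] = w[c, g] * (x[i, g] - background_mean[g])`, with the
#' per-class base value `intercept[c] + sum_g w[c, g] * background_mean[g]`
#' (the class score of the background-average cell).  The attributions are
#' exact: `base_value[c] + sum_g phi[i, g, c]` equals the class decision
#' score of cell `i`.
#'
#' @param weights classes x genes weight matrix.
#' @param intercepts per-class intercepts.
#' @param X cells x genes standardized matrix (same gene order as
#'   `weights`).
#' @param background_mean per-gene background expectation.
#' @return an `AttributionMatrix`: list with `phi` (cells x genes x
#'   classes array) and `base_value` (per class).
#' @export
shap_linear <- function(weights, intercepts, X, background_mean) {
  X <- as.matrix(X)
  if (ncol(weights) != ncol(X) || length(background_mean) != ncol(X))
    stop("gene dimension mismatch between weights (", ncol(weights),
         "), X (", ncol(X), ") and background_mean (",
         length(background_mean), ")")
  if (length(intercepts) != nrow(weights))
    stop("need one intercept per class")
  centered <- sweep(X, 2L, background_mean, "-")
  n_class <- nrow(weights)
  phi <- array(0, dim = c(nrow(X), ncol(X), n_class),
               dimnames = list(rownames(X), colnames(X), rownames(weights)))
  for (k in seq_len(n_class))
    phi[, , k] <- sweep(centered, 2L, weights[k, ], "*")
  base_value <- as.numeric(weights %*% background_mean) + intercepts
  names(base_value) <- rownames(weights)
  structure(list(phi = phi, base_value = base_value),
            class = "AttributionMatrix")
}

#' Aggregate attributions into one non-negative importance per gene
#'
#' `score[g] = sum_c mean_i |phi[i, g, c]|`: the mean absolute attribution
#' over cells, summed across classes.  Deterministic for fixed input.
#'
#' @param att an `AttributionMatrix` from [shap_linear].
#' @return named non-negative numeric vector over genes.
#' @export
aggregate_importance <- function(att) {
  stopifnot(inherits(att, "AttributionMatrix"))
  if (dim(att$phi)[1L] < 1L) stop("need at least one cell")
  apply(abs(att$phi), 2L, function(gene_slice) sum(colMeans(gene_slice)))
}

# Same quantity without materializing the cells x genes x classes array:
# |w * (x - mu)| factorizes as |w| * |x - mu|, so
# score[g] = (sum_c |w[c,g]|) * mean_i |x[i,g] - mu[g]|.
importance_linear <- function(weights, X, background_mean) {
  X <- as.matrix(X)
  mad_g <- colMeans(abs(sweep(X, 2L, background_mean, "-")))
  stats::setNames(colSums(abs(weights)) * mad_g, colnames(weights))
}

#' Retained-panel sizes of recursive feature elimination
#'
#' Iterates `m <- ceiling(f * m)` for `rounds` rounds.
#'
#' @param n_genes starting gene count.
#' @param rounds number of elimination rounds.
#' @param retain_fraction fraction retained per round, in `(0, 1]`.
#' @return integer vector of length `rounds`: genes retained after each
#'   round.
#' @export
elimination_schedule <- function(n_genes, rounds, retain_fraction = 0.5) {
  if (retain_fraction <= 0 || retain_fraction > 1)
    stop("retain_fraction must be in (0, 1]")
  if (rounds < 0) stop("rounds must be non-negative")
  out <- integer(rounds)
  m <- as.integer(n_genes)
  for (r in seq_len(rounds)) {
    m <- as.integer(ceiling(retain_fraction * m))
    out[r] <- m
  }
  out
}

#' Shapley-driven recursive feature elimination
#'
#' Starting from all genes (highly variable or not), each round fits an
#' interim one-vs-rest classifier on the surviving genes, computes Shapley
#' attributions against the mean of a seeded background subsample of
#' `background_size` reference cells, aggregates them into per-gene
#' importances ([aggregate_importance]), and retains the top
#' `ceiling(retain_fraction * m)` genes.  Ties on equal importance are
#' broken lexicographically by gene ID.  Interim models reuse the final
#' hyperparameters in `model_cfg`.
#'
#' @param ref a [ReferenceAtlas].
#' @param rounds number of elimination rounds (default 4).
#' @param retain_fraction fraction of genes kept per round (default 0.5).
#' @param background_size cells in the background subsample (default 1000).
#' @param model_cfg a [model_config] used for the interim fits.
#' @param target_sum,n_top_hvg preprocessing parameters.
#' @param seed seed for the background subsample (default: the config
#'   seed).
#' @return list with `gene_panel` (selected genes, reference order),
#'   `report` (data.frame: round, genes_in, genes_out), and
#'   `hvg_composition` (HVG / non-HVG counts of the final panel).
#' @export
recursive_elimination <- function(ref, rounds = 4L, retain_fraction = 0.5,
                                  background_size = 1000L,
                                  model_cfg = model_config(),
                                  target_sum = 1e4, n_top_hvg = 2000,
                                  seed = model_cfg$seed) {
  stopifnot(inherits(ref, "ReferenceAtlas"))
  if (length(ref$label_vocabulary) < 2L)
    stop("at least 2 classes are required")
  if (retain_fraction <= 0 || retain_fraction > 1)
    stop("retain_fraction must be in (0, 1]")
  norm <- normalize_counts(ref$matrix, target_sum)
  stats_all <- compute_gene_stats(norm, min(n_top_hvg,
                                            length(ref$matrix$gene_ids)))
  vocab <- ref$label_vocabulary
  n_cells <- length(ref$matrix$cell_ids)
  bg_idx <- with_seed(seed, sample.int(n_cells,
                                       min(background_size, n_cells)))
  current <- ref$matrix$gene_ids
  report <- data.frame(round = integer(0), genes_in = integer(0),
                       genes_out = integer(0))
  for (r in seq_len(rounds)) {
    keep_n <- as.integer(ceiling(retain_fraction * length(current)))
    if (keep_n < length(vocab)) {
      warning("stopping after round ", r - 1L, ": retaining ", keep_n,
              " genes would fall below the number of classes (",
              length(vocab), ")")
      break
    }
    stats_cur <- subset_gene_stats(stats_all, current)
    Z <- standardize_panel(norm, current, stats_cur)
    ovr <- fit_ovr(Z, ref$labels, vocab, model_cfg)
    Zbg <- Z[bg_idx, , drop = FALSE]
    mu_bg <- colMeans(Zbg)
    score <- importance_linear(ovr$weights, Zbg, mu_bg)
    ord <- order(-score, current)
    kept <- sort(current[ord[seq_len(keep_n)]])
    report <- rbind(report,
                    data.frame(round = r, genes_in = length(current),
                               genes_out = keep_n))
    # preserve reference gene order in the panel
    current <- ref$matrix$gene_ids[ref$matrix$gene_ids %in% kept]
  }
  hvg <- stats_all$hvg[match(current, stats_all$gene_ids)]
  list(gene_panel = current,
       report = report,
       hvg_composition = c(hvg = sum(hvg), non_hvg = sum(!hvg)))
}
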