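#' Certainty thresholds for binning
#'
#' Certainty scores are binned low / medium / high at `tau_low = 0.3` and
#' `tau_high = 0.7`.  The boundaries follow a half-open convention:
#' low = `[0, tau_low)`, medium = `[tau_low, tau_high)`,
#' high = `[tau_high, 1]`.
#'
#' @param tau_low,tau_high thresholds with `0 <= tau_low < tau_high <= 1`.
#' @return object of class `CertaintyThresholds`.
#' @export
certainty_thresholds <- function(tau_low = 0.3, tau_high = 0.7) {
  if (!(tau_low >= 0 && tau_low < tau_high && tau_high <= 1))
    stop("need 0 <= tau_low < tau_high <= 1")
  structure(list(tau_low = tau_low, tau_high = tau_high),
            class = "CertaintyThresholds")
}

#' Bin certainty scores into low / medium / high
#'
#' @param s numeric certainty scores in `[0, 1]`.
#' @param thresholds a [certainty_thresholds].
#' @return character vector in `{"low", "medium", "high"}`.
#' @export
bin_certainty <- function(s, thresholds = certainty_thresholds()) {
  if (any(!is.finite(s)) || any(s < 0 | s > 1))
    stop("certainty scores must lie in [0, 1]")
  out <- rep("medium", length(s))
  out[s < thresholds$tau_low] <- "low"
  out[s >= thresholds$tau_high] <- "high"
  out
}

#' Annotate a query dataset with a calibrated model
#'
#' Per query cell: library-size normalize, harmonize the gene space to the
#' model's panel, standardize with the *reference* statistics, compute
#' per-class decision scores, map them through the per-class calibrators,
#' renormalize to sum to 1, and take the argmax state (ties broken
#' lexicographically).  The certainty score is the maximum renormalized
#' probability; it is binned with `thresholds`.
#'
#' @param object a calibrated `TrainedModel`.
#' @param query an [ExpressionMatrix] of raw counts.
#' @param thresholds a [certainty_thresholds].
#' @param max_missing maximum tolerated fraction of panel genes absent from
#'   the query (see [harmonize_genes]).
#' @param ... unused.
#' @return data.frame with one row per query cell: `cell_id`,
#'   `predicted_label`, `certainty`, `bin`, then one `prob.<state>` column
#'   per state.
#' @export
predict.TrainedModel <- function(object, query,
                                 thresholds = certainty_thresholds(),
                                 max_missing = 0.5, ...) {
  if (is.null(object$calibrators))
    stop("uncalibrated model: run calibrate_model() before predict()")
  stopifnot(inherits(query, "ExpressionMatrix"))
  if (query$layer != "raw_counts")
    stop("predict expects a raw_counts query matrix")
  norm <- normalize_counts(query)
  harm <- harmonize_genes(norm, object$gene_panel, max_missing = max_missing)
  Z <- standardize(harm, object$gene_stats)$values
  S <- decision_scores(object$weights, object$intercepts, Z)
  P <- vapply(seq_along(object$label_vocabulary),
              function(k) apply_platt(object$calibrators[[k]], S[, k]),
              numeric(nrow(S)))
  P <- matrix(P, nrow = nrow(S),
              dimnames = list(query$cell_ids, object$label_vocabulary))
  row_tot <- rowSums(P)
  # a cell scoring zero for every class carries no information: uniform
  P[row_tot == 0, ] <- 1 / ncol(P)
  row_tot[row_tot == 0] <- 1
  P <- P / row_tot
  # vocabulary is sorted, so the first maximum is the lexicographic tie-break
  top <- max.col(P, ties.method = "first")
  certainty <- P[cbind(seq_len(nrow(P)), top)]
  out <- data.frame(cell_id = query$cell_ids,
                    predicted_label = object$label_vocabulary[top],
                    certainty = certainty,
                    bin = bin_certainty(certainty, thresholds),
                    stringsAsFactors = FALSE)
  probs <- as.data.frame(P)
  names(probs) <- paste0("prob.", object$label_vocabulary)
  rownames(out) <- NULL
  cbind(out, probs, row.names = NULL)
}

#' Summarize a prediction table
#'
#' @param records data.frame from [predict.TrainedModel].
#' @return list with `bin_counts`, `bin_percent` (over low/medium/high),
#'   `per_state` (n, median certainty per predicted state), and `cdf`
#'   (sorted certainties with cumulative fractions, for certainty plots).
#' @export
summarize_predictions <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("need at least one prediction record")
  bins <- factor(records$bin, levels = c("low", "medium", "high"))
  counts <- table(bins)
  per_state <- do.call(rbind, lapply(split(records, records$predicted_label),
    function(d) data.frame(state = d$predicted_label[1L], n = nrow(d),
                           median_certainty = median(d$certainty))))
  rownames(per_state) <- NULL
  s <- sort(records$certainty)
  list(bin_counts = stats::setNames(as.integer(counts), names(counts)),
       bin_percent = stats::setNames(100 * as.integer(counts) / nrow(records),
                                     names(counts)),
       per_state = per_state[order(per_state$state), ],
       cdf = data.frame(certainty = s,
                        cumulative_fraction = seq_along(s) / length(s)))
}

#' Top explainable genes per predicted state
#'
#' For each state with at least one predicted cell, computes the Shapley
#' attributions of that state's decision function over the query cells
#' predicted as that state (background: the reference mean, which is the
#' origin of the standardized space), averages them per gene, keeps only
#' strictly positive mean attributions, and returns the top `n_top`
#' non-increasing.  Explanations are computed on the query — the table
#' reflects what drove *these* predictions.
#'
#' @param model a calibrated `TrainedModel`.
#' @param query the [ExpressionMatrix] the records were predicted from.
#' @param records data.frame from [predict.TrainedModel].
#' @param n_top genes kept per state (default 10).
#' @param max_missing see [harmonize_genes].
#' @return named list (one entry per predicted state) of data.frames with
#'   columns `gene`, `mean_attribution`.
#' @export
top_explainable_genes <- function(model, query, records, n_top = 10L,
                                  max_missing = 0.5) {
  stopifnot(inherits(model, "TrainedModel"))
  norm <- normalize_counts(query)
  harm <- harmonize_genes(norm, model$gene_panel, max_missing = max_missing)
  Z <- standardize(harm, model$gene_stats)$values
  states <- sort(unique(records$predicted_label))
  absent <- setdiff(model$label_vocabulary, states)
  if (length(absent))
    warning("state(s) with zero predicted cells omitted: ",
            paste(absent, collapse = ", "))
  out <- list()
  for (st in states) {
    cells <- match(records$cell_id[records$predicted_label == st],
                   query$cell_ids)
    if (anyNA(cells)) stop("records contain cell_ids absent from the query")
    k <- match(st, model$label_vocabulary)
    # reference mean is 0 in standardized space, so phi = w * z
    mean_phi <- model$weights[k, ] * colMeans(Z[cells, , drop = FALSE])
    keep <- mean_phi > 0
    tab <- data.frame(gene = model$gene_panel[keep],
                      mean_attribution = unname(mean_phi[keep]))
    tab <- tab[order(-tab$mean_attribution, tab$gene), , drop = FALSE]
    rownames(tab) <- NULL
    out[[st]] <- head(tab, n_top)
  }
  out
}
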