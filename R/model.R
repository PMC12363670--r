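#' Model configuration
#'
#' Hyperparameters of the one-vs-rest linear max-margin classifier.  The
#' defaults are the selected operating point of the method: regularization
#' `C = 0.01`, balanced class weights, at most 1000 solver epochs, and
#' 5-fold cross-validation.
#'
#' @param C regularization strength (> 0); larger C fits training data
#'   harder.
#' @param class_weight `"balanced"` (per-class weight `N / (K * n_c)`) or
#'   `"uniform"`.
#' @param max_iter solver epoch cap per binary problem.
#' @param folds number of cross-validation folds (>= 2).
#' @param tuning_grid named list of candidate values for `C`,
#'   `class_weight`, `max_iter` used by [tune_model].
#' @param seed integer seed governing fold shuffles and solver coordinate
#'   order.
#' @param tol solver stopping tolerance on the projected gradient.
#' @return an object of class `ModelConfig`.
#' @export
model_config <- function(C = 0.01, class_weight = c("balanced", "uniform"),
                         max_iter = 1000L, folds = 5L,
                         tuning_grid = list(C = c(0.001, 0.01, 0.1, 1),
                                            class_weight = "balanced",
                                            max_iter = 1000L),
                         seed = 0L, tol = 1e-3) {
  class_weight <- match.arg(class_weight)
  if (!is.numeric(C) || C <= 0) stop("C must be > 0")
  if (folds < 2L) stop("folds must be >= 2")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (!is.null(tuning_grid$C) && any(tuning_grid$C <= 0))
    stop("tuning_grid C values must all be > 0")
  structure(list(C = C, class_weight = class_weight,
                 max_iter = as.integer(max_iter), folds = as.integer(folds),
                 tuning_grid = tuning_grid, seed = as.integer(seed),
                 tol = tol),
            class = "ModelConfig")
}

#' Class-size-weighted F1 score
#'
#' `sum_c (n_c / N) * F1_c` with `n_c` the support of class `c` in
#' `y_true` and `F1_c` the harmonic mean of that class's precision and
#' recall (0 when undefined).
#'
#' @param y_true,y_pred character vectors of equal positive length.
#' @return score in `[0, 1]`.
#' @export
weighted_f1 <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- sort(unique(y_true))
  total <- 0
  for (cl in classes) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    total <- total + sum(y_true == cl) / length(y_true) * f1
  }
  total
}

# per-class weights: balanced = N / (K * n_c), uniform = 1
class_weights <- function(labels, vocab, scheme) {
  n_c <- table(factor(labels, levels = vocab))
  if (scheme == "balanced")
    stats::setNames(length(labels) / (length(vocab) * as.numeric(n_c)), vocab)
  else stats::setNames(rep(1, length(vocab)), vocab)
}

# Fit one-vs-rest linear hinge-loss classifiers on a standardized matrix.
# Internal work-horse shared by fit_model, cross-validation, calibration and
# the feature-elimination rounds.
fit_ovr <- function(X, labels, vocab, cfg) {
  X <- as.matrix(X)
  wts <- class_weights(labels, vocab, cfg$class_weight)
  W <- matrix(0, length(vocab), ncol(X),
              dimnames = list(vocab, colnames(X)))
  b <- stats::setNames(numeric(length(vocab)), vocab)
  convergence <- stats::setNames(logical(length(vocab)), vocab)
  cost <- cfg$C * wts[labels]
  for (k in seq_along(vocab)) {
    y <- ifelse(labels == vocab[k], 1, -1)
    fitk <- .svm_dcd(X, y, unname(cost), cfg$max_iter, cfg$tol,
                     as.integer((cfg$seed + k) %% .Machine$integer.max))
    W[k, ] <- fitk$w
    b[k] <- fitk$b
    convergence[k] <- fitk$converged
  }
  if (!all(convergence))
    warning("solver hit max_iter (", cfg$max_iter, ") without convergence ",
            "for class(es): ",
            paste(vocab[!convergence], collapse = ", "))
  list(weights = W, intercepts = b, converged = convergence)
}

decision_scores <- function(weights, intercepts, X) {
  S <- as.matrix(X) %*% t(weights)
  sweep(S, 2L, intercepts, "+")
}

#' Fit the multiclass linear max-margin classifier
#'
#' One binary hinge-loss linear classifier per state (one-vs-rest), L2
#' penalty with strength `C`, optional balanced class weights, solved by
#' dual coordinate descent with a seeded coordinate order so refits are
#' bit-reproducible.  The returned model is *uncalibrated*: [predict] on it
#' refuses until [calibrate_model] has been run.
#'
#' @param ref a [ReferenceAtlas] (raw counts).
#' @param gene_panel ordered gene subset to train on (default: all genes).
#' @param cfg a [model_config].
#' @param target_sum,n_top_hvg preprocessing parameters (see
#'   [normalize_counts], [flag_hvgs]).
#' @return an object of class `TrainedModel`.
#' @export
fit_model <- function(ref, gene_panel = NULL, cfg = model_config(),
                      target_sum = 1e4, n_top_hvg = 2000) {
  stopifnot(inherits(ref, "ReferenceAtlas"), inherits(cfg, "ModelConfig"))
  vocab <- ref$label_vocabulary
  if (length(vocab) < 2L) stop("at least 2 classes are required")
  too_small <- vocab[table(factor(ref$labels, levels = vocab)) < cfg$folds]
  if (length(too_small))
    stop("class(es) with fewer cells than folds (", cfg$folds, "): ",
         paste(too_small, collapse = ", "))
  norm <- normalize_counts(ref$matrix, target_sum)
  stats_all <- compute_gene_stats(norm, min(n_top_hvg,
                                            length(ref$matrix$gene_ids)))
  if (is.null(gene_panel)) gene_panel <- ref$matrix$gene_ids
  stats_panel <- subset_gene_stats(stats_all, gene_panel)
  Z <- standardize_panel(norm, gene_panel, stats_panel)
  ovr <- fit_ovr(Z, ref$labels, vocab, cfg)
  pred <- vocab[max.col(decision_scores(ovr$weights, ovr$intercepts, Z),
                        ties.method = "first")]
  structure(list(gene_panel = gene_panel,
                 gene_stats = stats_panel,
                 weights = ovr$weights,
                 intercepts = ovr$intercepts,
                 calibrators = NULL,
                 label_vocabulary = vocab,
                 config = cfg,
                 target_sum = target_sum,
                 training_report = list(
                   training_weighted_f1 = weighted_f1(ref$labels, pred),
                   converged = ovr$converged)),
            class = "TrainedModel")
}

# restrict normalized matrix to a panel and standardize with panel stats;
# returns the dense cells x genes matrix the solver consumes
standardize_panel <- function(norm, gene_panel, stats_panel) {
  idx <- match(gene_panel, norm$gene_ids)
  if (anyNA(idx)) stop("gene_panel contains genes absent from the matrix")
  sub <- structure(list(values = norm$values[, idx, drop = FALSE],
                        cell_ids = norm$cell_ids, gene_ids = gene_panel,
                        layer = "normalized"),
                   class = "ExpressionMatrix")
  standardize(sub, stats_panel)$values
}

#' @export
print.TrainedModel <- function(x, ...) {
  cat(sprintf("TrainedModel: %d states, %d-gene panel, %s\n",
              length(x$label_vocabulary), length(x$gene_panel),
              if (is.null(x$calibrators)) "uncalibrated" else "calibrated"))
  invisible(x)
}

# stratified K folds, shuffled with seed; fold of cell i in fold_id[i]
stratified_folds <- function(labels, k, seed) {
  vocab <- sort(unique(labels))
  counts <- table(factor(labels, levels = vocab))
  rare <- vocab[counts < k]
  if (length(rare))
    stop("class(es) too rare for ", k, "-fold CV (need >= ", k,
         " cells): ", paste(rare, collapse = ", "),
         "; use a smaller number of folds")
  fold_id <- integer(length(labels))
  with_seed(seed, {
    for (cl in vocab) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold_id
}

# run code under a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit(if (had) assign(".Random.seed", old, envir = genv)
          else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv))
  set.seed(seed)
  code
}

#' Stratified K-fold cross-validation of the classifier
#'
#' Folds are stratified by state and shuffled with the config seed.  Each
#' fold is scored by [weighted_f1] on the held-out cells; the aggregate is
#' the mean of fold scores.  Per-class precision/recall/F1 over the pooled
#' out-of-fold predictions are also returned.
#'
#' @inheritParams fit_model
#' @return list with `fold_scores`, `aggregate`, `per_class`.
#' @export
cross_validate <- function(ref, gene_panel = NULL, cfg = model_config(),
                           target_sum = 1e4) {
  stopifnot(inherits(ref, "ReferenceAtlas"))
  vocab <- ref$label_vocabulary
  if (is.null(gene_panel)) gene_panel <- ref$matrix$gene_ids
  fold_id <- stratified_folds(ref$labels, cfg$folds, cfg$seed)
  oof_pred <- character(length(ref$labels))
  fold_scores <- numeric(cfg$folds)
  for (f in seq_len(cfg$folds)) {
    train <- fold_id != f
    # reference statistics recomputed on the training split only
    norm_tr <- normalize_counts(subset_cells(ref$matrix, train), target_sum)
    stats_tr <- subset_gene_stats(compute_gene_stats(norm_tr, 0L), gene_panel)
    Z_tr <- standardize_panel(norm_tr, gene_panel, stats_tr)
    ovr <- fit_ovr(Z_tr, ref$labels[train], vocab, cfg)
    norm_te <- normalize_counts(subset_cells(ref$matrix, !train), target_sum)
    Z_te <- standardize_panel(norm_te, gene_panel, stats_tr)
    pred <- vocab[max.col(decision_scores(ovr$weights, ovr$intercepts, Z_te),
                          ties.method = "first")]
    oof_pred[!train] <- pred
    fold_scores[f] <- weighted_f1(ref$labels[!train], pred)
  }
  list(fold_scores = fold_scores,
       aggregate = mean(fold_scores),
       per_class = per_class_metrics(ref$labels, oof_pred, vocab))
}

subset_cells <- function(m, keep) {
  structure(list(values = m$values[keep, , drop = FALSE],
                 cell_ids = m$cell_ids[keep], gene_ids = m$gene_ids,
                 layer = m$layer),
            class = "ExpressionMatrix")
}

per_class_metrics <- function(y_true, y_pred, vocab) {
  out <- lapply(vocab, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0
          else 2 * precision * recall / (precision + recall)
    data.frame(state = cl, n = sum(y_true == cl), precision = precision,
               recall = recall, f1 = f1)
  })
  do.call(rbind, out)
}

#' Exhaustive grid search over classifier hyperparameters
#'
#' Every combination in `cfg$tuning_grid` is scored by cross-validated
#' weighted F1.  Ties are broken toward smaller `C` (stronger
#' regularization), then balanced class weights, then smaller `max_iter`.
#'
#' @inheritParams fit_model
#' @return list with `best` (a [model_config]), `grid` (one row per point,
#'   with its CV score).
#' @export
tune_model <- function(ref, gene_panel = NULL, cfg = model_config(),
                       target_sum = 1e4) {
  grid <- cfg$tuning_grid
  if (is.null(grid) || !length(grid)) stop("tuning_grid is empty")
  if (!is.null(grid$C) && any(grid$C <= 0))
    stop("tuning_grid C values must all be > 0")
  pts <- expand.grid(C = grid$C %||% cfg$C,
                     class_weight = grid$class_weight %||% cfg$class_weight,
                     max_iter = grid$max_iter %||% cfg$max_iter,
                     stringsAsFactors = FALSE)
  pts$score <- NA_real_
  for (i in seq_len(nrow(pts))) {
    cfg_i <- model_config(C = pts$C[i], class_weight = pts$class_weight[i],
                          max_iter = pts$max_iter[i], folds = cfg$folds,
                          tuning_grid = cfg$tuning_grid, seed = cfg$seed,
                          tol = cfg$tol)
    pts$score[i] <- cross_validate(ref, gene_panel, cfg_i,
                                   target_sum)$aggregate
  }
  ord <- order(-pts$score, pts$C, pts$class_weight != "balanced", pts$max_iter)
  best <- pts[ord[1L], ]
  list(best = model_config(C = best$C, class_weight = best$class_weight,
                           max_iter = best$max_iter, folds = cfg$folds,
                           tuning_grid = cfg$tuning_grid, seed = cfg$seed,
                           tol = cfg$tol),
       grid = pts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrate per-class decision scores into probabilities
#'
#' Fits one Platt-style sigmoid per class, `P(c | s) = 1 / (1 + exp(a*s +
#' b))`, on *out-of-fold* decision scores from an internal stratified
#' K-fold split of the reference — calibration never sees scores produced
#' by a model trained on the same cells.  Per-class reliability curves (10
#' equal-width bins) are stored in the training report.  Classes whose
#' scores are all identical get an identity-like fallback map and a
#' warning.
#'
#' @param model an uncalibrated `TrainedModel` from [fit_model].
#' @param ref the [ReferenceAtlas] the model was trained on.
#' @return the `TrainedModel` with calibrators attached.
#' @export
calibrate_model <- function(model, ref) {
  stopifnot(inherits(model, "TrainedModel"), inherits(ref, "ReferenceAtlas"))
  cfg <- model$config
  vocab <- model$label_vocabulary
  fold_id <- stratified_folds(ref$labels, cfg$folds,
                              cfg$seed + 104729L)  # split independent of CV
  S <- matrix(NA_real_, length(ref$labels), length(vocab),
              dimnames = list(ref$matrix$cell_ids, vocab))
  for (f in seq_len(cfg$folds)) {
    train <- fold_id != f
    norm_tr <- normalize_counts(subset_cells(ref$matrix, train),
                                model$target_sum)
    stats_tr <- subset_gene_stats(compute_gene_stats(norm_tr, 0L),
                                  model$gene_panel)
    Z_tr <- standardize_panel(norm_tr, model$gene_panel, stats_tr)
    ovr <- fit_ovr(Z_tr, ref$labels[train], vocab, cfg)
    norm_te <- normalize_counts(subset_cells(ref$matrix, !train),
                                model$target_sum)
    Z_te <- standardize_panel(norm_te, model$gene_panel, stats_tr)
    S[!train, ] <- decision_scores(ovr$weights, ovr$intercepts, Z_te)
  }
  calibrators <- vector("list", length(vocab))
  names(calibrators) <- vocab
  reliability <- vector("list", length(vocab))
  names(reliability) <- vocab
  for (k in seq_along(vocab)) {
    y <- as.integer(ref$labels == vocab[k])
    s <- S[, k]
    calibrators[[k]] <- fit_platt(s, y, vocab[k])
    p <- apply_platt(calibrators[[k]], s)
    reliability[[k]] <- reliability_curve(p, y, n_bins = 10L)
  }
  model$calibrators <- calibrators
  model$training_report$reliability <- reliability
  model
}

# Platt scaling: logistic fit of class membership on the decision score.
# A non-positive slope cannot arise for a working discriminant; if it does
# (degenerate scores), fall back to a clipped identity map.
fit_platt <- function(s, y, label = "") {
  if (length(unique(s)) < 2L || length(unique(y)) < 2L) {
    warning("degenerate decision scores for class '", label,
            "'; using identity-like calibration map")
    return(list(type = "identity"))
  }
  fit <- suppressWarnings(glm(y ~ s, family = binomial()))
  cf <- coef(fit)
  if (!all(is.finite(cf)) || cf[2L] <= 0) {
    warning("non-monotone calibration fit for class '", label,
            "'; using identity-like calibration map")
    return(list(type = "identity"))
  }
  list(type = "sigmoid", intercept = unname(cf[1L]), slope = unname(cf[2L]))
}

apply_platt <- function(cal, s) {
  if (cal$type == "identity") return(pmin(pmax((s + 1) / 2, 0), 1))
  1 / (1 + exp(-(cal$intercept + cal$slope * s)))
}

reliability_curve <- function(p, y, n_bins = 10L) {
  bins <- pmin(floor(p * n_bins) + 1L, n_bins)
  out <- data.frame(bin = seq_len(n_bins),
                    lower = (seq_len(n_bins) - 1) / n_bins,
                    upper = seq_len(n_bins) / n_bins)
  out$n <- tabulate(bins, n_bins)
  out$mean_predicted <- vapply(seq_len(n_bins), function(b)
    if (out$n[b] == 0) NA_real_ else mean(p[bins == b]), numeric(1))
  out$observed_frequency <- vapply(seq_len(n_bins), function(b)
    if (out$n[b] == 0) NA_real_ else mean(y[bins == b]), numeric(1))
  out
}

#' Expected calibration error
#'
#' Mean absolute gap between predicted certainty and observed accuracy over
#' `n_bins` equal-width certainty bins, weighted by bin occupancy.
#'
#' @param certainty predicted top-class probabilities in `[0, 1]`.
#' @param correct logical: was the predicted label correct?
#' @param n_bins number of equal-width bins (default 10).
#' @return scalar ECE in `[0, 1]`.
#' @export
expected_calibration_error <- function(certainty, correct, n_bins = 10L) {
  stopifnot(length(certainty) == length(correct))
  bins <- pmin(floor(certainty * n_bins) + 1L, n_bins)
  ece <- 0
  for (b in seq_len(n_bins)) {
    idx <- bins == b
    if (!any(idx)) next
    ece <- ece + sum(idx) / length(certainty) *
      abs(mean(certainty[idx]) - mean(correct[idx]))
  }
  ece
}
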