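test_that("weighted F1 matches hand-computed confusion matrices", {
  expect_equal(weighted_f1(c("A", "A", "B"), c("A", "A", "B")), 1.0)
  expect_equal(weighted_f1(c("A", "A", "B"), c("B", "B", "A")), 0.0)
  # F1_A = 2/3, F1_B = 2/3, weights (2/3, 1/3) -> 2/3
  expect_equal(weighted_f1(c("A", "A", "B"), c("A", "B", "B")), 2 / 3)
  expect_error(weighted_f1(character(0), character(0)), "empty")
  expect_error(weighted_f1(c("A"), c("A", "B")), "length")
})

test_that("weighted F1 agrees with the brute-force oracle on random labels", {
  set.seed(99)
  for (rep in seq_len(200)) {
    n <- sample(2:40, 1)
    k <- sample(2:5, 1)
    y_true <- sample(LETTERS[1:k], n, replace = TRUE)
    y_pred <- sample(LETTERS[1:k], n, replace = TRUE)
    expect_equal(weighted_f1(y_true, y_pred),
                 oracle_weighted_f1(y_true, y_pred))
  }
})

test_that("the solver agrees with libsvm on a separable binary problem", {
  set.seed(1)
  n <- 60; d <- 5
  X <- rbind(matrix(rnorm(n / 2 * d, 1.5), ncol = d),
             matrix(rnorm(n / 2 * d, -1.5), ncol = d))
  y <- rep(c(1, -1), each = n / 2)
  fit <- cellstateR:::.svm_dcd(X, y, rep(1.0, n), 1000L, 1e-6, 42L)
  sv <- e1071::svm(X, factor(y), kernel = "linear", cost = 1, scale = FALSE)
  w_ref <- drop(t(sv$coefs) %*% sv$SV)
  # same decision boundary up to the differing bias treatment
  my_scores <- drop(X %*% fit$w + fit$b)
  ref_scores <- drop(X %*% w_ref - sv$rho)
  expect_gt(stats::cor(my_scores, ref_scores), 0.99)
  expect_equal(sign(my_scores), sign(ref_scores))
  expect_true(fit$converged)
})

test_that("separable states are fit perfectly; degenerate inputs refused", {
  sim <- tiny_sim(n_states = 2, cells_per_state = 20, seed = 0)
  model <- fit_model(sim$atlas, cfg = model_config(seed = 0))
  expect_equal(model$training_report$training_weighted_f1, 1.0)
  one_class <- ReferenceAtlas(sim$atlas$matrix,
                              rep("only", length(sim$atlas$labels)))
  expect_error(fit_model(one_class), "at least 2 classes")
  few <- ReferenceAtlas(sim$atlas$matrix,
                        c(rep("A", 3), rep("B", 37)))
  expect_error(fit_model(few, cfg = model_config(folds = 5)),
               "fewer cells than folds.*A")
})

test_that("balanced class weights do not hurt minority recall", {
  set.seed(0)
  # 95:5 imbalanced separable blobs on 2 informative genes
  n_maj <- 190; n_min <- 10
  counts <- rbind(cbind(rpois(n_maj, 20), rpois(n_maj, 2), rpois(n_maj, 5)),
                  cbind(rpois(n_min, 2), rpois(n_min, 20), rpois(n_min, 5)))
  m <- ExpressionMatrix(counts, sprintf("c%d", seq_len(n_maj + n_min)),
                        c("gA", "gB", "gC"))
  ref <- ReferenceAtlas(m, c(rep("maj", n_maj), rep("min", n_min)))
  rec <- function(scheme) {
    mod <- fit_model(ref, cfg = model_config(class_weight = scheme,
                                             folds = 2, seed = 0))
    Z <- cellstateR:::standardize_panel(normalize_counts(m),
                                        mod$gene_panel, mod$gene_stats)
    pred <- ref$label_vocabulary[max.col(
      cellstateR:::decision_scores(mod$weights, mod$intercepts, Z),
      ties.method = "first")]
    mean(pred[ref$labels == "min"] == "min")
  }
  expect_gte(rec("balanced"), rec("uniform"))
})

test_that("cross-validation separates easy atlases from permuted labels", {
  sim <- tiny_sim(n_states = 3, cells_per_state = 40, seed = 2)
  cv <- cross_validate(sim$atlas, cfg = model_config(seed = 2))
  expect_equal(cv$aggregate, 1.0)
  expect_length(cv$fold_scores, 5)
  expect_equal(nrow(cv$per_class), 3)
  set.seed(2)
  perm <- ReferenceAtlas(sim$atlas$matrix, sample(sim$atlas$labels))
  cv_perm <- cross_validate(perm, cfg = model_config(seed = 2))
  expect_lt(cv_perm$aggregate, cv$aggregate)
  # K larger than the smallest class must refuse
  expect_error(cross_validate(sim$atlas, cfg = model_config(folds = 41)),
               "smaller number of folds")
})

test_that("cross-validation is reproducible for a fixed seed", {
  sim <- tiny_sim(n_states = 3, cells_per_state = 30, seed = 5)
  a <- cross_validate(sim$atlas, cfg = model_config(seed = 5))
  b <- cross_validate(sim$atlas, cfg = model_config(seed = 5))
  expect_identical(a, b)
})

test_that("grid tuning scores every point and breaks ties toward smaller C", {
  sim <- tiny_sim(n_states = 3, cells_per_state = 30, seed = 0)
  cfg1 <- model_config(seed = 0,
                       tuning_grid = list(C = 0.01,
                                          class_weight = "balanced",
                                          max_iter = 1000L))
  t1 <- tune_model(sim$atlas, cfg = cfg1)
  expect_equal(nrow(t1$grid), 1)
  expect_equal(t1$grid$score,
               cross_validate(sim$atlas, cfg = cfg1)$aggregate)
  cfg4 <- model_config(seed = 0,
                       tuning_grid = list(C = c(0.001, 0.01, 0.1, 1),
                                          class_weight = "balanced",
                                          max_iter = 1000L))
  t4 <- tune_model(sim$atlas, cfg = cfg4)
  expect_equal(nrow(t4$grid), 4)
  # easy data: every C performs comparably, tie goes to the smallest C
  expect_lt(diff(range(t4$grid$score)), 0.05)
  expect_equal(t4$best$C, 0.001)
  expect_error(model_config(tuning_grid = list(C = c(0.01, -1))), "C values")
})

test_that("calibration produces monotone maps and confident true-class probabilities", {
  sim <- tiny_sim(n_states = 3, cells_per_state = 50, seed = 0)
  model <- fit_calibrated(sim)
  for (cal in model$calibrators) {
    expect_equal(cal$type, "sigmoid")
    s <- seq(-3, 3, length.out = 50)
    expect_true(all(diff(cellstateR:::apply_platt(cal, s)) >= 0))
  }
  q <- simulate_query(sim, cells_per_state = 40, seed = 3)
  pred <- predict(model, q$matrix)
  probs <- as.matrix(pred[, paste0("prob.", model$label_vocabulary)])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-9)
  true_p <- probs[cbind(seq_len(nrow(probs)),
                        match(q$true_labels, model$label_vocabulary))]
  expect_gte(mean(true_p), 0.9)
  expect_false(is.null(model$training_report$reliability))
})

test_that("degenerate per-class scores fall back to an identity-like map", {
  s <- rep(0.2, 30)
  expect_warning(cal <- cellstateR:::fit_platt(s, rep(c(0L, 1L), 15)),
                 "identity-like")
  expect_equal(cal$type, "identity")
  p <- cellstateR:::apply_platt(cal, c(-2, 0, 1, 5))
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p) >= 0))
})
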