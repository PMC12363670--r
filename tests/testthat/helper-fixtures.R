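# Small in-code fixtures shared across test files.

# cells x genes count matrix with names
make_counts <- function(values, cells = NULL, genes = NULL) {
  m <- matrix(values$x, nrow = values$n, byrow = TRUE)
  ExpressionMatrix(m,
                   cells %||% sprintf("c%d", seq_len(nrow(m))),
                   genes %||% sprintf("g%d", seq_len(ncol(m))),
                   layer = "raw_counts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# quick separable simulated atlas for classifier tests
tiny_sim <- function(n_states = 3, cells_per_state = 50, n_genes = 120,
                     markers_per_state = 8, seed = 0, ...) {
  simulate_atlas(simulation_config(n_states = n_states,
                                   cells_per_state = cells_per_state,
                                   n_genes = n_genes,
                                   markers_per_state = markers_per_state,
                                   seed = seed, ...))
}

# independent brute-force weighted F1: explicit confusion-matrix loops,
# no shared code with the package implementation
oracle_weighted_f1 <- function(y_true, y_pred) {
  total <- 0
  for (cl in unique(y_true)) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(y_true)) {
      if (y_pred[i] == cl && y_true[i] == cl) tp <- tp + 1
      if (y_pred[i] == cl && y_true[i] != cl) fp <- fp + 1
      if (y_pred[i] != cl && y_true[i] == cl) fn <- fn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    total <- total + f1 * sum(y_true == cl) / length(y_true)
  }
  total
}

# train + calibrate on a SimulatedAtlas with given panel/config
fit_calibrated <- function(sim, gene_panel = NULL, cfg = model_config()) {
  calibrate_model(fit_model(sim$atlas, gene_panel, cfg), sim$atlas)
}
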