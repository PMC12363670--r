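#' Configuration of the synthetic atlas generator
#'
#' The generator emulates the statistical structure the annotation task
#' assumes: transcriptionally distinct states, each with a disjoint set of
#' marker genes whose mean expression is elevated `marker_fold_change`-fold
#' over baseline, negative-binomial counts with gene-level baseline means
#' drawn log-normal(0, 1), per-cell library-size variation, and (for
#' queries) optional multiplicative batch shift and novel states.
#'
#' @param n_states number of cell states.
#' @param cells_per_state scalar or per-state vector of cell counts.
#' @param n_genes total genes.
#' @param markers_per_state markers planted per state (disjoint across
#'   states).
#' @param marker_fold_change fold elevation of a marker's mean within its
#'   state (> 1, default 8).
#' @param dispersion negative-binomial inverse-dispersion `size` parameter
#'   (default 2; variance = mu + mu^2 / dispersion).
#' @param library_size_sigma log-normal sigma of per-cell depth factors
#'   (default 0.3).
#' @param seed integer seed; the generator is deterministic given the
#'   config.
#' @return object of class `SimulationConfig`.
#' @export
simulation_config <- function(n_states = 15L, cells_per_state = 200L,
                              n_genes = 2000L, markers_per_state = 30L,
                              marker_fold_change = 8,
                              dispersion = 2, library_size_sigma = 0.3,
                              seed = 0L) {
  if (marker_fold_change <= 1) stop("marker_fold_change must be > 1")
  if (n_states < 1L) stop("need at least one state")
  if (markers_per_state * n_states > n_genes)
    stop("infeasible marker allocation: ", markers_per_state, " markers x ",
         n_states, " states > ", n_genes, " genes")
  if (!length(cells_per_state) %in% c(1L, n_states))
    stop("cells_per_state must be a scalar or one entry per state")
  structure(list(n_states = as.integer(n_states),
                 cells_per_state = as.integer(rep_len(cells_per_state,
                                                      n_states)),
                 n_genes = as.integer(n_genes),
                 markers_per_state = as.integer(markers_per_state),
                 marker_fold_change = marker_fold_change,
                 dispersion = dispersion,
                 library_size_sigma = library_size_sigma,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Named simulation presets
#'
#' `"atlas15"` is the default training-scale atlas: 15 states at 200 cells
#' each except one rare state at 0.5% of cells (14 cells), 2000 genes, 30
#' markers per state, 8-fold marker elevation — the rare state exercises
#' balanced class weighting.
#'
#' @param name preset name.
#' @param seed seed passed through to the config.
#' @return a [simulation_config].
#' @export
simulation_preset <- function(name = c("atlas15"), seed = 0L) {
  name <- match.arg(name)
  switch(name,
         atlas15 = simulation_config(n_states = 15L,
                                     cells_per_state = c(rep(200L, 14L), 14L),
                                     n_genes = 2000L, markers_per_state = 30L,
                                     seed = seed))
}

state_names <- function(n, prefix = "state")
  sprintf("%s%02d", prefix, seq_len(n))

# per-gene baseline means and the disjoint state -> marker assignment
draw_gene_model <- function(cfg) {
  baseline <- rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1)
  marker_pool <- sample.int(cfg$n_genes,
                            cfg$markers_per_state * cfg$n_states)
  markers <- split(marker_pool,
                   rep(seq_len(cfg$n_states), each = cfg$markers_per_state))
  names(markers) <- state_names(cfg$n_states)
  list(baseline = baseline, markers = markers)
}

# NB counts for a block of cells sharing one state's mean profile
draw_state_counts <- function(n_cells, mu_gene, cfg) {
  depth <- rlnorm(n_cells, meanlog = 0, sdlog = cfg$library_size_sigma)
  mu <- outer(depth, mu_gene)
  matrix(rnbinom(length(mu), mu = mu, size = cfg$dispersion),
         nrow = n_cells, ncol = length(mu_gene))
}

#' Simulate a labeled reference atlas
#'
#' Counts are drawn `NB(mean = baseline[g] * F^{1[g marker of state]} *
#' depth[cell], size = dispersion)`.  Deterministic given the config seed.
#'
#' @param cfg a [simulation_config].
#' @return object of class `SimulatedAtlas`: list with `atlas` (a
#'   [ReferenceAtlas]), `marker_map` (data.frame state/gene of every
#'   planted marker), `baseline_mean`, and `config`.
#' @export
simulate_atlas <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  states <- state_names(cfg$n_states)
  with_seed(cfg$seed, {
    gm <- draw_gene_model(cfg)
    blocks <- vector("list", cfg$n_states)
    for (s in seq_len(cfg$n_states)) {
      mu_gene <- gm$baseline
      mu_gene[gm$markers[[s]]] <- mu_gene[gm$markers[[s]]] *
        cfg$marker_fold_change
      blocks[[s]] <- draw_state_counts(cfg$cells_per_state[s], mu_gene, cfg)
    }
  })
  counts <- do.call(rbind, blocks)
  labels <- rep(states, times = cfg$cells_per_state)
  gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  cell_ids <- sprintf("cell%05d", seq_len(nrow(counts)))
  m <- ExpressionMatrix(counts, cell_ids, gene_ids, layer = "raw_counts")
  marker_map <- do.call(rbind, lapply(states, function(s)
    data.frame(state = s, gene = gene_ids[sort(gm$markers[[s]])])))
  structure(list(atlas = ReferenceAtlas(m, labels),
                 marker_map = marker_map,
                 baseline_mean = gm$baseline,
                 config = cfg),
            class = "SimulatedAtlas")
}

#' Simulate a query dataset from an atlas generative model
#'
#' Cells are drawn from the same negative-binomial model as the atlas
#' (same baseline means and marker map), then optionally distorted by a
#' per-gene multiplicative batch shift `~ log-normal(0,
#' batch_shift_sigma)` and augmented with `novel_states` states carrying
#' fresh marker sets never seen in training.  True labels are returned
#' separately — they exist only for evaluation.
#'
#' @param sim a `SimulatedAtlas` from [simulate_atlas].
#' @param cells_per_state cells per state in the query (scalar or vector
#'   over atlas states then novel states).
#' @param batch_shift_sigma log-normal sigma of the per-gene batch factor
#'   (default 0 = no shift).
#' @param novel_states number of states absent from the atlas vocabulary
#'   (default 0).
#' @param permute_genes randomly permute the query's gene columns (the
#'   pipeline must be invariant to gene order).
#' @param seed query seed (independent of the atlas seed).
#' @return list with `matrix` (an [ExpressionMatrix] of raw counts) and
#'   `true_labels` (hidden labels; novel states are named `novel01`, ...).
#' @export
simulate_query <- function(sim, cells_per_state = 100L,
                           batch_shift_sigma = 0, novel_states = 0L,
                           permute_genes = FALSE, seed = 1L) {
  stopifnot(inherits(sim, "SimulatedAtlas"))
  cfg <- sim$config
  n_states <- cfg$n_states + novel_states
  cells_per_state <- as.integer(rep_len(cells_per_state, n_states))
  states <- c(state_names(cfg$n_states),
              state_names(novel_states, prefix = "novel"))
  atlas_markers <- lapply(state_names(cfg$n_states), function(s)
    match(sim$marker_map$gene[sim$marker_map$state == s],
          sprintf("g%05d", seq_len(cfg$n_genes))))
  with_seed(seed, {
    used <- unlist(atlas_markers)
    novel_markers <- list()
    if (novel_states > 0L) {
      free <- setdiff(seq_len(cfg$n_genes), used)
      if (length(free) < novel_states * cfg$markers_per_state)
        stop("not enough unused genes for novel-state markers")
      pool <- sample(free, novel_states * cfg$markers_per_state)
      novel_markers <- split(pool, rep(seq_len(novel_states),
                                       each = cfg$markers_per_state))
    }
    markers <- c(atlas_markers, novel_markers)
    batch <- if (batch_shift_sigma > 0)
      rlnorm(cfg$n_genes, 0, batch_shift_sigma) else rep(1, cfg$n_genes)
    blocks <- vector("list", n_states)
    for (s in seq_len(n_states)) {
      mu_gene <- sim$baseline_mean
      mu_gene[markers[[s]]] <- mu_gene[markers[[s]]] * cfg$marker_fold_change
      blocks[[s]] <- draw_state_counts(cells_per_state[s], mu_gene * batch,
                                       cfg)
    }
    counts <- do.call(rbind, blocks)
    gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))
    if (permute_genes) {
      perm <- sample.int(cfg$n_genes)
      counts <- counts[, perm, drop = FALSE]
      gene_ids <- gene_ids[perm]
    }
  })
  labels <- rep(states, times = cells_per_state)
  cell_ids <- sprintf("query%05d", seq_len(nrow(counts)))
  list(matrix = ExpressionMatrix(counts, cell_ids, gene_ids,
                                 layer = "raw_counts"),
       true_labels = labels)
}
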