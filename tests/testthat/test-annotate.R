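test_that("certainty binning follows the half-open boundary convention", {
  expect_equal(bin_certainty(0.75), "high")
  expect_equal(bin_certainty(0.5), "medium")
  expect_equal(bin_certainty(c(0.29, 0.30, 0.70)),
               c("low", "medium", "high"))
  expect_equal(bin_certainty(c(0, 1)), c("low", "high"))
  expect_error(bin_certainty(1.2), "\\[0, 1\\]")
  expect_error(bin_certainty(-0.1), "\\[0, 1\\]")
  expect_error(certainty_thresholds(0.8, 0.3), "tau_low < tau_high")
})

test_that("binning is monotone and raising tau_high never promotes a cell", {
  set.seed(3)
  s <- sort(runif(200))
  bins <- bin_certainty(s)
  rank <- c(low = 1, medium = 2, high = 3)[bins]
  expect_true(all(diff(rank) >= 0))
  higher <- bin_certainty(s, certainty_thresholds(0.3, 0.8))
  expect_true(all(!(bins == "medium" & higher == "high")))
})

test_that("prediction is deterministic and duplicates map identically", {
  sim <- tiny_sim(seed = 6)
  model <- fit_calibrated(sim)
  q <- simulate_query(sim, cells_per_state = 2, seed = 8)
  one <- cellstateR:::subset_cells(q$matrix, c(TRUE, rep(FALSE, 5)))
  five <- ExpressionMatrix(one$values[rep(1, 5), , drop = FALSE],
                           sprintf("dup%d", 1:5), one$gene_ids)
  pred <- predict(model, five)
  expect_equal(nrow(unique(pred[, -1])), 1)
  expect_identical(predict(model, five), pred)
})

test_that("prediction is invariant to gene-column and cell-row permutations", {
  sim <- tiny_sim(seed = 10)
  model <- fit_calibrated(sim)
  q <- simulate_query(sim, cells_per_state = 10, seed = 11)
  base <- predict(model, q$matrix)
  set.seed(1)
  gperm <- sample.int(length(q$matrix$gene_ids))
  shuffled <- ExpressionMatrix(q$matrix$values[, gperm],
                               q$matrix$cell_ids,
                               q$matrix$gene_ids[gperm])
  expect_identical(predict(model, shuffled), base)
  cperm <- sample.int(length(q$matrix$cell_ids))
  reordered <- ExpressionMatrix(q$matrix$values[cperm, ],
                                q$matrix$cell_ids[cperm],
                                q$matrix$gene_ids)
  got <- predict(model, reordered)
  realigned <- got[match(base$cell_id, got$cell_id), ]
  rownames(realigned) <- NULL
  expect_equal(realigned, base)
})

test_that("prediction summaries count bins and states correctly", {
  records <- data.frame(cell_id = sprintf("c%d", 1:10),
                        predicted_label = rep(c("A", "B"), 5),
                        certainty = c(0.1, 0.2, rep(0.5, 4), rep(0.8, 4)),
                        bin = bin_certainty(c(0.1, 0.2, rep(0.5, 4),
                                              rep(0.8, 4))))
  s <- summarize_predictions(records)
  expect_equal(s$bin_counts, c(low = 2L, medium = 4L, high = 4L))
  expect_equal(s$bin_percent, c(low = 20, medium = 40, high = 40))
  expect_equal(sum(s$bin_counts), 10L)
  expect_equal(nrow(s$per_state), 2)
  expect_equal(max(s$cdf$cumulative_fraction), 1)
  one_state <- records
  one_state$predicted_label <- "A"
  expect_equal(nrow(summarize_predictions(one_state)$per_state), 1)
  expect_error(summarize_predictions(records[0, ]), "at least one")
})

test_that("summary percentages agree with a brute-force recount", {
  set.seed(21)
  for (rep in seq_len(100)) {
    n <- sample(1:50, 1)
    cert <- runif(n)
    records <- data.frame(cell_id = sprintf("c%d", seq_len(n)),
                          predicted_label = "A", certainty = cert,
                          bin = bin_certainty(cert))
    s <- summarize_predictions(records)
    recount <- c(low = sum(cert < 0.3),
                 medium = sum(cert >= 0.3 & cert < 0.7),
                 high = sum(cert >= 0.7))
    expect_equal(unname(s$bin_counts), unname(recount))
    expect_equal(unname(s$bin_percent), unname(100 * recount / n))
  }
})

test_that("planted markers surface in the explanation tables", {
  for (seed in 1:3) {
    sim <- tiny_sim(n_states = 3, cells_per_state = 60, n_genes = 200,
                    markers_per_state = 6, seed = seed)
    model <- fit_calibrated(sim)
    q <- simulate_query(sim, cells_per_state = 40, seed = seed + 100)
    records <- predict(model, q$matrix)
    tabs <- top_explainable_genes(model, q$matrix, records, n_top = 10)
    for (st in names(tabs)) {
      planted <- sim$marker_map$gene[sim$marker_map$state == st]
      expect_gt(length(intersect(tabs[[st]]$gene, planted)), 0)
      expect_true(all(tabs[[st]]$mean_attribution > 0))
      expect_true(all(diff(tabs[[st]]$mean_attribution) <= 0))
      expect_lte(nrow(tabs[[st]]), 10)
    }
  }
})

test_that("explanation tables respect n_top and zero-weight genes", {
  sim <- tiny_sim(seed = 12)
  model <- fit_calibrated(sim)
  q <- simulate_query(sim, cells_per_state = 10, seed = 13)
  records <- predict(model, q$matrix)
  empty <- top_explainable_genes(model, q$matrix, records, n_top = 0)
  expect_true(all(vapply(empty, nrow, integer(1)) == 0))
  # force one gene's weight to zero for the first state: it can never appear
  st <- model$label_vocabulary[1]
  gene0 <- model$gene_panel[5]
  model$weights[1, 5] <- 0
  tabs <- top_explainable_genes(model, q$matrix, records,
                                n_top = length(model$gene_panel))
  if (st %in% names(tabs))
    expect_false(gene0 %in% tabs[[st]]$gene)
})

test_that("states with zero predicted cells are omitted with a warning", {
  sim <- tiny_sim(seed = 14)
  model <- fit_calibrated(sim)
  q <- simulate_query(sim, cells_per_state = c(10, 10, 0), seed = 15)
  records <- predict(model, q$matrix)
  records <- records[records$predicted_label != "state03", ]
  expect_warning(tabs <- top_explainable_genes(model, q$matrix, records),
                 "zero predicted cells.*state03")
  expect_false("state03" %in% names(tabs))
})
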