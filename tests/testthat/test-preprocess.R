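test_that("normalization matches its closed form", {
  m <- make_counts(list(x = c(1, 1, 0, 2, 0, 8), n = 2),
                   genes = c("g1", "g2", "g3"))
  n4 <- normalize_counts(m, target_sum = 4)
  # cell 1: counts (1,1,0) scaled to sum 4 -> (2,2,0) -> log1p
  expect_equal(as_dense(n4)[1, ], c(g1 = log(3), g2 = log(3), g3 = 0))
  n10 <- normalize_counts(m, target_sum = 10)
  # cell 2: (2,0,8) -> (2,0,8) -> (log 3, 0, log 9)
  expect_equal(as_dense(n10)[2, ], c(g1 = log(3), g2 = 0, g3 = log(9)))
  expect_equal(n10$layer, "normalized")
  expect_error(normalize_counts(n10), "raw_counts")
  expect_error(normalize_counts(m, target_sum = -1), "positive")
})

test_that("all-zero cells stay zero with a single warning", {
  m <- make_counts(list(x = c(0, 0, 1, 3), n = 2))
  expect_warning(out <- normalize_counts(m), "zero total counts")
  expect_equal(as_dense(out)[1, ], c(g1 = 0, g2 = 0))
})

test_that("normalization is invariant to per-cell count scaling", {
  set.seed(11)
  counts <- matrix(rpois(80, 3) + 1, nrow = 8)
  m1 <- ExpressionMatrix(counts, sprintf("c%d", 1:8), sprintf("g%d", 1:10))
  m2 <- ExpressionMatrix(counts * 7L, m1$cell_ids, m1$gene_ids)
  expect_equal(as_dense(normalize_counts(m1)), as_dense(normalize_counts(m2)))
})

test_that("HVG flags pick top dispersion with lexicographic ties", {
  # 4-cell hand-built matrix; dispersion = var/mean of the normalized layer
  norm <- structure(list(values = cbind(g1 = c(0, 4, 0, 4),
                                        g2 = c(2, 2, 2.2, 1.8),
                                        g3 = c(4, 0, 4, 0)),
                         cell_ids = sprintf("c%d", 1:4),
                         gene_ids = c("g1", "g2", "g3"),
                         layer = "normalized"),
                    class = "ExpressionMatrix")
  disp <- apply(norm$values, 2, stats::var) / colMeans(norm$values)
  expect_true(all(disp[c("g1", "g3")] > disp["g2"]))
  flags <- flag_hvgs(norm, n_top = 2)
  expect_equal(flags, c(g1 = TRUE, g2 = FALSE, g3 = TRUE))
  # g1 and g3 tie exactly; n_top = 1 keeps the lexicographically smaller
  expect_equal(flag_hvgs(norm, n_top = 1),
               c(g1 = TRUE, g2 = FALSE, g3 = FALSE))
  expect_equal(sum(flag_hvgs(norm, n_top = 0)), 0)
  expect_warning(all_flagged <- flag_hvgs(norm, n_top = 10), "exceeds")
  expect_true(all(all_flagged))
})

test_that("constant genes are never flagged while any gene varies", {
  norm <- structure(list(values = cbind(flat = rep(3, 5),
                                        varies = c(0, 1, 5, 0, 2)),
                         cell_ids = sprintf("c%d", 1:5),
                         gene_ids = c("flat", "varies"),
                         layer = "normalized"),
                    class = "ExpressionMatrix")
  expect_equal(flag_hvgs(norm, n_top = 1),
               c(flat = FALSE, varies = TRUE))
})

test_that("gene harmonization aligns, zero-fills, and enforces the threshold", {
  set.seed(5)
  counts <- matrix(rpois(30, 2), nrow = 5)
  q <- ExpressionMatrix(counts, sprintf("c%d", 1:5), sprintf("g%d", 1:6))
  # permutation: values reordered, nothing zero-filled
  perm <- c("g4", "g1", "g6", "g2", "g5", "g3")
  h <- harmonize_genes(q, perm)
  expect_equal(attr(h, "missing_fraction"), 0)
  expect_equal(as_dense(h), as_dense(q)[, perm])
  # absent gene becomes a zero column at its position
  h2 <- harmonize_genes(q, c("g1", "gX", "g2"))
  expect_equal(attr(h2, "missing_fraction"), 1 / 3)
  expect_equal(unname(as_dense(h2)[, "gX"]), rep(0, 5))
  # 60% missing exceeds the default 50% threshold
  expect_error(harmonize_genes(q, c("g1", "g2", "a", "b", "c")),
               "60% .*missing")
  # idempotence once aligned
  expect_equal(as_dense(harmonize_genes(h, perm)), as_dense(h))
})

test_that("standardization uses reference statistics and clips", {
  stats <- structure(list(gene_ids = c("g1", "g2", "g3"),
                          mean = c(1, 0, 2), sd = c(2, 0.1, 0)),
                     class = "GeneStats")
  norm <- structure(list(values = rbind(c(5, 10, 7), c(1, 0, 2)),
                         cell_ids = c("c1", "c2"),
                         gene_ids = c("g1", "g2", "g3"),
                         layer = "normalized"),
                    class = "ExpressionMatrix")
  z <- as_dense(standardize(norm, stats))
  expect_equal(unname(z[1, ]), c(2, 10, 0))   # (5-1)/2; clipped 100 -> 10; zero-sd -> 0
  expect_equal(unname(z[2, ]), c(0, 0, 0))    # x == reference mean -> 0
  bad <- structure(list(gene_ids = c("g2", "g1", "g3"),
                        mean = c(0, 0, 0), sd = c(1, 1, 1)),
                   class = "GeneStats")
  expect_error(standardize(norm, bad), "gene order mismatch")
})

test_that("reference gene stats match direct computation on sparse input", {
  set.seed(2)
  counts <- matrix(rpois(200, 0.5), nrow = 20)
  m <- ExpressionMatrix(counts, sprintf("c%d", 1:20), sprintf("g%d", 1:10))
  norm <- normalize_counts(m)
  gs <- compute_gene_stats(norm, n_top_hvg = 3)
  dense <- as_dense(norm)
  expect_equal(gs$mean, unname(colMeans(dense)))
  expect_equal(gs$sd, unname(apply(dense, 2, stats::sd)), tolerance = 1e-12)
  expect_equal(sum(gs$hvg), 3)
  sub <- subset_gene_stats(gs, c("g5", "g2"))
  expect_equal(sub$mean, gs$mean[c(5, 2)])
  expect_error(subset_gene_stats(gs, "gZ"), "absent")
})
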