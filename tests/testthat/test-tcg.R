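test_that("lagged edge weight matches its closed form", {
  z <- rep(0, 10)
  expect_equal(lagged_edge_weight(z, z, 1), 0)

  # unstandardized constant ones: sum of 4 products over 4 = 1
  ones <- rep(1, 5)
  expect_equal(lagged_edge_weight(ones, ones, 1, standardize = FALSE), 1)

  # a 1-step-delayed copy has lag-1 weight near 1 after standardization
  a <- with_seed_test(2, rnorm(200))
  b <- c(0, a[-200])
  w <- lagged_edge_weight(a, b, 1)
  expect_gte(w, 0.95)
  expect_lte(w, 1.0)

  expect_error(lagged_edge_weight(a, b, 200), "lag")
})

test_that("null panels survive thresholding almost nowhere", {
  p <- generate_panel(panel_spec(6, 500, seed = 31))
  g <- build_tcg(p, threshold = 0.3)
  expect_lte(mean(g$adjacency != 0), 0.05)
})

test_that("a planted edge is recovered as the dominant adjacency entry", {
  pe <- data.frame(source = 1, target = 2, coef = 0.9)
  p <- generate_panel(panel_spec(6, 500, planted_edges = pe,
                                 noise_sd = 0.1, seed = 32))
  g <- build_tcg(p, threshold = 0.3)
  expect_true(g$adjacency["V1", "V2"] != 0)
  expect_equal(max(abs(g$adjacency)), abs(g$adjacency["V1", "V2"]))
  # normalization bound: all weights in [-1, 1], one attains magnitude 1
  expect_true(all(abs(g$edges$normalized_weight) <= 1 + 1e-12))
  expect_equal(max(abs(g$edges$normalized_weight)), 1)
})

test_that("raising the threshold never adds edges", {
  p <- generate_panel(panel_spec(5, 300,
                                 planted_edges = data.frame(
                                   source = c(1, 2), target = c(2, 3),
                                   coef = 0.6),
                                 noise_sd = 0.5, seed = 33))
  prev <- NULL
  for (th in c(0.1, 0.3, 0.5, 0.7)) {
    edges <- which(build_tcg(p, threshold = th,
                             min_edge_weight = 0)$adjacency != 0)
    if (!is.null(prev)) expect_true(all(edges %in% prev))
    prev <- edges
  }
})

test_that("graph features match hand enumeration on a 3-node chain", {
  f <- extract_tcg_features(chain_tcg())
  expect_equal(f$in_degree, c(0, 1, 1))
  expect_equal(f$out_degree, c(1, 1, 0))
  expect_equal(f$chain_length, c(2, 1, 0))
  expect_equal(f$weighted_degree, c(0.8, 1.4, 0.6))
  expect_equal(f$scc_size, c(1, 1, 1))
  expect_equal(f$motif_2chains, c(0, 1, 0))

  # empty adjacency: all-zero features, singleton components
  empty <- chain_tcg()
  empty$adjacency[] <- 0
  fe <- extract_tcg_features(empty)
  expect_true(all(fe$in_degree == 0 & fe$out_degree == 0 &
                    fe$weighted_degree == 0 & fe$chain_length == 0))
  expect_equal(fe$scc_size, rep(1, 3))
})

test_that("weighted degree is the absolute incident weight sum", {
  g <- chain_tcg()
  g$adjacency[] <- 0
  g$adjacency["a", "b"] <- 0.5
  g$adjacency["c", "b"] <- -0.4
  expect_equal(extract_tcg_features(g)$weighted_degree[2], 0.9)
})

test_that("node matrix concatenates features deterministically", {
  tab <- separable_table(n = 120, seed = 5)
  g <- tcg_from_table(tab, window = 32)
  feats <- extract_tcg_features(g)
  K <- build_node_matrix(tab, feats)
  n_f <- length(setdiff(names(tab), "event"))
  expect_equal(ncol(K) - 1, n_f + (ncol(feats) - 1))
  expect_identical(K, build_node_matrix(tab, feats))

  # zero TCG features pad with zeros
  feats0 <- feats
  feats0[setdiff(names(feats0), "node")] <- 0
  K0 <- build_node_matrix(tab, feats0)
  expect_true(all(as.matrix(K0[grep("^tcg_", names(K0))]) == 0))

  bad <- feats[-1, ]
  expect_error(build_node_matrix(tab, bad), "match")
})

test_that("planted-edge ranking separates causal from null pairs", {
  # reduced-size recovery check; the full 20-seed AUC run lives in the
  # acceptance suite
  pe <- data.frame(source = c(1, 2, 3, 4), target = c(2, 3, 4, 5),
                   coef = 0.8)
  aucs <- vapply(1:5, function(s) {
    p <- generate_panel(panel_spec(6, 300, planted_edges = pe,
                                   noise_sd = 0.2, seed = s))
    e <- build_tcg(p)$edges
    planted <- paste(e$source, e$target) %in%
      paste(paste0("V", pe$source), paste0("V", pe$target))
    r <- rank(abs(e$normalized_weight))
    (mean(r[planted]) - (sum(planted) + 1) / 2) / sum(!planted)
  }, numeric(1))
  expect_gte(min(aucs), 0.9)
})

test_that("short panels and bad arguments are rejected", {
  p <- generate_panel(panel_spec(3, 30, seed = 1))
  expect_error(build_tcg(p[1:4, ], max_lag = 3), "short")
  expect_error(build_tcg(p, threshold = 0), "threshold")
})
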