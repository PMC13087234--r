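test_that("mean-centering normalization zeroes column means", {
  expect_equal(mcn(matrix(c(1, 3, 3, 5), 2)), matrix(c(-1, 1, -1, 1), 2))
  x <- with_seed_test(1, matrix(rnorm(50), 10))
  expect_true(all(abs(colMeans(mcn(x))) < 1e-12))
  expect_equal(mcn(matrix(c(4, 7), 1)), matrix(c(0, 0), 1))
})

test_that("EHR graph construction follows cosine k-NN with self-loops", {
  K <- with_seed_test(3, matrix(rnorm(50), 10, 5))
  g0 <- build_ehr_graph(K, 0)
  expect_equal(g0$adjacency, diag(1, 10))

  # duplicated rows are mutual nearest neighbours
  K2 <- rbind(c(1, 0), c(0, 1), c(1, 0.02), c(-1, 3), c(2, -1))
  g1 <- build_ehr_graph(K2, 1)
  expect_equal(g1$adjacency[1, 3], 1)
  expect_equal(g1$adjacency[3, 1], 1)

  # degrees after symmetrization lie in [k, n - 1]
  K3 <- with_seed_test(5, matrix(rnorm(25), 5, 5))
  g2 <- build_ehr_graph(K3, 2)
  deg <- rowSums(g2$adjacency) - 1
  expect_true(all(deg >= 2 & deg <= 4))
  expect_true(isSymmetric(g2$adjacency))

  expect_error(build_ehr_graph(K3, 5), "k_neighbours")
})

test_that("forward pass produces normalized class probabilities", {
  K <- with_seed_test(11, matrix(rnorm(40), 10, 4))
  graph <- build_ehr_graph(K, 3)
  params <- gnn_params(4, hidden = 8, layers = 2, seed = 2)

  pred <- gnn_forward(graph, params)
  expect_equal(pred$prob_normal + pred$prob_event, rep(1, 10))
  expect_true(all(pred$prob_normal >= 0 & pred$prob_event >= 0))

  # all-zero parameters give symmetric logits
  zero <- unflatten_params(rep(0, length(flatten_params(params))), params)
  pz <- gnn_forward(graph, zero)
  expect_equal(pz$prob_normal, rep(0.5, 10))

  # MCN keeps per-column hidden means at zero after every layer
  cache <- gnn_forward(graph, params, cache = TRUE)
  for (l in 2:length(cache$Hs)) {
    expect_true(all(abs(colMeans(cache$Hs[[l]])) < 1e-10))
  }
})

test_that("mean neighbourhood aggregation matches hand arithmetic", {
  # 2 fully connected nodes, 1-dim features 1 and 3, identity weights:
  # each node's aggregated message is the mean 2 before activation
  graph <- structure(list(features = matrix(c(1, 3), 2, 1),
                          adjacency = matrix(1, 2, 2), labels = c(0L, 1L)),
                     class = "ehr_graph")
  params <- gnn_params(1, hidden = 1, layers = 2, seed = 1)
  params$W_in <- matrix(1)
  params$b_in <- 0
  params$W1 <- matrix(1)
  params$b1 <- 0
  cache <- gnn_forward(graph, params, cache = TRUE)
  expect_equal(as.numeric(cache$Ss[[1]]), c(2, 2))
  expect_equal(as.numeric(pmax(cache$Zs[[1]], 0)), c(2, 2))
})

test_that("mean-centering counters over-smoothing across deep stacks", {
  K <- with_seed_test(21, matrix(rnorm(200), 40, 5))
  graph <- build_ehr_graph(K, 6)
  params <- gnn_params(5, hidden = 16, layers = 4, seed = 3)
  # over-smoothing = nodes becoming indistinguishable relative to the
  # representation's scale, so compare across-node variance normalized by
  # mean squared magnitude (the residual path inflates raw scale without
  # separating nodes)
  node_var <- function(H) mean(apply(H, 2, stats::var)) / mean(H^2)
  with_mcn <- gnn_forward(graph, params, use_mcn = TRUE, cache = TRUE)
  without <- gnn_forward(graph, params, use_mcn = FALSE, cache = TRUE)
  expect_gte(node_var(with_mcn$Hs[[5]]), node_var(without$Hs[[5]]))
})

test_that("training is seeded-deterministic with a gradient per parameter", {
  tab <- separable_table(n = 120, seed = 9)
  cfg <- train_config(epochs = 3, seed = 4)
  f1 <- train_local(tab, cfg, hidden = 8, layers = 2, k_neighbours = 4)
  f2 <- train_local(tab, cfg, hidden = 8, layers = 2, k_neighbours = 4)
  expect_identical(f1$gradient, f2$gradient)
  expect_equal(length(f1$gradient), length(flatten_params(f1$params)))
  expect_equal(length(f1$train_idx), floor(0.8 * 120))

  flat <- flatten_params(f1$params)
  expect_equal(unflatten_params(flat, f1$params), f1$params)

  single <- tab
  single$event <- 0L
  expect_error(train_local(single, cfg), "single class")
})

test_that("loss decreases over early epochs on separable data", {
  drops <- vapply(1:5, function(s) {
    tab <- separable_table(n = 150, seed = 100 + s)
    fit <- train_local(tab, train_config(epochs = 10, seed = s),
                       hidden = 8, layers = 2, k_neighbours = 4)
    fit$metrics$loss[1] - fit$metrics$loss[10]
  }, numeric(1))
  expect_gte(mean(drops), 0)
})

test_that("a separable cohort is learned to high training accuracy", {
  tab <- separable_table(n = 500, seed = 7)
  fit <- train_local(tab, train_config(epochs = 50, seed = 1))
  expect_gte(fit$metrics$train_accuracy, 0.95)
})
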