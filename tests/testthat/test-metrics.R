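# Independent literal-loop oracles, coded directly from the metric
# definitions, against which the vectorized implementations are checked.

oracle_continual <- function(alpha, Tn) {
  a <- function(v, s) alpha[v + 1, s]  # alpha has rows v = 0..Tn
  ret <- 0
  forg <- 0
  back <- 0
  for (s in 1:(Tn - 1)) {
    ret <- ret + a(Tn, s)
    m <- -Inf
    for (v in 0:(s - 1)) m <- max(m, a(v, s))
    forg <- forg + (m - a(Tn, s))
    back <- back + (a(Tn, s) - a(s, s))
  }
  fwd <- 0
  if (Tn >= 3) for (s in 2:(Tn - 1)) fwd <- fwd + (a(s - 1, s) - a(0, s))
  c(ret, forg, fwd, back) / (Tn - 1)
}

oracle_classification <- function(TP, TN, FP, FN) {
  div <- function(n, d) if (d > 0) n / d else NA_real_
  pr <- div(TP, TP + FP)
  rc <- div(TP, TP + FN)
  c(accuracy = div(TP + TN, TP + TN + FP + FN), precision = pr, recall = rc,
    f_measure = if (!is.na(pr) && !is.na(rc) && pr + rc > 0) {
      2 * pr * rc / (pr + rc)
    } else {
      NA_real_
    },
    ppv = pr, npv = div(TN, TN + FN), fnr = div(FN, FN + TP),
    fpr = div(FP, FP + TN))
}

oracle_sil_dbi <- function(pts, lab) {
  n <- nrow(pts)
  d <- function(i, j) sqrt(sum((pts[i, ] - pts[j, ])^2))
  labs <- sort(unique(lab))
  sil <- numeric(n)
  for (i in 1:n) {
    own <- setdiff(which(lab == lab[i]), i)
    if (!length(own)) next
    Int <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    Near <- Inf
    for (l in setdiff(labs, lab[i])) {
      Near <- min(Near, mean(vapply(which(lab == l), function(j) d(i, j),
                                    numeric(1))))
    }
    sil[i] <- (Near - Int) / max(Int, Near)
  }
  cent <- lapply(labs, function(l) colMeans(pts[lab == l, , drop = FALSE]))
  Cu <- vapply(seq_along(labs), function(k) {
    mean(vapply(which(lab == labs[k]), function(i) {
      sqrt(sum((pts[i, ] - cent[[k]])^2))
    }, numeric(1)))
  }, numeric(1))
  db <- 0
  for (b in seq_along(labs)) {
    best <- -Inf
    for (cc in setdiff(seq_along(labs), b)) {
      Sp <- sqrt(sum((cent[[b]] - cent[[cc]])^2))
      best <- max(best, if (Sp == 0) Inf else (Cu[b] + Cu[cc]) / Sp)
    }
    db <- db + best
  }
  c(mean(sil), db / length(labs))
}

test_that("continual metrics match hand values and the loop oracle", {
  Tn <- 3
  const <- matrix(1, Tn + 1, Tn)
  m <- continual_metrics(const, Tn)
  expect_equal(m$retained_accuracy, 1)
  expect_equal(m$average_forgetting, 0)
  expect_equal(m$backward_transfer, 0)

  alpha <- matrix(0.5, Tn + 1, Tn)
  alpha[Tn + 1, 1] <- 0.8
  alpha[Tn + 1, 2] <- 0.9
  expect_equal(continual_metrics(alpha, Tn)$retained_accuracy, 0.85)

  for (trial in 1:100) {
    Tn_r <- sample(2:6, 1)
    A <- with_seed_test(trial, matrix(runif((Tn_r + 1) * Tn_r),
                                      Tn_r + 1, Tn_r))
    got <- continual_metrics(A, Tn_r)
    want <- oracle_continual(A, Tn_r)
    expect_equal(got$retained_accuracy, want[1], tolerance = 1e-12)
    expect_equal(got$average_forgetting, want[2], tolerance = 1e-12)
    if (Tn_r >= 3) expect_equal(got$forward_transfer, want[3],
                                tolerance = 1e-12)
    expect_equal(got$backward_transfer, want[4], tolerance = 1e-12)
  }
  expect_error(continual_metrics(matrix(1, 2, 1), 1), "Tn")
})

test_that("forgetting is nonnegative on monotone-degrading schedules", {
  for (trial in 1:20) {
    Tn <- 4
    A <- with_seed_test(200 + trial, {
      m <- matrix(runif((Tn + 1) * Tn), Tn + 1, Tn)
      # degrade the final row below the best earlier accuracy per task
      for (s in 1:(Tn - 1)) {
        m[Tn + 1, s] <- min(m[Tn + 1, s], max(m[1:s, s]))
      }
      m
    })
    expect_gte(continual_metrics(A, Tn)$average_forgetting, 0)
  }
})

test_that("classification metrics match hand values and the loop oracle", {
  m <- classification_metrics(1, 1, 0, 0)
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f_measure")]),
               c(accuracy = 1, precision = 1, recall = 1, f_measure = 1))

  m2 <- classification_metrics(8, 8, 2, 2)
  expect_equal(m2$precision, 0.8)
  expect_equal(m2$recall, 0.8)
  expect_equal(m2$f_measure, 0.8)
  expect_equal(m2$accuracy, 0.8)

  expect_true(is.na(classification_metrics(0, 5, 0, 3)$precision))

  for (trial in 1:100) {
    cc <- with_seed_test(300 + trial, sample(0:20, 4, replace = TRUE))
    got <- classification_metrics(cc[1], cc[2], cc[3], cc[4])
    want <- oracle_classification(cc[1], cc[2], cc[3], cc[4])
    expect_equal(unlist(got), want, tolerance = 1e-12)
  }
})

test_that("error, fairness and convergence metrics behave as defined", {
  expect_equal(regression_and_fairness(allocations = c(3, 3, 3))$jain_index,
               1)
  expect_equal(regression_and_fairness(
    allocations = c(1, 0, 0, 0))$jain_index, 0.25)

  r <- regression_and_fairness(predictions = c(1, 2), actuals = c(1, 2))
  expect_equal(r$mse, 0)
  expect_equal(r$mae, 0)

  lcr <- regression_and_fairness(loss_start = 1, loss_end = 0.2,
                                 rounds_start = 0, rounds_end = 8)
  expect_equal(lcr$loss_convergence_rate, -0.1)

  # Jain bounds 1/n <= J <= 1 over random nonnegative allocations
  for (trial in 1:50) {
    x <- with_seed_test(400 + trial, runif(sample(2:10, 1)))
    j <- regression_and_fairness(allocations = x)$jain_index
    expect_gte(j, 1 / length(x) - 1e-12)
    expect_lte(j, 1 + 1e-12)
  }
  expect_error(regression_and_fairness(allocations = c(0, 0)), "allocations")
})

test_that("cluster quality matches hand values and the loop oracle", {
  pts <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  q <- cluster_quality(pts, c(1, 1, 2, 2))
  expect_equal(q$davies_bouldin, 0.01)

  tight <- with_seed_test(5, rbind(matrix(rnorm(40, 0, 0.01), 20, 2),
                                   matrix(rnorm(40, 10, 0.01), 20, 2)))
  expect_gte(cluster_quality(tight, rep(1:2, each = 20))$silhouette, 0.99)

  same <- matrix(1, 6, 2)
  expect_equal(cluster_quality(same, rep(1:2, 3))$davies_bouldin, Inf)

  for (trial in 1:30) {
    pts_r <- with_seed_test(500 + trial, matrix(rnorm(30), 10, 3))
    lab <- with_seed_test(600 + trial, sample(1:3, 10, replace = TRUE))
    if (length(unique(lab)) < 2) next
    got <- cluster_quality(pts_r, lab)
    want <- oracle_sil_dbi(pts_r, lab)
    expect_equal(got$silhouette, want[1], tolerance = 1e-12)
    expect_equal(got$davies_bouldin, want[2], tolerance = 1e-12)
  }
})

test_that("security metrics weight the contribution components", {
  expect_equal(security_metrics(rep(100, 5))$security_level, 100)
  expect_equal(security_metrics(rep(90, 5))$security_level, 90)
  s <- security_metrics(c(80, 90, 100, 70, 60),
                        weights = c(0.4, 0.2, 0.2, 0.1, 0.1),
                        successful_attacks = 0, total_attacks = 50)
  expect_equal(s$security_level, 0.4 * 80 + 0.2 * 90 + 0.2 * 100 + 7 + 6)
  expect_equal(s$attack_level, 0)
  expect_error(security_metrics(rep(50, 5), weights = rep(0.3, 5)), "sum")
})
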