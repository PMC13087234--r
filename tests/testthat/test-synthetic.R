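test_that("cohort generation is deterministic and respects the missing rate", {
  spec <- cohort_spec(100, missing_rate = 0, seed = 3)
  tab <- generate_cohort(spec)
  expect_equal(nrow(tab), 100)
  expect_equal(sum(is.na(tab)), 0)

  # identical spec + seed -> byte-identical CSV serializations
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(generate_cohort(spec), f1)
  write_cohort_csv(generate_cohort(spec), f2)
  expect_identical(readLines(f1), readLines(f2))

  # binomial oracle on the observed missing fraction at rate 0.1
  big <- generate_cohort(cohort_spec(10000, missing_rate = 0.1, seed = 5))
  feats <- setdiff(names(big), "event")
  frac <- sum(is.na(big[feats])) / (10000 * length(feats))
  expect_gte(frac, 0.09)
  expect_lte(frac, 0.11)
  expect_equal(sum(is.na(big$event)), 0)
})

test_that("label prevalence matches the logistic model's expectation", {
  spec <- cohort_spec(10000, missing_rate = 0, seed = 11)
  tab <- generate_cohort(spec)
  # independent oracle: Monte Carlo expectation of plogis(eta) drawn straight
  # from the spec's feature distributions
  expected <- with_seed_test(999, {
    n <- 200000
    eta <- spec$label_model$intercept
    for (nm in names(spec$numeric_features)) {
      f <- spec$numeric_features[[nm]]
      b <- spec$label_model$coef[nm]
      if (!is.na(b)) eta <- eta + b * rnorm(n, f$mean, f$sd)
    }
    for (term in names(spec$label_model$coef)) {
      if (grepl("=", term)) {
        parts <- strsplit(term, "=")[[1]]
        cf <- spec$categorical_features[[parts[1]]]
        pr <- cf$probs[cf$levels == parts[2]]
        eta <- eta + spec$label_model$coef[[term]] * rbinom(n, 1, pr)
      }
    }
    mean(plogis(eta))
  })
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(mean(tab$event) - expected), 3 * se)
})

test_that("cohort spec validation names the offending field", {
  expect_error(cohort_spec(1), "n_records")
  expect_error(cohort_spec(10, missing_rate = 1), "missing_rate")
  expect_error(
    cohort_spec(10, categorical_features = list(
      sex = list(levels = c("F", "M"), probs = c(0.5, 0.6)))),
    "sex")
})

test_that("panel generation is deterministic with planted lagged structure", {
  spec <- panel_spec(4, 500, seed = 2)
  expect_identical(generate_panel(spec), generate_panel(spec))

  # null panel: all pairwise lagged weights stay small
  p <- generate_panel(spec)
  ws <- c()
  for (a in 1:4) for (b in 1:4) {
    if (a != b) ws <- c(ws, lagged_edge_weight(p[, a], p[, b], 1))
  }
  expect_true(all(abs(ws) < 0.2))

  # planted a -> b edge dominates
  pe <- data.frame(source = 1, target = 2, coef = 0.9)
  p2 <- generate_panel(panel_spec(4, 500, planted_edges = pe,
                                  noise_sd = 0.1, seed = 4))
  expect_gt(lagged_edge_weight(p2[, 1], p2[, 2], 1), 0.6)
})

test_that("null panels give white-noise autocorrelations", {
  nT <- 400
  p <- generate_panel(panel_spec(5, nT, seed = 8))
  for (j in 1:5) {
    ac <- stats::acf(p[, j], lag.max = 1, plot = FALSE)$acf[2]
    expect_lt(abs(ac), 4 / sqrt(nT))
  }
})

test_that("panel spec rejects invalid configurations", {
  expect_error(panel_spec(3, 10, lag = 10), "lag")
  expect_error(panel_spec(3, 10, noise_sd = 0), "noise_sd")
  expect_error(
    panel_spec(3, 10, planted_edges = data.frame(source = 5, target = 1,
                                                 coef = 1)),
    "endpoints")
})
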