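test_that("split counts follow floor(0.8 n) with the remainder held out", {
  sc <- train_test_split_counts(c(10, 11, 919))
  expect_equal(sc$train, c(8, 8, 735))
  expect_equal(sc$test, c(2, 3, 184))
  expect_equal(sc$train + sc$test, sc$total)
})

test_that("non-IID partitioning is a valid, skew-controlled partition", {
  tab <- generate_cohort(cohort_spec(2000, missing_rate = 0, seed = 17))
  shards <- partition_noniid(tab, 5, alpha = 0.5, seed = 1)
  all_idx <- sort(unlist(shards))
  expect_equal(all_idx, seq_len(2000))          # union, no duplicates
  expect_true(all(lengths(shards) > 0))

  # near-IID limit: per-shard label proportions close to global
  shards_iid <- partition_noniid(tab, 5, alpha = 1e6, seed = 2)
  global <- mean(tab$event)
  for (s in shards_iid) {
    expect_lt(abs(mean(tab$event[s]) - global), 0.05)
  }

  # severe skew: some shard is dominated by one class
  hit <- vapply(1:5, function(sd) {
    sh <- partition_noniid(tab, 5, alpha = 0.1, seed = sd)
    any(vapply(sh, function(s) {
      p <- mean(tab$event[s])
      max(p, 1 - p) >= 0.8
    }, logical(1)))
  }, logical(1))
  expect_true(any(hit))

  expect_error(partition_noniid(tab, 5000, 0.5), "more clients")
  expect_error(partition_noniid(tab, 2, alpha = 0), "alpha")
})

small_config <- function(seed = 1) {
  federation_config(n_hospitals = 3, rounds = 2, n_records = 120,
                    epochs_per_client = 2, baseline_epochs = 2,
                    hidden = 8, layers = 2, k_neighbours = 4, seed = seed)
}

test_that("a small federated run is reproducible and fully audited", {
  res1 <- run_simulation(small_config())
  res2 <- run_simulation(small_config())
  expect_equal(res1$round_log, res2$round_log)
  expect_equal(res1$summary, res2$summary)
  expect_identical(res1$ledger$blocks[[length(res1$ledger$blocks)]]$block_hash,
                   res2$ledger$blocks[[length(res2$ledger$blocks)]]$block_hash)

  expect_true(verify_chain(res1$ledger)$ok)
  # ceil(0.3 * 3) = 1 participant per round
  expect_equal(unique(res1$round_log$participants), 1)

  acts <- vapply(res1$ledger$blocks,
                 function(b) b$transaction$action, character(1))
  expect_equal(sum(acts == "registration"), 3)
  expect_equal(sum(acts == "login"), 3)
  # per round: 1 local_training + 1 privacy + 1 authentication +
  # aggregation + global_prediction + 1 continual_update
  expect_equal(sum(acts == "aggregation"), 2)
  expect_equal(sum(acts == "global_prediction"), 2)
  expect_equal(sum(acts == "local_training"), 3 + 2)

  expect_s3_class(tidy(res1), "tbl_df")
  expect_equal(nrow(glance(res1)), 1)
})

test_that("tampered submissions are excluded from aggregation", {
  cfg <- federation_config(n_hospitals = 3, rounds = 1, n_records = 120,
                           epochs_per_client = 2, baseline_epochs = 2,
                           participation_ratio = 1, hidden = 8, layers = 2,
                           k_neighbours = 4, seed = 5)
  clean <- run_simulation(cfg)
  expect_equal(clean$round_log$authenticated, 3)

  tampered <- run_simulation(cfg, tamper = list("1" = "H2"))
  expect_equal(tampered$round_log$authenticated, 2)
  expect_equal(tampered$round_log$excluded, "H2")
  # the excluded hospital never enters any cluster
  expect_false("H2" %in% names(tampered$clustering$assignment))
  # and the rejection is on the ledger
  verdicts <- Filter(function(b) b$transaction$action == "authentication",
                     tampered$ledger$blocks)
  expect_equal(length(verdicts), 3)
  expect_true(verify_chain(tampered$ledger)$ok)
})
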