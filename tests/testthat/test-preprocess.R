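test_that("neighbour-mean imputation follows the stated rules", {
  t1 <- tibble::tibble(x = c(1, NA, 3), event = c(0L, 1L, 0L))
  expect_equal(impute_missing(t1)$x, c(1, 2, 3))

  t2 <- tibble::tibble(x = c(NA, 5, 7), event = c(0L, 1L, 0L))
  expect_equal(impute_missing(t2)$x, c(5, 5, 7))

  # nearest non-missing neighbours are 2 and 8 for both gap cells
  t3 <- tibble::tibble(x = c(2, NA, NA, 8), event = c(0L, 1L, 0L, 1L))
  expect_equal(impute_missing(t3)$x, c(2, 5, 5, 8))

  # categorical: nearer neighbour wins, tie goes to the preceding value
  t4 <- tibble::tibble(s = c("A", NA, "B", NA, NA, "C"),
                       event = rep(0:1, 3))
  expect_equal(impute_missing(t4)$s, c("A", "A", "B", "B", "C", "C"))

  expect_error(
    impute_missing(tibble::tibble(x = c(NA_real_, NA), event = c(0L, 1L))),
    "x")
})

test_that("imputation is idempotent and never touches the label", {
  tab <- toy_raw_table()
  tab$event[2] <- NA
  imp <- impute_missing(tab)
  expect_true(is.na(imp$event[2]))
  imp$event[2] <- 1L
  expect_equal(impute_missing(imp)[1:3], imp[1:3], ignore_attr = TRUE)
  expect_equal(attr(impute_missing(imp), "imputed_cells"), 0)
})

test_that("one-hot encoding uses lexicographic level order", {
  tab <- tibble::tibble(sex = c("M", "F", "M"), event = c(1L, 0L, 1L))
  enc <- one_hot_encode(tab)
  expect_equal(names(enc), c("sex=F", "sex=M", "event"))
  expect_equal(enc$`sex=F`, c(0, 1, 0))
  expect_equal(enc$`sex=M`, c(1, 0, 1))
  # indicator column sums equal category counts; row sums are 1
  expect_equal(colSums(enc[1:2]), c(`sex=F` = 1, `sex=M` = 2))
  expect_equal(rowSums(enc[1:2]), rep(1, 3))

  abc <- tibble::tibble(g = c("A", "B", "C"), event = c(0L, 1L, 0L))
  expect_equal(unlist(one_hot_encode(abc)[2, 1:3], use.names = FALSE),
               c(0, 1, 0))
})

test_that("min-max normalization matches the closed form", {
  tab <- tibble::tibble(x = c(2, 4, 6), event = c(0L, 1L, 0L))
  expect_equal(min_max_normalize(tab)$x, c(0, 0.5, 1))

  const <- tibble::tibble(x = c(5, 5, 5), event = c(0L, 1L, 0L))
  expect_equal(min_max_normalize(const)$x, c(0, 0, 0))

  t2 <- tibble::tibble(x = c(10, 0, 5, 20), event = c(0L, 1L, 0L, 1L))
  expect_equal(min_max_normalize(t2)$x, c(0.5, 0, 0.25, 1))
})

test_that("pipeline composes the stages and reports its work", {
  tab <- toy_raw_table()
  out <- preprocess_pipeline(tab)
  expect_equal(out$report$imputed_cells, 3)
  feats <- setdiff(names(out$table), "event")
  for (nm in feats) {
    expect_true(all(out$table[[nm]] >= 0 & out$table[[nm]] <= 1))
  }
  # stored ranges reproduce the normalized table exactly
  enc <- one_hot_encode(impute_missing(tab))
  again <- min_max_normalize(enc, ranges = out$report$ranges)
  expect_equal(again[feats], out$table[feats])

  # one-hot row sums equal the number of original categorical columns
  ind <- out$report$indicator_columns
  expect_equal(rowSums(out$table[ind]), rep(1, nrow(tab)))

  # with nothing to impute or encode, the pipeline is normalization alone
  plain <- tibble::tibble(x = c(1, 2, 4), event = c(0L, 1L, 0L))
  expect_equal(preprocess_pipeline(plain)$table$x,
               min_max_normalize(plain)$x)
  expect_identical(preprocess_pipeline(tab)$table, out$table)
})

test_that("stored statistics transform unseen records with clipping", {
  train <- tibble::tibble(x = c(0, 10), g = c("A", "B"), event = c(0L, 1L))
  rep_ <- preprocess_pipeline(train)$report
  new <- tibble::tibble(x = c(-5, 5, 15), g = c("A", "C", "B"),
                        event = c(0L, 1L, 0L))
  out <- apply_preprocess(new, rep_)
  expect_equal(out$x, c(0, 0.5, 1))      # clipped to [0, 1]
  expect_equal(out$`g=A`, c(1, 0, 0))    # unseen category C -> all zeros
  expect_equal(out$`g=B`, c(0, 0, 1))
})
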