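# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is read from disk.

# Two informative standard-normal features with a strong (+10, -10) logistic
# signal: labels are nearly deterministic, so a working classifier should
# approach perfect training accuracy.
separable_cohort_spec <- function(n = 500, seed = 7) {
  cohort_spec(
    n_records = n,
    numeric_features = list(f1 = list(mean = 0, sd = 1),
                            f2 = list(mean = 0, sd = 1)),
    categorical_features = list(),
    missing_rate = 0,
    label_model = list(coef = c(f1 = 10, f2 = -10), intercept = 0),
    seed = seed
  )
}

separable_table <- function(n = 500, seed = 7) {
  preprocess_pipeline(generate_cohort(separable_cohort_spec(n, seed)))$table
}

# Tiny raw EHR table with known missing cells and one categorical column.
toy_raw_table <- function() {
  tibble::tibble(
    age = c(1, NA, 3, 5),
    bp = c(NA, 5, 7, 9),
    sex = c("F", "M", NA, "M"),
    event = c(0L, 1L, 0L, 1L)
  )
}

# A hand-specified temporal causal graph a -> b -> c for feature tests.
chain_tcg <- function() {
  adj <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  adj["a", "b"] <- 0.8
  adj["b", "c"] <- 0.6
  structure(list(nodes = c("a", "b", "c"), max_lag = 1L, threshold = 0.3,
                 edges = NULL, adjacency = adj, norm_factor = 1),
            class = "tcg")
}

random_ids <- function(n, seed, len = 8) {
  with_seed_test(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c(LETTERS, letters, 0:9), len, replace = TRUE),
            collapse = "")
    }, character(1))
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

perturb_one_char <- function(id) {
  pos <- sample.int(nchar(id), 1)
  alphabet <- c(LETTERS, letters, 0:9)
  old <- substr(id, pos, pos)
  new <- sample(setdiff(alphabet, old), 1)
  paste0(substr(id, 1, pos - 1), new, substr(id, pos + 1, nchar(id)))
}
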