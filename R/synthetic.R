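#' Specification of a synthetic EHR cohort
#'
#' Describes an EHR-like cohort: normally distributed numeric features,
#' multinomial categorical features, an optional missing-data rate applied to
#' feature cells only, and a logistic outcome model for the binary event
#' label. The default template mirrors a heart-failure screening schema
#' (age, sex, resting blood pressure, chest pain type, cholesterol, maximum
#' heart rate), so fixtures stay recognizably EHR-shaped.
#'
#' @param n_records Number of patient records (>= 2).
#' @param numeric_features Named list; each element `list(mean =, sd =)`.
#' @param categorical_features Named list; each element
#'   `list(levels = c(...), probs = c(...))` with probabilities summing to 1.
#' @param missing_rate Fraction of feature cells masked at random, in `[0, 1)`.
#' @param label_model List with `coef` (named coefficients over numeric
#'   features and/or `"col=level"` indicator terms) and `intercept`, defining
#'   `P(event = 1) = plogis(intercept + sum(coef * x))` on the raw scale.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_records,
                        numeric_features = default_numeric_features(),
                        categorical_features = default_categorical_features(),
                        missing_rate = 0,
                        label_model = default_label_model(),
                        seed = 1L) {
  if (!is.numeric(n_records) || length(n_records) != 1 || n_records < 2) {
    stop_config("`n_records` must be a single integer >= 2")
  }
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stop_config("`missing_rate` must lie in [0, 1)")
  }
  for (nm in names(categorical_features)) {
    cf <- categorical_features[[nm]]
    if (length(cf$levels) != length(cf$probs)) {
      stop_config(paste0("categorical feature `", nm,
                         "`: levels and probs differ in length"))
    }
    if (abs(sum(cf$probs) - 1) > 1e-9) {
      stop_config(paste0("categorical feature `", nm,
                         "`: probabilities must sum to 1"))
    }
  }
  if (is.null(label_model$coef) || is.null(label_model$intercept)) {
    stop_config("`label_model` needs `coef` and `intercept`")
  }
  structure(
    list(n_records = as.integer(n_records),
         numeric_features = numeric_features,
         categorical_features = categorical_features,
         missing_rate = missing_rate,
         label_model = label_model,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @rdname cohort_spec
#' @export
default_numeric_features <- function() {
  list(
    age = list(mean = 54, sd = 9),
    resting_bp = list(mean = 132, sd = 18),
    cholesterol = list(mean = 200, sd = 60),
    max_heart_rate = list(mean = 137, sd = 25)
  )
}

#' @rdname cohort_spec
#' @export
default_categorical_features <- function() {
  list(
    sex = list(levels = c("F", "M"), probs = c(0.21, 0.79)),
    chest_pain_type = list(levels = c("ASY", "ATA", "NAP", "TA"),
                           probs = c(0.54, 0.19, 0.22, 0.05))
  )
}

#' @rdname cohort_spec
#' @export
default_label_model <- function() {
  list(coef = c(age = 0.04, resting_bp = 0.01, cholesterol = -0.002,
                max_heart_rate = -0.03, "sex=M" = 0.8,
                "chest_pain_type=ASY" = 1.2),
       intercept = 0.0)
}

#' Generate a synthetic EHR cohort
#'
#' Draws a patient-record table from a [cohort_spec()]: numeric cells from the
#' stated normals, categoricals from the stated multinomials, the binary
#' `event` label from `Bernoulli(plogis(linear predictor))`, and finally masks
#' feature cells (never the label) independently at `missing_rate`. Missing
#' cells are `NA` in memory and empty fields in CSV.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per record, feature columns, and an integer
#'   `event` column; attribute `"spec"` carries the generating spec.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_records
    cols <- list()
    for (nm in names(spec$numeric_features)) {
      f <- spec$numeric_features[[nm]]
      cols[[nm]] <- rnorm(n, f$mean, f$sd)
    }
    for (nm in names(spec$categorical_features)) {
      f <- spec$categorical_features[[nm]]
      cols[[nm]] <- sample(f$levels, n, replace = TRUE, prob = f$probs)
    }
    tab <- tibble::as_tibble(cols)

    eta <- rep(spec$label_model$intercept, n)
    for (term in names(spec$label_model$coef)) {
      beta <- spec$label_model$coef[[term]]
      if (grepl("=", term, fixed = TRUE)) {
        parts <- strsplit(term, "=", fixed = TRUE)[[1]]
        if (!parts[1] %in% names(tab)) {
          stop_config(paste0("label_model term `", term,
                             "`: no such column `", parts[1], "`"))
        }
        eta <- eta + beta * as.numeric(tab[[parts[1]]] == parts[2])
      } else {
        if (!term %in% names(tab)) {
          stop_config(paste0("label_model term `", term, "`: no such column"))
        }
        eta <- eta + beta * tab[[term]]
      }
    }
    event <- rbinom(n, 1, stats::plogis(eta))

    if (spec$missing_rate > 0) {
      for (nm in names(tab)) {
        mask <- runif(n) < spec$missing_rate
        tab[[nm]][mask] <- NA
      }
    }
    tab$event <- as.integer(event)
    attr(tab, "spec") <- spec
    tab
  })
}

#' Specification of a lagged-causal time-series panel
#'
#' Describes a multivariate panel generated by a lag-`lag` linear process with
#' planted directed edges: `x[target, t] = sum(coef * x[source, t - lag]) +
#' noise`. Used as ground truth for temporal-causal-graph recovery.
#'
#' @param n_nodes Number of series.
#' @param n_steps Number of time steps (must exceed `lag`).
#' @param lag Positive causal lag shared by all planted edges.
#' @param planted_edges Data frame / tibble with columns `source`, `target`
#'   (1-based node indices) and `coef`; may have zero rows.
#' @param noise_sd Positive innovation standard deviation.
#' @param seed Integer seed.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(n_nodes, n_steps, lag = 1L,
                       planted_edges = data.frame(source = integer(),
                                                  target = integer(),
                                                  coef = numeric()),
                       noise_sd = 1, seed = 1L) {
  if (n_nodes < 1) stop_config("`n_nodes` must be positive")
  if (lag < 1) stop_config("`lag` must be a positive integer")
  if (lag >= n_steps) stop_config("`lag` must be smaller than `n_steps`")
  if (noise_sd <= 0) stop_config("`noise_sd` must be positive")
  pe <- as.data.frame(planted_edges)
  if (nrow(pe) > 0) {
    bad <- pe$source < 1 | pe$source > n_nodes | pe$target < 1 |
      pe$target > n_nodes
    if (any(bad)) stop_config("planted edge endpoints out of node range")
  }
  structure(
    list(n_nodes = as.integer(n_nodes), n_steps = as.integer(n_steps),
         lag = as.integer(lag), planted_edges = pe,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "panel_spec"
  )
}

#' Generate a time-series panel with planted lagged causal edges
#'
#' @param spec A [panel_spec()].
#' @return Numeric matrix of `n_steps` rows by `n_nodes` columns (columns
#'   `V1..Vk`), with attributes `"planted_edges"` and `"spec"`.
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  with_seed(spec$seed, {
    x <- matrix(rnorm(spec$n_steps * spec$n_nodes, sd = spec$noise_sd),
                nrow = spec$n_steps, ncol = spec$n_nodes)
    pe <- spec$planted_edges
    if (nrow(pe) > 0) {
      for (t in seq(spec$lag + 1, spec$n_steps)) {
        for (i in seq_len(nrow(pe))) {
          x[t, pe$target[i]] <- x[t, pe$target[i]] +
            pe$coef[i] * x[t - spec$lag, pe$source[i]]
        }
      }
    }
    colnames(x) <- paste0("V", seq_len(spec$n_nodes))
    attr(x, "planted_edges") <- pe
    attr(x, "spec") <- spec
    x
  })
}

#' Write / read a cohort as CSV with a JSON spec sidecar
#'
#' Missing cells serialize as empty fields; the generating spec is written to
#' `<path>.json` so a cohort round-trips with its provenance.
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param path CSV file path.
#' @return `path`, invisibly (`write_cohort_csv`); a tibble
#'   (`read_cohort_csv`).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  spec <- attr(cohort, "spec")
  if (!is.null(spec)) {
    jsonlite::write_json(unclass(spec), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                         check.names = FALSE)
  tibble::as_tibble(tab)
}
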