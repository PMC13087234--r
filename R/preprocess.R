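#' Preprocessing state of an EHR table
#'
#' An EHR table is an ordinary tibble with a binary `event` label column and a
#' `"state"` attribute tracking its position in the preprocessing chain:
#' `"raw"` -> `"imputed"` (no missing cells) -> `"encoded"` (all feature
#' columns numeric, categoricals expanded to `col=level` indicators) ->
#' `"normalized"` (every feature in `[0, 1]`, per-column min/max recorded in
#' attribute `"ranges"` for reuse on unseen records).
#'
#' @param table A tibble.
#' @return The state string (`"raw"` if untagged).
#' @export
ehr_state <- function(table) attr(table, "state") %||% "raw"

feature_cols <- function(table, label_col = "event") {
  setdiff(names(table), label_col)
}

# Nearest non-missing neighbour above/below within one column (given row
# order). Numeric gaps take the mean of the two; boundaries take the single
# available neighbour; categorical cells take the nearer neighbour, ties
# resolved to the preceding one.
impute_column <- function(x, name) {
  miss <- is.na(x)
  if (!any(miss)) return(x)
  if (all(miss)) stop_data(paste0("column `", name, "` is entirely missing"))
  obs <- which(!miss)
  numericish <- is.numeric(x)
  for (i in which(miss)) {
    above <- obs[obs < i]
    below <- obs[obs > i]
    prev <- if (length(above)) max(above) else NA_integer_
    nxt <- if (length(below)) min(below) else NA_integer_
    if (is.na(prev)) {
      x[i] <- x[nxt]
    } else if (is.na(nxt)) {
      x[i] <- x[prev]
    } else if (numericish) {
      x[i] <- (x[prev] + x[nxt]) / 2
    } else {
      d_prev <- i - prev
      d_next <- nxt - i
      x[i] <- if (d_next < d_prev) x[nxt] else x[prev]
    }
  }
  x
}

#' Impute missing cells by neighbour means
#'
#' Each missing cell is replaced by the mean of the nearest non-missing values
#' above and below it in the same column (rows in the given order); boundary
#' cells take their single available neighbour; categorical cells take the
#' nearer neighbour with ties resolved upward. The label column is never
#' touched. Idempotent on already-imputed tables.
#'
#' @param table EHR tibble (state `"raw"` or `"imputed"`).
#' @param label_col Name of the label column; default `"event"`.
#' @return The table with state `"imputed"` and attribute `"imputed_cells"`.
#' @export
impute_missing <- function(table, label_col = "event") {
  n_missing <- sum(vapply(table[feature_cols(table, label_col)],
                          function(x) sum(is.na(x)), integer(1)))
  for (nm in feature_cols(table, label_col)) {
    table[[nm]] <- impute_column(table[[nm]], nm)
  }
  attr(table, "state") <- "imputed"
  attr(table, "imputed_cells") <- n_missing
  table
}

#' One-hot encode categorical features
#'
#' Each categorical column with `k` observed categories (sorted
#' lexicographically with `method = "radix"` for locale independence) becomes
#' `k` binary indicator columns named `col=level`; numeric columns pass
#' through. Exactly one indicator per original column is 1 on each row.
#'
#' @param table Imputed EHR tibble (no missing cells).
#' @param label_col Label column name.
#' @param categories Optional named list of level vectors to encode against
#'   (e.g. the training-time categories); unseen levels map to all-zero
#'   indicators.
#' @return Encoded tibble, state `"encoded"`, attribute `"categories"`.
#' @export
one_hot_encode <- function(table, label_col = "event", categories = NULL) {
  feats <- feature_cols(table, label_col)
  if (any(vapply(table[feats], anyNA, logical(1)))) {
    stop_data("one_hot_encode requires an imputed table (no missing cells)")
  }
  out <- list()
  cats <- list()
  for (nm in feats) {
    x <- table[[nm]]
    if (is.numeric(x)) {
      out[[nm]] <- x
    } else {
      levs <- categories[[nm]] %||% sort(unique(as.character(x)),
                                         method = "radix")
      cats[[nm]] <- levs
      for (lv in levs) {
        out[[paste0(nm, "=", lv)]] <- as.numeric(as.character(x) == lv)
      }
    }
  }
  res <- tibble::as_tibble(out)
  res[[label_col]] <- table[[label_col]]
  attr(res, "state") <- "encoded"
  attr(res, "imputed_cells") <- attr(table, "imputed_cells")
  attr(res, "categories") <- cats
  res
}

#' Min-max normalize feature columns
#'
#' Maps each feature column through `(x - min) / (max - min)` so every value
#' lies in `[0, 1]`. A constant column maps to all zeros (the degenerate 0/0
#' range). Per-column min/max are stored in attribute `"ranges"`; pass them
#' back via `ranges` to transform unseen records with the training statistics
#' (values clipped to `[0, 1]`).
#'
#' @param table Encoded EHR tibble (all feature columns numeric).
#' @param label_col Label column name.
#' @param ranges Optional named list `list(col = c(min, max), ...)` from a
#'   previous call.
#' @return Normalized tibble, state `"normalized"`, attribute `"ranges"`.
#' @export
min_max_normalize <- function(table, label_col = "event", ranges = NULL) {
  feats <- feature_cols(table, label_col)
  if (!all(vapply(table[feats], is.numeric, logical(1)))) {
    stop_data("min_max_normalize requires all-numeric feature columns")
  }
  stored <- list()
  for (nm in feats) {
    x <- table[[nm]]
    r <- ranges[[nm]] %||% range(x)
    stored[[nm]] <- r
    span <- r[2] - r[1]
    y <- if (span == 0) rep(0, length(x)) else (x - r[1]) / span
    table[[nm]] <- pmin(pmax(y, 0), 1)
  }
  attr(table, "state") <- "normalized"
  attr(table, "ranges") <- stored
  table
}

#' Full preprocessing pipeline
#'
#' Composes [impute_missing()], [one_hot_encode()] and [min_max_normalize()]
#' and returns the normalized table plus a report of what was done. The
#' normalization statistics and encoding categories live on the result for
#' transforming held-out records with [apply_preprocess()]; they are computed
#' per table (per hospital), never shared.
#'
#' @param table Raw EHR tibble.
#' @param label_col Label column name.
#' @return List with `table` (state `"normalized"`) and `report`
#'   (`imputed_cells`, `indicator_columns`, `ranges`).
#' @export
preprocess_pipeline <- function(table, label_col = "event") {
  if (nrow(table) == 0) stop_data("empty table")
  imp <- impute_missing(table, label_col)
  enc <- one_hot_encode(imp, label_col)
  norm <- min_max_normalize(enc, label_col)
  indicator_cols <- setdiff(names(enc), names(table))
  list(
    table = norm,
    report = list(
      imputed_cells = attr(imp, "imputed_cells"),
      indicator_columns = indicator_cols,
      ranges = attr(norm, "ranges"),
      categories = attr(enc, "categories")
    )
  )
}

#' Transform unseen records with stored preprocessing statistics
#'
#' Applies a fitted pipeline's categories and min/max ranges to new raw
#' records: imputation, encoding against the training categories (unseen
#' levels become all-zero indicators), then normalization clipped to
#' `[0, 1]`.
#'
#' @param table Raw tibble of new records.
#' @param report Report from [preprocess_pipeline()].
#' @param label_col Label column name.
#' @return Normalized tibble aligned to the training schema.
#' @export
apply_preprocess <- function(table, report, label_col = "event") {
  imp <- impute_missing(table, label_col)
  enc <- one_hot_encode(imp, label_col, categories = report$categories)
  for (nm in names(report$ranges)) {
    if (!nm %in% names(enc)) enc[[nm]] <- 0
  }
  enc <- enc[c(names(report$ranges), label_col)]
  min_max_normalize(enc, label_col, ranges = report$ranges)
}
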