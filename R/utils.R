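#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm runif rbinom setNames coef predict
NULL

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic operations in the package go
# through this so that seeded calls never disturb (or depend on) global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed below 2^31 from a parent seed and a label; keeps the
# many per-hospital / per-round streams independent but reproducible.
derive_seed <- function(seed, ...) {
  h <- digest::digest(list(as.integer(seed), ...), algo = "sha256")
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}

#' Canonical JSON serialization
#'
#' Serializes an R object to JSON with recursively sorted names, unboxed
#' scalars and 15 significant digits, so that equal objects always produce
#' byte-identical strings. Used for ledger payload digests and signature
#' encodings, where hashes must be recomputable bit-exactly.
#'
#' @param x An R object (lists, vectors, data frames).
#' @return A single JSON string.
#' @export
canonical_json <- function(x) {
  sort_names <- function(o) {
    if (is.list(o)) {
      if (!is.null(names(o)) && length(o) > 0) {
        o <- o[order(names(o))]
      }
      lapply(o, sort_names)
    } else {
      o
    }
  }
  as.character(jsonlite::toJSON(sort_names(x), auto_unbox = TRUE, digits = 15,
                                null = "null", na = "null"))
}

sha256_hex <- function(x) {
  digest::digest(x, algo = "sha256", serialize = FALSE)
}

stop_config <- function(msg) abort(msg, class = "fedcep_config_error")
stop_data <- function(msg) abort(msg, class = "fedcep_data_error")
stop_arg <- function(msg) abort(msg, class = "fedcep_arg_error")
stop_numeric <- function(msg) abort(msg, class = "fedcep_numeric_error")
stop_security <- function(msg) abort(msg, class = "fedcep_security_error")
stop_key <- function(msg) abort(msg, class = "fedcep_key_error")
stop_ledger <- function(msg) abort(msg, class = "fedcep_ledger_error")

#' Elapsed wall-clock time of an expression
#'
#' Minimal timing helper for encryption/decryption/signature/clustering
#' benchmarks; returns the value together with elapsed seconds.
#'
#' @param expr Expression to evaluate.
#' @return List with `value` and `seconds`.
#' @export
with_timing <- function(expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- force(expr)
  list(value = value, seconds = proc.time()[["elapsed"]] - t0)
}
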