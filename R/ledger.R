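ledger_actions <- c("registration", "login", "local_training",
                    "privacy_preservation", "authentication", "aggregation",
                    "global_prediction", "continual_update")

#' Create a ledger transaction
#'
#' A transaction names the actor, one of the eight framework actions, and
#' the SHA-256 digest of the canonical serialization of its payload; the
#' payload itself never enters the chain.
#'
#' @param actor Actor id string.
#' @param action One of `"registration"`, `"login"`, `"local_training"`,
#'   `"privacy_preservation"`, `"authentication"`, `"aggregation"`,
#'   `"global_prediction"`, `"continual_update"`.
#' @param payload Any serializable object; digested, not stored.
#' @param timestamp Timestamp string; pass a logical clock for reproducible
#'   simulations (default: wall-clock time).
#' @return A named list transaction.
#' @export
ledger_transaction <- function(actor, action, payload = list(),
                               timestamp = format(Sys.time(),
                                                  "%Y-%m-%dT%H:%M:%OS3")) {
  if (!action %in% ledger_actions) {
    stop_arg(paste0("unknown ledger action `", action, "`"))
  }
  list(actor = as.character(actor), action = action,
       payload_digest = sha256_hex(canonical_json(payload)),
       timestamp = as.character(timestamp))
}

block_hash <- function(index, prev_hash, tx) {
  sha256_hex(paste0(index, "|", prev_hash, "|", canonical_json(tx)))
}

#' Append-only hash-chained ledger
#'
#' A single-process stand-in for a permissioned blockchain: every block
#' stores its index, the previous block's hash, one transaction, and its own
#' SHA-256 over the three. The genesis block links to 64 zeros. The API
#' exposes only append and read; any external mutation is detected by
#' [verify_chain()].
#'
#' @param path Optional JSONL file; when set, each block is persisted
#'   (appended) before `ledger_append` returns.
#' @return An object of class `fedcep_ledger`.
#' @export
ledger_new <- function(path = NULL) {
  structure(list(blocks = list(), path = path), class = "fedcep_ledger")
}

#' @rdname ledger_new
#' @param ledger A `fedcep_ledger`.
#' @param tx A [ledger_transaction()].
#' @export
ledger_append <- function(ledger, tx) {
  if (!is.list(tx) || is.null(tx$action)) stop_ledger("invalid transaction")
  index <- length(ledger$blocks)
  prev_hash <- if (index == 0) {
    strrep("0", 64)
  } else {
    ledger$blocks[[index]]$block_hash
  }
  block <- list(index = index, prev_hash = prev_hash, transaction = tx,
                block_hash = block_hash(index, prev_hash, tx))
  if (!is.null(ledger$path)) {
    line <- tryCatch(canonical_json(block),
                     error = function(e) stop_ledger("serialization failure"))
    cat(line, "\n", sep = "", file = ledger$path, append = TRUE)
  }
  ledger$blocks <- c(ledger$blocks, list(block))
  ledger
}

#' Verify a hash chain
#'
#' Recomputes every block hash and checks the links; a freshly built chain
#' verifies, any single-field mutation (or broken link) is reported with the
#' earliest violating index. Prefix chains remain valid after truncation.
#'
#' @param ledger A `fedcep_ledger`, or a list of blocks, or a JSONL path.
#' @return List with `ok` (logical) and `first_bad_index` (`NA` when ok).
#' @export
verify_chain <- function(ledger) {
  blocks <- if (inherits(ledger, "fedcep_ledger")) {
    ledger$blocks
  } else if (is.character(ledger)) {
    lapply(readLines(ledger), function(l) {
      jsonlite::fromJSON(l, simplifyVector = TRUE)
    })
  } else {
    ledger
  }
  prev <- strrep("0", 64)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    ok <- identical(b$index, i - 1L) || isTRUE(b$index == i - 1)
    ok <- ok && identical(as.character(b$prev_hash), prev)
    ok <- ok && identical(as.character(b$block_hash),
                          block_hash(b$index, b$prev_hash, b$transaction))
    if (!ok) return(list(ok = FALSE, first_bad_index = i - 1))
    prev <- b$block_hash
  }
  list(ok = TRUE, first_bad_index = NA_integer_)
}

#' @export
print.fedcep_ledger <- function(x, ...) {
  v <- verify_chain(x)
  cat("Hash-chained ledger:", length(x$blocks), "blocks;",
      if (v$ok) "verified" else paste("BROKEN at index", v$first_bad_index),
      "\n")
  invisible(x)
}
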