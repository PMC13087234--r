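#' Lagged edge weight between two series
#'
#' The directed temporal influence of series `a` on series `b` at a given
#' lag: `(1/(nT - 1)) * sum_{t = lag+1..nT} a(t - lag) * b(t)`. With
#' `standardize = TRUE` (the default) both series are z-scored first, so the
#' weight is a lagged correlation and the causality threshold band 0.3-0.6
#' is meaningful on its scale.
#'
#' @param series_a,series_b Numeric vectors of equal length `nT`.
#' @param lag Integer lag, `1 <= lag < nT`.
#' @param standardize Z-score both series before the sum.
#' @return A single numeric weight.
#' @export
lagged_edge_weight <- function(series_a, series_b, lag, standardize = TRUE) {
  nT <- length(series_a)
  if (length(series_b) != nT) stop_arg("series lengths differ")
  if (lag < 1 || lag >= nT) stop_arg("`lag` must satisfy 1 <= lag < nT")
  if (standardize) {
    series_a <- zscore(series_a)
    series_b <- zscore(series_b)
  }
  idx <- seq(lag + 1, nT)
  sum(series_a[idx - lag] * series_b[idx]) / (nT - 1)
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Build a temporal causal graph from a panel
#'
#' Computes the lagged edge weight for every ordered node pair and every lag
#' up to `max_lag` (on z-scored series; optionally averaged over sliding
#' pseudo-time windows), keeps the single best lag per pair, normalizes all
#' weights by the maximum absolute weight, and thresholds: a directed edge is
#' retained when its raw (correlation-scale) weight exceeds
#' `min_edge_weight` in magnitude and meets `threshold`. The adjacency
#' `adjacency[source, target]` holds the normalized weight of retained edges
#' and 0 elsewhere. Optionally the weakest retained edges are pruned so at
#' most `1 - prune_ratio` of ordered pairs survive.
#'
#' @param panel Numeric matrix, rows = time steps, columns = nodes.
#' @param max_lag Maximum temporal lag (default 3).
#' @param threshold Causality threshold on the absolute correlation-scale
#'   weight, in `(0, 1)` (default 0.3).
#' @param min_edge_weight Pre-filter on the absolute raw weight (default
#'   0.05).
#' @param prune_ratio Optional edge-pruning ratio in `(0, 1)`; `NULL` (the
#'   default) disables pruning.
#' @param window,stride Optional sliding pseudo-time window length and
#'   stride; weights are averaged across windows. `NULL` window uses the
#'   whole series.
#' @param include_self Allow lagged self-edges (`a -> a`, lag >= 1);
#'   default `FALSE`.
#' @return An object of class `tcg`: node names, an `edges` tibble
#'   (`source`, `target`, `lag`, `weight`, `normalized_weight`, `retained`),
#'   the `adjacency` matrix, and the normalization factor.
#' @export
build_tcg <- function(panel, max_lag = 3, threshold = 0.3,
                      min_edge_weight = 0.05, prune_ratio = NULL,
                      window = NULL, stride = 1, include_self = FALSE) {
  panel <- as.matrix(panel)
  nT <- nrow(panel)
  k <- ncol(panel)
  if (max_lag < 1) stop_arg("`max_lag` must be >= 1")
  if (threshold <= 0 || threshold >= 1) stop_arg("`threshold` must be in (0, 1)")
  if (nT < max_lag + 2) stop_data("panel too short for the requested max_lag")
  nodes <- colnames(panel) %||% paste0("V", seq_len(k))
  colnames(panel) <- nodes

  starts <- if (is.null(window) || window >= nT) {
    list(c(1L, nT))
  } else {
    if (window < max_lag + 2) stop_arg("`window` too short for `max_lag`")
    s <- seq(1L, nT - window + 1L, by = stride)
    lapply(s, function(i) c(i, i + window - 1L))
  }

  pairs <- expand.grid(source = seq_len(k), target = seq_len(k))
  if (!include_self) pairs <- pairs[pairs$source != pairs$target, ]

  best_lag <- numeric(nrow(pairs))
  best_w <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$source[r]
    b <- pairs$target[r]
    w_by_lag <- vapply(seq_len(max_lag), function(lg) {
      ws <- vapply(starts, function(se) {
        lagged_edge_weight(panel[se[1]:se[2], a], panel[se[1]:se[2], b], lg)
      }, numeric(1))
      mean(ws)
    }, numeric(1))
    j <- which.max(abs(w_by_lag))
    best_lag[r] <- j
    best_w[r] <- w_by_lag[j]
  }

  norm_factor <- max(abs(best_w))
  normalized <- if (norm_factor > 0) best_w / norm_factor else best_w
  retained <- abs(best_w) >= max(threshold, min_edge_weight)

  if (!is.null(prune_ratio)) {
    if (prune_ratio <= 0 || prune_ratio >= 1) {
      stop_arg("`prune_ratio` must be in (0, 1)")
    }
    keep_n <- floor((1 - prune_ratio) * nrow(pairs))
    if (sum(retained) > keep_n) {
      ord <- order(abs(normalized), decreasing = TRUE)
      allowed <- ord[seq_len(keep_n)]
      retained <- retained & seq_len(nrow(pairs)) %in% allowed
    }
  }

  adjacency <- matrix(0, k, k, dimnames = list(nodes, nodes))
  for (r in which(retained)) {
    adjacency[pairs$source[r], pairs$target[r]] <- normalized[r]
  }

  structure(
    list(
      nodes = nodes,
      max_lag = as.integer(max_lag),
      threshold = threshold,
      edges = tibble::tibble(
        source = nodes[pairs$source],
        target = nodes[pairs$target],
        lag = as.integer(best_lag),
        weight = best_w,
        normalized_weight = normalized,
        retained = retained
      ),
      adjacency = adjacency,
      norm_factor = norm_factor
    ),
    class = "tcg"
  )
}

#' @export
print.tcg <- function(x, ...) {
  cat("Temporal causal graph:", length(x$nodes), "nodes,",
      sum(x$edges$retained), "retained edges (threshold", x$threshold,
      ", max lag", x$max_lag, ")\n")
  invisible(x)
}

#' Per-node features of a temporal causal graph
#'
#' Computes, on the thresholded adjacency: in/out degree, weighted degree
#' (sum of absolute incident normalized weights), mean and max absolute
#' incident weight, an edge-confidence score (max absolute incident
#' normalized weight, already in `[0, 1]`), strongly-connected-component id
#' and size, longest causal chain length (longest directed path in the SCC
#' condensation; within a cycle, SCC size minus one), and the count of
#' directed 2-chains through the node.
#'
#' @param graph A [build_tcg()] result.
#' @return Tibble with one row per node and 10 feature columns after `node`.
#' @export
extract_tcg_features <- function(graph) {
  stopifnot(inherits(graph, "tcg"))
  A <- graph$adjacency
  k <- nrow(A)
  B <- A != 0
  in_deg <- colSums(B)
  out_deg <- rowSums(B)
  wdeg <- rowSums(abs(A)) + colSums(abs(A))
  inc_w <- lapply(seq_len(k), function(i) {
    w <- c(abs(A[i, B[i, ]]), abs(A[B[, i], i]))
    w[w > 0]
  })
  mean_w <- vapply(inc_w, function(w) if (length(w)) mean(w) else 0, numeric(1))
  max_w <- vapply(inc_w, function(w) if (length(w)) max(w) else 0, numeric(1))

  g <- igraph::graph_from_adjacency_matrix(1 * B, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  scc_id <- comp$membership
  scc_size <- comp$csize[scc_id]

  # Longest chain by DP over the SCC condensation in reverse topological
  # order: L(c) = (|c| - 1) + max over successors c' of (1 + L(c')).
  nscc <- comp$no
  succ <- vector("list", nscc)
  for (i in seq_len(k)) {
    for (j in which(B[i, ])) {
      if (scc_id[i] != scc_id[j]) {
        succ[[scc_id[i]]] <- union(succ[[scc_id[i]]], scc_id[j])
      }
    }
  }
  Lmemo <- rep(NA_real_, nscc)
  chain_of_scc <- function(c) {
    if (!is.na(Lmemo[c])) return(Lmemo[c])
    base <- comp$csize[c] - 1
    ext <- 0
    for (s in succ[[c]]) ext <- max(ext, 1 + chain_of_scc(s))
    Lmemo[c] <<- base + ext
    Lmemo[c]
  }
  chain <- vapply(scc_id, chain_of_scc, numeric(1))

  motif <- vapply(seq_len(k), function(v) {
    ins <- setdiff(which(B[, v]), v)
    outs <- setdiff(which(B[v, ]), v)
    sum(outer(ins, outs, FUN = "!="))
  }, numeric(1))

  tibble::tibble(
    node = graph$nodes,
    in_degree = unname(as.numeric(in_deg)),
    out_degree = unname(as.numeric(out_deg)),
    weighted_degree = unname(wdeg),
    mean_incident_weight = unname(mean_w),
    max_incident_weight = unname(max_w),
    edge_confidence = unname(max_w),
    scc_id = unname(as.numeric(scc_id)),
    scc_size = unname(as.numeric(scc_size)),
    chain_length = unname(chain),
    motif_2chains = unname(motif)
  )
}

#' Build a temporal causal graph from a cross-sectional EHR table
#'
#' Cross-sectional records have no clock; record order within sliding windows
#' serves as pseudo-time (window length 32, stride 1 by default), and each
#' normalized feature column is one node series.
#'
#' @param table Normalized EHR tibble.
#' @param label_col Label column name.
#' @param window,stride Pseudo-time window length and stride.
#' @inheritParams build_tcg
#' @return A `tcg` object over the feature columns.
#' @export
tcg_from_table <- function(table, label_col = "event", max_lag = 3,
                           threshold = 0.3, min_edge_weight = 0.05,
                           window = 32, stride = 1) {
  feats <- feature_cols(table, label_col)
  panel <- as.matrix(table[feats])
  build_tcg(panel, max_lag = max_lag, threshold = threshold,
            min_edge_weight = min_edge_weight, window = window,
            stride = stride)
}

#' Assemble the node matrix from preprocessed features and TCG features
#'
#' Each record's row is its preprocessed feature vector concatenated with an
#' activity-weighted summary of the per-feature graph statistics: the
#' normalized feature values of the record (all in `[0, 1]`) weight the rows
#' of the TCG feature table, and their weighted mean forms the record's graph
#' feature block (`tcg_*` columns). A record with all-zero features gets a
#' zero block.
#'
#' @param table Normalized EHR tibble (the feature block `F`).
#' @param tcg_features Tibble from [extract_tcg_features()] whose `node`
#'   column matches the feature columns of `table`.
#' @param label_col Label column name.
#' @return Tibble with `|F| + l` feature columns plus the label.
#' @export
build_node_matrix <- function(table, tcg_features, label_col = "event") {
  feats <- feature_cols(table, label_col)
  if (!setequal(tcg_features$node, feats)) {
    stop_data("TCG feature nodes do not match the table's feature columns")
  }
  Nmat <- as.matrix(tcg_features[match(feats, tcg_features$node),
                                 setdiff(names(tcg_features), "node")])
  Fmat <- as.matrix(table[feats])
  wsum <- rowSums(Fmat)
  W <- Fmat / ifelse(wsum > 0, wsum, 1)
  W[wsum == 0, ] <- 0
  block <- W %*% Nmat
  colnames(block) <- paste0("tcg_", colnames(Nmat))
  out <- dplyr::bind_cols(table[feats], tibble::as_tibble(block))
  out[[label_col]] <- table[[label_col]]
  out
}
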