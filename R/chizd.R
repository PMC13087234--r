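#' Calinski-Harabasz score of a partition
#'
#' `(eta1 / eta2) * ((n - p) / (p - 1))` with `eta1` the between-cluster and
#' `eta2` the within-cluster dispersion (trace form). Used to score sampled
#' centroid initializations. `eta2 = 0` (all clusters collapsed onto their
#' centroids) returns `Inf`; `eta1 = 0` (all points identical) returns 0.
#'
#' @param points Numeric matrix, rows = points.
#' @param centroids Numeric matrix, rows = the `p` centroids.
#' @param assignment Integer vector mapping each point to a centroid row.
#' @return A single score.
#' @export
chi_score <- function(points, centroids, assignment) {
  points <- as.matrix(points)
  n <- nrow(points)
  p <- nrow(centroids)
  if (p < 2 || n <= p) stop_arg("need n > p >= 2 for the CHI score")
  mu <- colMeans(points)
  eta1 <- 0
  eta2 <- 0
  for (k in seq_len(p)) {
    idx <- which(assignment == k)
    if (!length(idx)) next
    mk <- colMeans(points[idx, , drop = FALSE])
    eta1 <- eta1 + length(idx) * sum((mk - mu)^2)
    eta2 <- eta2 + sum(sweep(points[idx, , drop = FALSE], 2, mk)^2)
  }
  if (eta1 == 0) return(0)
  if (eta2 == 0) return(Inf)
  (eta1 / eta2) * ((n - p) / (p - 1))
}

#' Zhonghua distance configuration
#'
#' @param weights Nonnegative per-coordinate feature weights (recycled;
#'   default uniform 1).
#' @param huber Positive Huber parameter `h` (default 1): the per-coordinate
#'   penalty is `t^2 / 2` for `|t| <= h`, else `h * (|t| - h / 2)`.
#' @param similarity `"plus"` (literal `1 + cos` factor, the default),
#'   `"minus"` (conventional `1 - cos`), or `"off"` (factor 1).
#' @return An object of class `zd_config`.
#' @export
zd_config <- function(weights = 1, huber = 1,
                      similarity = c("plus", "minus", "off")) {
  if (any(weights < 0)) stop_arg("feature weights must be nonnegative")
  if (huber <= 0) stop_arg("Huber parameter must be positive")
  structure(list(weights = weights, huber = huber,
                 similarity = match.arg(similarity)),
            class = "zd_config")
}

huber_fun <- function(t, h) {
  ifelse(abs(t) <= h, t^2 / 2, h * (abs(t) - h / 2))
}

#' Zhonghua distance between a centroid and a gradient
#'
#' `V = sqrt(sum(r * huber(L - x))) * factor`, where the factor is
#' `1 + cos(L, x)` (literal form), `1 - cos(L, x)`, or 1 depending on the
#' configured similarity term. The cosine of a zero vector is defined as 0
#' with a warning.
#'
#' @param L,x Equal-length numeric vectors.
#' @param config A [zd_config()].
#' @return A single nonnegative distance.
#' @export
zhonghua_distance <- function(L, x, config = zd_config()) {
  if (length(L) != length(x)) stop_data("vector length mismatch")
  r <- rep_len(config$weights, length(L))
  base <- sqrt(sum(r * huber_fun(L - x, config$huber)))
  fac <- switch(config$similarity,
    off = 1,
    plus = 1 + cosine_sim(L, x),
    minus = 1 - cosine_sim(L, x)
  )
  base * fac
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warn("cosine similarity of a zero vector defined as 0")
    return(0)
  }
  sum(a * b) / (na * nb)
}

zd_matrix <- function(points, centroids, config) {
  V <- matrix(0, nrow(points), nrow(centroids))
  for (k in seq_len(nrow(centroids))) {
    for (i in seq_len(nrow(points))) {
      V[i, k] <- zhonghua_distance(centroids[k, ], points[i, ], config)
    }
  }
  V
}

#' Cluster-wise aggregation of hospital gradients
#'
#' K-means under the Zhonghua distance with Calinski-Harabasz-scored
#' initialization: `n_candidates` random centroid sets (sampled from the
#' points) each get one assignment pass, the set with the highest CHI score
#' wins; Lloyd iterations then alternate Zhonghua assignment and mean
#' centroid updates until assignments stabilize (at most `max_iter`). An
#' emptied cluster is repaired by seizing the point farthest from its own
#' centroid. Each cluster's aggregate is the mean of its member gradients.
#' With fewer than 2 gradients or `p = 1` the call degrades to a
#' single-cluster mean passthrough.
#'
#' @param G Numeric matrix (rows = hospital gradients) or list of equal
#'   length vectors; row names identify hospitals.
#' @param p Number of clusters.
#' @param config A [zd_config()].
#' @param n_candidates Number of CHI-scored random initializations
#'   (default 10).
#' @param seed Integer seed.
#' @param max_iter Lloyd iteration cap (default 100).
#' @param init_centroids Optional matrix of `p` starting centroids; when
#'   given, the CHI candidate search is skipped (used e.g. to compare
#'   against a reference k-means from identical starts).
#' @return An object of class `cluster_assignment`: `centroids`,
#'   `assignment`, per-cluster aggregates `X` (matrix, one row per cluster),
#'   `chi`, `iterations`, and the candidate CHI scores.
#' @export
cluster_aggregate <- function(G, p = 2, config = zd_config(),
                              n_candidates = 10, seed = 1L, max_iter = 100,
                              init_centroids = NULL) {
  if (is.list(G) && !is.data.frame(G)) G <- do.call(rbind, G)
  G <- as.matrix(G)
  n <- nrow(G)
  ids <- rownames(G) %||% paste0("H", seq_len(n))
  if (n < 2 || p < 2) {
    X <- matrix(colMeans(G), 1)
    return(structure(list(centroids = X, assignment = setNames(rep(1L, n), ids),
                          X = X, chi = NA_real_, iterations = 0L,
                          candidate_chi = numeric(0)),
                     class = "cluster_assignment"))
  }
  if (n < p) stop_data("fewer gradients than clusters")
  if (n == p) {
    # one gradient per cluster: the partition is forced, CHI undefined
    return(structure(list(centroids = G,
                          assignment = setNames(seq_len(n), ids),
                          X = G, chi = NA_real_, iterations = 0L,
                          candidate_chi = numeric(0)),
                     class = "cluster_assignment"))
  }

  with_seed(seed, {
    assign_pass <- function(centroids) {
      V <- zd_matrix(G, centroids, config)
      apply(V, 1, which.min)
    }
    best <- NULL
    if (!is.null(init_centroids)) {
      best <- list(centroids = as.matrix(init_centroids), chi = NA_real_)
      n_candidates <- 0L
    }
    candidate_chi <- numeric(n_candidates)
    for (c in seq_len(n_candidates)) {
      centroids <- G[sample.int(n, p), , drop = FALSE]
      a <- assign_pass(centroids)
      candidate_chi[c] <- if (length(unique(a)) < 2) -Inf else {
        chi_score(G, centroids, a)
      }
      if (is.null(best) || candidate_chi[c] > best$chi) {
        best <- list(centroids = centroids, chi = candidate_chi[c])
      }
    }
    centroids <- best$centroids
    assignment <- assign_pass(centroids)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      # centroid update
      for (k in seq_len(p)) {
        idx <- which(assignment == k)
        if (length(idx)) {
          centroids[k, ] <- colMeans(G[idx, , drop = FALSE])
        }
      }
      new_assignment <- assign_pass(centroids)
      # empty-cluster repair: seize the point farthest from its own centroid
      for (k in seq_len(p)) {
        if (!any(new_assignment == k)) {
          d_own <- vapply(seq_len(n), function(i) {
            zhonghua_distance(centroids[new_assignment[i], ], G[i, ], config)
          }, numeric(1))
          movable <- which(tabulate(new_assignment, p)[new_assignment] > 1)
          victim <- movable[which.max(d_own[movable])]
          new_assignment[victim] <- k
          centroids[k, ] <- G[victim, ]
        }
      }
      if (identical(new_assignment, assignment) || iter >= max_iter) {
        assignment <- new_assignment
        break
      }
      assignment <- new_assignment
    }
    X <- matrix(0, p, ncol(G))
    for (k in seq_len(p)) {
      idx <- which(assignment == k)
      X[k, ] <- colMeans(G[idx, , drop = FALSE])
    }
    chi <- if (length(unique(assignment)) >= 2) {
      chi_score(G, centroids, assignment)
    } else {
      NA_real_
    }
    structure(list(centroids = centroids,
                   assignment = setNames(as.integer(assignment), ids),
                   X = X, chi = chi, iterations = iter,
                   candidate_chi = candidate_chi),
              class = "cluster_assignment")
  })
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Cluster assignment:", length(x$assignment), "gradients into",
      nrow(x$X), "clusters; CHI =", format(x$chi, digits = 5),
      "after", x$iterations, "iterations\n")
  invisible(x)
}
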