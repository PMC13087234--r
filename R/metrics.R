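#' Continual-learning metrics from a task-accuracy matrix
#'
#' Takes the accuracy matrix `alpha` with `alpha[v, s]` = accuracy on task
#' `s` after learning task `v`, for `Tn` tasks. Forward transfer needs the
#' pre-training row `alpha[0, ]` (accuracy of the randomly initialized
#' model), so `alpha` may have `Tn + 1` rows with row 1 = `v = 0`; with a
#' square `Tn x Tn` matrix forward transfer is returned as `NA`.
#'
#' Retained accuracy `= mean_{s < Tn} alpha[Tn, s]`; average forgetting
#' `= mean_{s < Tn} (max_{v < s} alpha[v, s] - alpha[Tn, s])`; forward
#' transfer `= (1/(Tn-1)) * sum_{s = 2..Tn-1} (alpha[s-1, s] - alpha[0, s])`
#' (as printed, the last task is skipped); backward transfer
#' `= mean_{s < Tn} (alpha[Tn, s] - alpha[s, s])`.
#'
#' @param alpha Numeric matrix, entries in `[0, 1]`.
#' @param Tn Number of tasks (>= 2); default inferred from `ncol(alpha)`.
#' @return Tibble with one row: `retained_accuracy`, `average_forgetting`,
#'   `forward_transfer`, `backward_transfer`.
#' @export
continual_metrics <- function(alpha, Tn = ncol(alpha)) {
  alpha <- as.matrix(alpha)
  if (Tn < 2) stop_arg("`Tn` must be >= 2")
  has_zero_row <- nrow(alpha) == Tn + 1
  if (!has_zero_row && nrow(alpha) != Tn) {
    stop_arg("`alpha` must have Tn or Tn + 1 rows")
  }
  # a(v, s) with 1-based task indices; v = 0 is the pre-training row
  a <- function(v, s) alpha[v + has_zero_row, s]
  s_idx <- seq_len(Tn - 1)
  retained <- mean(vapply(s_idx, function(s) a(Tn, s), numeric(1)))
  forgetting <- mean(vapply(s_idx, function(s) {
    v_first <- if (has_zero_row) 0 else 1
    cand_v <- if (v_first <= s - 1) seq(v_first, s - 1) else s
    max(vapply(cand_v, function(v) a(v, s), numeric(1))) - a(Tn, s)
  }, numeric(1)))
  forward <- if (has_zero_row && Tn >= 3) {
    sum(vapply(2:(Tn - 1), function(s) a(s - 1, s) - a(0, s),
               numeric(1))) / (Tn - 1)
  } else if (has_zero_row) {
    0
  } else {
    NA_real_
  }
  backward <- mean(vapply(s_idx, function(s) a(Tn, s) - a(s, s), numeric(1)))
  tibble::tibble(retained_accuracy = retained,
                 average_forgetting = forgetting,
                 forward_transfer = forward,
                 backward_transfer = backward)
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall, F-measure, PPV, NPV, FNR and FPR from the
#' four confusion counts. A metric whose denominator is zero is returned as
#' `NA` (an explicit undefined marker, never 0).
#'
#' @param TP,TN,FP,FN Nonnegative integer counts.
#' @return Tibble with one row of the eight metrics.
#' @export
classification_metrics <- function(TP, TN, FP, FN) {
  if (any(c(TP, TN, FP, FN) < 0)) stop_arg("counts must be nonnegative")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- ratio(TP, TP + FP)
  recall <- ratio(TP, TP + FN)
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  tibble::tibble(
    accuracy = ratio(TP + TN, TP + TN + FP + FN),
    precision = precision,
    recall = recall,
    f_measure = f,
    ppv = precision,
    npv = ratio(TN, TN + FN),
    fnr = ratio(FN, FN + TP),
    fpr = ratio(FP, FP + TN)
  )
}

#' Confusion counts from predicted and actual binary labels
#'
#' @param predicted,actual Vectors of 0/1 labels.
#' @return List with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop_arg("length mismatch")
  list(TP = sum(predicted == 1 & actual == 1),
       TN = sum(predicted == 0 & actual == 0),
       FP = sum(predicted == 1 & actual == 0),
       FN = sum(predicted == 0 & actual == 1))
}

#' Regression error, fairness and convergence metrics
#'
#' MSE and MAE of predictions against actuals; Jain's fairness index
#' `(sum x)^2 / (n * sum x^2)` of nonnegative per-client allocations (1 =
#' perfectly even, `1/n` = maximally skewed); loss convergence rate
#' `(loss_end - loss_start) / (rounds_end - rounds_start)`.
#'
#' @param predictions,actuals Equal-length numeric vectors (optional).
#' @param allocations Nonnegative, not-all-zero numeric vector (optional).
#' @param loss_start,loss_end,rounds_start,rounds_end Loss-curve endpoints
#'   (optional).
#' @return Tibble with one row; metrics whose inputs were not supplied are
#'   `NA`.
#' @export
regression_and_fairness <- function(predictions = NULL, actuals = NULL,
                                    allocations = NULL,
                                    loss_start = NULL, loss_end = NULL,
                                    rounds_start = NULL, rounds_end = NULL) {
  mse <- mae <- jain <- lcr <- NA_real_
  if (!is.null(predictions)) {
    if (length(predictions) != length(actuals)) stop_arg("length mismatch")
    mse <- mean((actuals - predictions)^2)
    mae <- mean(abs(actuals - predictions))
  }
  if (!is.null(allocations)) {
    if (any(allocations < 0) || all(allocations == 0)) {
      stop_arg("allocations must be nonnegative and not all zero")
    }
    jain <- sum(allocations)^2 /
      (length(allocations) * sum(allocations^2))
  }
  if (!is.null(loss_start)) {
    if (rounds_end == rounds_start) stop_arg("zero round span")
    lcr <- (loss_end - loss_start) / (rounds_end - rounds_start)
  }
  tibble::tibble(mse = mse, mae = mae, jain_index = jain,
                 loss_convergence_rate = lcr)
}

#' Cluster validity: silhouette and Davies-Bouldin
#'
#' Silhouette: mean over points of `(Near - Int) / max(Int, Near)` with
#' `Int` the mean intra-cluster distance and `Near` the smallest mean
#' distance to another cluster (singleton clusters contribute 0).
#' Davies-Bouldin: `(1/nC) * sum_b max_{c != b} (Cu_b + Cu_c) / Sp_bc` with
#' `Cu` the mean distance to the centroid and `Sp` the centroid separation;
#' coincident centroids give an `Inf` sentinel. Euclidean metric throughout.
#'
#' @param points Numeric matrix, rows = points.
#' @param assignment Integer cluster labels (>= 2 nonempty clusters).
#' @return Tibble with `silhouette` and `davies_bouldin`.
#' @export
cluster_quality <- function(points, assignment) {
  points <- as.matrix(points)
  labs <- sort(unique(assignment))
  if (length(labs) < 2) stop_arg("need at least 2 clusters")
  n <- nrow(points)
  D <- as.matrix(stats::dist(points))
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(assignment == assignment[i])
    if (length(own) == 1) {
      sil[i] <- 0
      next
    }
    Int <- mean(D[i, setdiff(own, i)])
    Near <- min(vapply(setdiff(labs, assignment[i]), function(l) {
      mean(D[i, assignment == l])
    }, numeric(1)))
    sil[i] <- (Near - Int) / max(Int, Near)
  }
  centroids <- do.call(rbind, lapply(labs, function(l) {
    colMeans(points[assignment == l, , drop = FALSE])
  }))
  Cu <- vapply(seq_along(labs), function(k) {
    idx <- which(assignment == labs[k])
    mean(sqrt(rowSums(sweep(points[idx, , drop = FALSE], 2,
                            centroids[k, ])^2)))
  }, numeric(1))
  nC <- length(labs)
  db_terms <- vapply(seq_len(nC), function(b) {
    max(vapply(setdiff(seq_len(nC), b), function(cc) {
      Sp <- sqrt(sum((centroids[b, ] - centroids[cc, ])^2))
      if (Sp == 0) Inf else (Cu[b] + Cu[cc]) / Sp
    }, numeric(1)))
  }, numeric(1))
  tibble::tibble(silhouette = mean(sil), davies_bouldin = mean(db_terms))
}

#' Composite security level and attack level
#'
#' Security level is the weighted mean of the five contribution percentages
#' (key length, attack complexity, encryption strength, privacy
#' preservation, implementation security); the weights must sum to 1
#' (default 0.2 each). Attack level is successful over total attacks.
#'
#' @param contributions Numeric vector of 5 percentages in `[0, 100]`.
#' @param weights Numeric vector of 5 weights summing to 1.
#' @param successful_attacks,total_attacks Attack outcome counts (optional).
#' @return Tibble with `security_level` and `attack_level`.
#' @export
security_metrics <- function(contributions, weights = rep(0.2, 5),
                             successful_attacks = NULL,
                             total_attacks = NULL) {
  if (abs(sum(weights) - 1) > 1e-9) stop_arg("weights must sum to 1")
  if (any(contributions < 0 | contributions > 100)) {
    stop_arg("contributions must lie in [0, 100]")
  }
  attack <- if (!is.null(total_attacks) && total_attacks > 0) {
    successful_attacks / total_attacks
  } else {
    NA_real_
  }
  tibble::tibble(security_level = sum(weights * contributions),
                 attack_level = attack)
}
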