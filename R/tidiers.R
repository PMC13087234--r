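#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Broom-style accessors for fitted objects
#'
#' `tidy()` returns the per-component table of a result (edges of a temporal
#' causal graph, per-epoch loss of a GNN fit, memberships of a cluster
#' assignment, the per-round log of a federation run); `glance()` returns a
#' one-row summary.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name fedcep-tidiers
NULL

#' @rdname fedcep-tidiers
#' @export
tidy.tcg <- function(x, ...) x$edges

#' @rdname fedcep-tidiers
#' @export
glance.tcg <- function(x, ...) {
  tibble::tibble(nodes = length(x$nodes),
                 retained_edges = sum(x$edges$retained),
                 threshold = x$threshold, max_lag = x$max_lag,
                 norm_factor = x$norm_factor)
}

#' @rdname fedcep-tidiers
#' @export
tidy.gnn_fit <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$metrics$loss), loss = x$metrics$loss)
}

#' @rdname fedcep-tidiers
#' @export
glance.gnn_fit <- function(x, ...) {
  tibble::tibble(train_accuracy = x$metrics$train_accuracy,
                 test_accuracy = x$metrics$test_accuracy,
                 parameters = length(x$gradient),
                 epochs = x$config$epochs)
}

#' @rdname fedcep-tidiers
#' @export
tidy.cluster_assignment <- function(x, ...) {
  tibble::tibble(hospital = names(x$assignment),
                 cluster = as.integer(x$assignment))
}

#' @rdname fedcep-tidiers
#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble::tibble(clusters = nrow(x$X), chi = x$chi,
                 iterations = x$iterations)
}

#' @rdname fedcep-tidiers
#' @export
tidy.federation_result <- function(x, ...) x$round_log

#' @rdname fedcep-tidiers
#' @export
glance.federation_result <- function(x, ...) {
  tibble::as_tibble(x$summary)
}

#' Plot methods
#'
#' `autoplot()` draws the natural figure of each result type: per-round
#' accuracy for a federation run, the loss curve for a GNN fit, and the
#' normalized-weight adjacency for a temporal causal graph.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name fedcep-autoplot
NULL

#' @rdname fedcep-autoplot
#' @export
autoplot.federation_result <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$round_log[c("round", "val_accuracy", "mean_test_accuracy")],
    -"round", names_to = "series", values_to = "accuracy")
  ggplot2::ggplot(df, ggplot2::aes(.data$round, .data$accuracy,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "federated round", y = "accuracy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname fedcep-autoplot
#' @export
autoplot.gnn_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss") +
    ggplot2::theme_minimal()
}

#' @rdname fedcep-autoplot
#' @export
autoplot.tcg <- function(object, ...) {
  df <- object$edges
  ggplot2::ggplot(df, ggplot2::aes(.data$target, .data$source,
                                   fill = ifelse(df$retained,
                                                 df$normalized_weight, 0))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "weight") +
    ggplot2::labs(x = "target", y = "source") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
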