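#' Polynomial decay factor
#'
#' `R(b) = 1 / (1 + lambda * b)^tau`: 1 at iteration zero, strictly
#' decreasing in `b`, approaching 0 as `b` grows. Shapes both the
#' local-vs-global blending weight and the replay-buffer sampling weights so
#' early-task samples never dominate the buffer.
#'
#' @param lambda Decay-rate controlling factor, > 0.
#' @param tau Polynomial degree, > 0.
#' @param b Total iteration counter, >= 0.
#' @return The decay factor in `(0, 1]`.
#' @export
polynomial_decay <- function(lambda, tau, b) {
  if (lambda <= 0 || tau <= 0) stop_arg("`lambda` and `tau` must be positive")
  if (any(b < 0)) stop_arg("`b` must be nonnegative")
  1 / (1 + lambda * b)^tau
}

#' Blend the local replay gradient with the global gradient
#'
#' `A = R * G + (1 - R) * Y` elementwise: at `R = 1` the update is purely
#' local replay, at `R = 0` it adopts the global gradient outright. Every
#' coordinate of `A` lies between the corresponding coordinates of `G` and
#' `Y`.
#'
#' @param G Local replay gradient vector.
#' @param Y Global gradient vector of the same length.
#' @param decay Blending weight in `[0, 1]`.
#' @return The blended gradient.
#' @export
blend_gradients <- function(G, Y, decay) {
  if (length(G) != length(Y)) stop_data("gradient length mismatch")
  if (decay < 0 || decay > 1) stop_arg("`decay` must lie in [0, 1]")
  decay * G + (1 - decay) * Y
}

#' Bounded replay buffer of past gradients
#'
#' Stores gradients (never raw examples, respecting the privacy premise of
#' the framework) with their insertion round and a sampling weight set to the
#' decay factor at insertion time; when full, the oldest entry is evicted.
#'
#' @param capacity Maximum number of stored gradients (default 20).
#' @return An object of class `replay_buffer`.
#' @export
replay_buffer <- function(capacity = 20) {
  structure(list(entries = list(), capacity = as.integer(capacity)),
            class = "replay_buffer")
}

#' @rdname replay_buffer
#' @param buffer A `replay_buffer`.
#' @param gradient Numeric vector to store.
#' @param round Insertion round.
#' @param weight Positive sampling weight (the decay factor at insertion).
#' @export
buffer_push <- function(buffer, gradient, round, weight) {
  if (weight <= 0) stop_arg("buffer weights must be positive")
  entry <- list(gradient = gradient, round = round, weight = weight)
  buffer$entries <- c(buffer$entries, list(entry))
  if (length(buffer$entries) > buffer$capacity) {
    buffer$entries <- buffer$entries[-1]
  }
  buffer
}

#' Effective sampling weights of buffered entries
#'
#' An entry inserted at round `r`, viewed at the current counter `b`, gets
#' weight `polynomial_decay(lambda, tau, b - r)`: the decay acts on the
#' entry's age, so early-task samples lose influence and never dominate the
#' replay mixture.
#'
#' @param buffer A [replay_buffer()].
#' @param config A [decay_config()] (its `b` is the current counter).
#' @return Numeric vector of unnormalized weights, one per entry.
#' @export
buffer_weights <- function(buffer, config) {
  if (!length(buffer$entries)) return(numeric(0))
  rounds <- vapply(buffer$entries, `[[`, numeric(1), "round")
  polynomial_decay(config$lambda, config$tau, pmax(config$b - rounds, 0))
}

# Age-decayed weighted mean of buffered gradients (weights renormalized);
# zero vector of length `len` when the buffer is empty.
buffer_replay_gradient <- function(buffer, len, config) {
  if (!length(buffer$entries)) return(numeric(len))
  w <- buffer_weights(buffer, config)
  w <- w / sum(w)
  out <- numeric(len)
  for (i in seq_along(buffer$entries)) {
    out <- out + w[i] * buffer$entries[[i]]$gradient
  }
  out
}

#' Decay configuration for the continual update
#'
#' Defaults (`lambda = 0.05`, `tau = 1`) keep the blending weight in
#' roughly `[0.5, 1]` over 20 federated rounds — a gentle decay that lets
#' the global update in progressively without overwriting local knowledge.
#'
#' @param lambda,tau Positive decay parameters.
#' @param b Starting iteration counter (>= 0).
#' @return An object of class `decay_config`.
#' @export
decay_config <- function(lambda = 0.05, tau = 1, b = 0L) {
  polynomial_decay(lambda, tau, 0)  # validates lambda/tau
  if (b < 0) stop_arg("`b` must be nonnegative")
  structure(list(lambda = lambda, tau = tau, b = as.integer(b)),
            class = "decay_config")
}

#' Continual update of local parameters with experience replay
#'
#' Forms the local replay gradient `G` as the decay-weighted mean of the
#' buffered past gradients (a zero vector when the buffer is empty), blends
#' it with the incoming global gradient `Y` using the polynomial decay
#' factor at the current iteration, increments the local parameters by the
#' blend, advances the iteration counter, and pushes the blended gradient
#' into the buffer with the current decay weight.
#'
#' @param local_params Numeric parameter vector (flattened).
#' @param buffer A [replay_buffer()].
#' @param Y Global gradient vector, same length as `local_params`.
#' @param config A [decay_config()].
#' @return List with updated `params`, `buffer`, `config` (counter
#'   advanced), the applied `blend`, and the `decay` used.
#' @export
continual_update <- function(local_params, buffer, Y, config = decay_config()) {
  if (length(Y) != length(local_params)) stop_data("gradient length mismatch")
  decay <- polynomial_decay(config$lambda, config$tau, config$b)
  G <- buffer_replay_gradient(buffer, length(Y), config)
  A <- blend_gradients(G, Y, decay)
  config$b <- config$b + 1L
  buffer <- buffer_push(buffer, A, round = config$b, weight = decay)
  list(params = local_params + A, buffer = buffer, config = config,
       blend = A, decay = decay)
}
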