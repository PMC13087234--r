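#' Build the EHR graph over records
#'
#' Nodes are the rows of the node matrix; undirected edges connect each node
#' to its `k_neighbours` nearest neighbours by cosine similarity of feature
#' rows, symmetrized (union), with self-loops added. `k_neighbours = 0`
#' yields the identity adjacency (self-loops only).
#'
#' @param K Numeric matrix or tibble of node features (rows = records).
#' @param k_neighbours Number of nearest neighbours, `0 <= k < nrow(K)`.
#' @param label_col If `K` is a data frame containing this column it is
#'   dropped from the features and kept as `labels`.
#' @return An object of class `ehr_graph` with `features`, binary `adjacency`
#'   (diagonal ones) and optional `labels`.
#' @export
build_ehr_graph <- function(K, k_neighbours = 8, label_col = "event") {
  labels <- NULL
  if (is.data.frame(K)) {
    if (label_col %in% names(K)) {
      labels <- as.integer(K[[label_col]])
      K <- K[setdiff(names(K), label_col)]
    }
    K <- as.matrix(K)
  }
  if (!all(is.finite(K))) stop_data("node features must be finite")
  n <- nrow(K)
  if (k_neighbours >= n) stop_arg("`k_neighbours` must be < number of nodes")
  A <- diag(1, n)
  if (k_neighbours > 0) {
    nrm <- sqrt(rowSums(K^2))
    Kn <- K / ifelse(nrm > 0, nrm, 1)
    S <- Kn %*% t(Kn)
    diag(S) <- -Inf
    for (i in seq_len(n)) {
      nb <- order(S[i, ], decreasing = TRUE)[seq_len(k_neighbours)]
      A[i, nb] <- 1
      A[nb, i] <- 1
    }
  }
  structure(list(features = K, adjacency = A, labels = labels,
                 k_neighbours = as.integer(k_neighbours)),
            class = "ehr_graph")
}

#' Mean-centering normalization
#'
#' Subtracts the across-node mean of each feature column, so per-column node
#' means are exactly zero. Applied after every message-passing layer to
#' counter over-smoothing: centering removes the shared drift component that
#' repeated neighbourhood averaging accumulates, while preserving
#' node-specific deviations.
#'
#' @param x Numeric matrix (rows = nodes).
#' @return The centered matrix.
#' @export
mcn <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop_data("empty feature matrix")
  sweep(x, 2, colMeans(x))
}

#' Initialize GNN parameters
#'
#' A linear input embedding, `layers` residual message-passing blocks of a
#' shared hidden width, a ReLU readout, and a 2-class softmax head. Weights
#' are Glorot-scaled normal draws; biases start at zero.
#'
#' @param input_dim Number of node-feature columns.
#' @param hidden Hidden width (default 32).
#' @param layers Number of message-passing layers, 2-4 (default 3).
#' @param seed Integer seed for the initial draws.
#' @return An object of class `gnn_params` (named list of matrices/vectors).
#' @export
gnn_params <- function(input_dim, hidden = 32, layers = 3, seed = 1L) {
  if (layers < 2 || layers > 4) stop_config("`layers` must be between 2 and 4")
  glorot <- function(nin, nout) {
    matrix(rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
  }
  with_seed(seed, {
    p <- list(W_in = glorot(input_dim, hidden), b_in = numeric(hidden))
    for (l in seq_len(layers)) {
      p[[paste0("W", l)]] <- glorot(hidden, hidden)
      p[[paste0("b", l)]] <- numeric(hidden)
    }
    p$W_r <- glorot(hidden, hidden)
    p$b_r <- numeric(hidden)
    p$W_h <- glorot(hidden, 2)
    p$b_h <- numeric(2)
    structure(p, layers = as.integer(layers), hidden = as.integer(hidden),
              input_dim = as.integer(input_dim), class = "gnn_params")
  })
}

#' Flatten GNN parameters to a gradient-shaped vector (and back)
#'
#' @param params A `gnn_params` object.
#' @return `flatten_params`: a numeric vector; `unflatten_params`: a
#'   `gnn_params` object with the template's shapes.
#' @export
flatten_params <- function(params) {
  unlist(lapply(unclass(params), as.numeric), use.names = FALSE)
}

#' @rdname flatten_params
#' @param values Numeric vector of length `length(flatten_params(template))`.
#' @param template A `gnn_params` object providing the shapes.
#' @export
unflatten_params <- function(values, template) {
  out <- unclass(template)
  pos <- 0
  for (nm in names(out)) {
    len <- length(out[[nm]])
    chunk <- values[pos + seq_len(len)]
    if (is.matrix(out[[nm]])) {
      out[[nm]] <- matrix(chunk, nrow(out[[nm]]), ncol(out[[nm]]),
                          dimnames = dimnames(out[[nm]]))
    } else {
      out[[nm]] <- setNames(chunk, names(out[[nm]]))
    }
    pos <- pos + len
  }
  if (pos != length(values)) stop_data("parameter vector length mismatch")
  attributes(out) <- attributes(template)
  out
}

relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

row_normalize <- function(A) A / rowSums(A)

#' Forward pass of the mean-centered GNN
#'
#' Per layer: messages `m = ReLU(W %*% mean_{j in N(i)} h_j + b)` (mean
#' neighbourhood aggregation including the self-loop), residual node update
#' `h <- h + m`, then mean-centering normalization between layers. A ReLU
#' readout maps each node to a single vector and a softmax head produces the
#' class probabilities `(S1 normal, S2 event)`, which sum to one per node.
#'
#' @param graph An [build_ehr_graph()] result.
#' @param params A [gnn_params()] object.
#' @param use_mcn Apply mean-centering between layers (default `TRUE`);
#'   disabling it exposes the over-smoothing behaviour MCN counters.
#' @param cache Return intermediate activations for backpropagation.
#' @return Tibble with `prob_normal`, `prob_event`, `label` (argmax, 0/1);
#'   with `cache = TRUE`, a list with the tibble and activations.
#' @export
gnn_forward <- function(graph, params, use_mcn = TRUE, cache = FALSE) {
  K <- graph$features
  L <- attr(params, "layers")
  Ahat <- row_normalize(graph$adjacency)
  H <- K %*% params$W_in +
    matrix(params$b_in, nrow(K), length(params$b_in), byrow = TRUE)
  Hs <- list(H)
  Zs <- list()
  Ss <- list()
  for (l in seq_len(L)) {
    S <- Ahat %*% H
    Z <- S %*% params[[paste0("W", l)]] +
      matrix(params[[paste0("b", l)]], nrow(H), ncol(H), byrow = TRUE)
    M <- relu(Z)
    H <- H + M
    if (use_mcn) H <- mcn(H)
    Ss[[l]] <- S
    Zs[[l]] <- Z
    Hs[[l + 1]] <- H
  }
  Zr <- H %*% params$W_r +
    matrix(params$b_r, nrow(H), ncol(H), byrow = TRUE)
  U <- relu(Zr)
  logits <- U %*% params$W_h + matrix(params$b_h, nrow(U), 2, byrow = TRUE)
  P <- softmax_rows(logits)
  pred <- tibble::tibble(
    prob_normal = P[, 1], prob_event = P[, 2],
    label = as.integer(P[, 2] >= P[, 1])
  )
  if (!cache) return(pred)
  list(pred = pred, P = P, U = U, Zr = Zr, Hs = Hs, Zs = Zs, Ss = Ss,
       Ahat = Ahat, K = K, use_mcn = use_mcn)
}

# Backpropagate mean cross-entropy over `batch_idx` nodes; returns gradients
# with the same shapes as `params`. d(mcn)/dX is I - (1/n) 1 1' per column.
gnn_backward <- function(cache, params, labels, batch_idx) {
  L <- attr(params, "layers")
  n <- nrow(cache$P)
  Y <- cbind(1 - labels, labels)
  dLogit <- matrix(0, n, 2)
  dLogit[batch_idx, ] <- (cache$P[batch_idx, , drop = FALSE] -
                            Y[batch_idx, , drop = FALSE]) / length(batch_idx)
  g <- list()
  g$W_h <- t(cache$U) %*% dLogit
  g$b_h <- colSums(dLogit)
  dU <- dLogit %*% t(params$W_h)
  dZr <- dU * (cache$Zr > 0)
  H_L <- cache$Hs[[L + 1]]
  g$W_r <- t(H_L) %*% dZr
  g$b_r <- colSums(dZr)
  dH <- dZr %*% t(params$W_r)
  for (l in rev(seq_len(L))) {
    if (cache$use_mcn) dH <- sweep(dH, 2, colMeans(dH))
    dM <- dH
    dZ <- dM * (cache$Zs[[l]] > 0)
    g[[paste0("W", l)]] <- t(cache$Ss[[l]]) %*% dZ
    g[[paste0("b", l)]] <- colSums(dZ)
    dH <- dH + t(cache$Ahat) %*% (dZ %*% t(params[[paste0("W", l)]]))
  }
  g$W_in <- t(cache$K) %*% dH
  g$b_in <- colSums(dH)
  g[names(unclass(params))]
}

#' Local training configuration
#'
#' Reference settings: Adam, initial learning rate 0.001, batch size 32,
#' cross-entropy loss; 100 epochs standalone, 5 per federated round.
#'
#' @param learning_rate,batch_size,epochs,seed Positive numerics / seed.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32,
                         epochs = 100, seed = 1L) {
  if (learning_rate <= 0 || batch_size <= 0 || epochs <= 0) {
    stop_config("learning_rate, batch_size and epochs must be positive")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(unclass(params), function(p) p * 0),
       v = lapply(unclass(params), function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  p <- unclass(params)
  for (nm in names(p)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  attributes(p) <- attributes(params)
  list(params = p, state = state)
}

ce_loss <- function(P, labels, idx) {
  p_true <- ifelse(labels[idx] == 1, P[idx, 2], P[idx, 1])
  -mean(log(pmax(p_true, 1e-12)))
}

#' Train a local clinical-event-prediction model
#'
#' Builds the EHR graph over all records of the node matrix, splits records
#' into train/test with `floor(0.8 * h)` training nodes (seeded shuffle),
#' and minimizes cross-entropy on the training nodes by mini-batch Adam
#' (transductive node classification: the forward pass runs on the full
#' graph, the loss on the batch). The reported `gradient` is the flattened
#' parameter delta of the run, the object a hospital ships to the server.
#'
#' @param table Normalized EHR tibble; its feature columns (optionally
#'   already concatenated with TCG features via [build_node_matrix()]) form
#'   the node matrix.
#' @param config A [train_config()].
#' @param hidden,layers,k_neighbours Architecture settings.
#' @param init_params Optional `gnn_params` to continue training from.
#' @param label_col Label column name.
#' @return An object of class `gnn_fit`: `params`, `params_before`,
#'   `gradient`, `graph`, `train_idx`/`test_idx`, and `metrics`
#'   (train/test accuracy, per-epoch loss).
#' @export
train_local <- function(table, config = train_config(), hidden = 32,
                        layers = 3, k_neighbours = 8, init_params = NULL,
                        label_col = "event") {
  graph <- build_ehr_graph(table, k_neighbours, label_col)
  labels <- graph$labels
  h <- nrow(graph$features)
  with_seed(config$seed, {
    perm <- sample.int(h)
    n_train <- floor(0.8 * h)
    train_idx <- perm[seq_len(n_train)]
    test_idx <- perm[-seq_len(n_train)]
    if (length(unique(labels[train_idx])) < 2) {
      stop_data("training labels contain a single class")
    }
    params <- init_params %||%
      gnn_params(ncol(graph$features), hidden, layers, seed = config$seed)
    before <- flatten_params(params)
    state <- adam_init(params)
    losses <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      order_idx <- train_idx[sample.int(n_train)]
      batches <- split(order_idx,
                       ceiling(seq_along(order_idx) / config$batch_size))
      for (b in batches) {
        fw <- gnn_forward(graph, params, cache = TRUE)
        grads <- gnn_backward(fw, params, labels, b)
        upd <- adam_step(params, grads, state, config$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      fw <- gnn_forward(graph, params, cache = TRUE)
      losses[ep] <- ce_loss(fw$P, labels, train_idx)
    }
    pred <- gnn_forward(graph, params)
    metrics <- list(
      train_accuracy = mean(pred$label[train_idx] == labels[train_idx]),
      test_accuracy = if (length(test_idx)) {
        mean(pred$label[test_idx] == labels[test_idx])
      } else {
        NA_real_
      },
      loss = losses
    )
    structure(list(params = params, params_before = before,
                   gradient = flatten_params(params) - before,
                   graph = graph, train_idx = train_idx, test_idx = test_idx,
                   metrics = metrics, config = config),
              class = "gnn_fit")
  })
}

#' @export
print.gnn_fit <- function(x, ...) {
  cat("MCN-GNN fit:", length(x$gradient), "parameters;",
      "train accuracy", round(x$metrics$train_accuracy, 4), "/",
      "test accuracy", round(x$metrics$test_accuracy, 4), "\n")
  invisible(x)
}

#' Predict with trained parameters on a (new) graph
#'
#' @param object A `gnn_fit`.
#' @param graph Optional `ehr_graph` (defaults to the training graph).
#' @param ... Unused.
#' @return Prediction tibble as in [gnn_forward()].
#' @export
predict.gnn_fit <- function(object, graph = NULL, ...) {
  gnn_forward(graph %||% object$graph, object$params)
}
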