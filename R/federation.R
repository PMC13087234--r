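#' Federation configuration
#'
#' Reference settings: 5 hospitals with heterogeneous disease tasks, client
#' participation ratio 0.3, 5 epochs per client per round, batch size 32,
#' Dirichlet non-IID concentration 0.5 (mild) / 0.1 (severe). The reference
#' round count is 100; the desk-scale default is 10 rounds, which the
#' simulation completes in well under a CPU-minute.
#'
#' @param n_hospitals Number of hospital nodes.
#' @param rounds Number of federated rounds.
#' @param participation_ratio Fraction of hospitals sampled per round,
#'   `(0, 1]`; participant count is `ceiling(ratio * n)`.
#' @param epochs_per_client Local epochs per federated round.
#' @param baseline_epochs Epochs of the initial standalone local training
#'   each hospital performs before joining federation (the "before" state;
#'   the standalone reference setting is 100 epochs, the desk default 30).
#' @param batch_size,learning_rate Local Adam settings.
#' @param noniid_alpha Dirichlet concentration for label-skewed partitioning.
#' @param p_clusters Number of aggregation clusters.
#' @param n_records Records per hospital cohort.
#' @param hidden,layers,k_neighbours Shared GNN architecture (all hospitals
#'   share parameter shapes so gradients are aggregable).
#' @param lambda,tau,buffer_capacity Continual-update (replay) settings.
#' @param seed Master seed; every stream below derives from it.
#' @return An object of class `federation_config`.
#' @export
federation_config <- function(n_hospitals = 5, rounds = 10,
                              participation_ratio = 0.3,
                              epochs_per_client = 5, baseline_epochs = 30,
                              batch_size = 32,
                              learning_rate = 0.001, noniid_alpha = 0.5,
                              p_clusters = 2, n_records = 500, hidden = 32,
                              layers = 3, k_neighbours = 8, lambda = 0.05,
                              tau = 1, buffer_capacity = 20, seed = 1L) {
  if (n_hospitals < 1) stop_config("`n_hospitals` must be >= 1")
  if (participation_ratio <= 0 || participation_ratio > 1) {
    stop_config("`participation_ratio` must lie in (0, 1]")
  }
  structure(as.list(environment()), class = "federation_config")
}

#' Non-IID label-skewed partitioning
#'
#' For each class, proportions over clients are drawn from a Dirichlet with
#' concentration `alpha` and the class's records are split accordingly:
#' `alpha = 0.5` gives mild skew, `0.1` severe skew, large `alpha`
#' approaches an IID split. Every record is assigned exactly once; draws are
#' repeated until every shard is nonempty.
#'
#' @param dataset Tibble with a label column.
#' @param n_clients Number of shards.
#' @param alpha Positive Dirichlet concentration.
#' @param seed Integer seed.
#' @param label_col Label column name.
#' @return List of `n_clients` integer row-index vectors.
#' @export
partition_noniid <- function(dataset, n_clients, alpha = 0.5, seed = 1L,
                             label_col = "event") {
  n <- nrow(dataset)
  if (n_clients < 1) stop_arg("`n_clients` must be >= 1")
  if (n_clients > n) stop_arg("more clients than records")
  if (alpha <= 0) stop_arg("`alpha` must be positive")
  labels <- dataset[[label_col]]
  with_seed(seed, {
    for (attempt in seq_len(100)) {
      shards <- vector("list", n_clients)
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        props <- rgamma(n_clients, alpha)
        props <- props / sum(props)
        counts <- floor(props * length(idx))
        rem <- length(idx) - sum(counts)
        if (rem > 0) {
          extra <- order(props * length(idx) - counts,
                         decreasing = TRUE)[seq_len(rem)]
          counts[extra] <- counts[extra] + 1
        }
        pos <- 0
        for (k in seq_len(n_clients)) {
          if (counts[k] > 0) {
            shards[[k]] <- c(shards[[k]], idx[pos + seq_len(counts[k])])
            pos <- pos + counts[k]
          }
        }
      }
      if (all(vapply(shards, length, integer(1)) > 0)) {
        return(lapply(shards, sort))
      }
    }
    stop_data("could not produce nonempty shards in 100 attempts")
  })
}

# Heterogeneous, strongly separable disease-task label models: each task
# weights the vital-sign features with a task-specific sign pattern, centred
# so prevalence is near 1/2 and the linear signal is ~4 SD strong.
task_label_model <- function(task) {
  signs <- c(1, -1)[1 + (c(bitwAnd(task, 1), bitwAnd(task, 2),
                           bitwAnd(task, 4), bitwAnd(task, 8)) > 0)]
  coef <- c(age = 1.5 * signs[1], resting_bp = 0.72 * signs[2],
            max_heart_rate = 0.6 * signs[3], cholesterol = 0.06 * signs[4])
  means <- c(age = 54, resting_bp = 132, max_heart_rate = 137,
             cholesterol = 200)
  list(coef = coef, intercept = -sum(coef * means[names(coef)]))
}

hospital_cohort <- function(i, config) {
  spec <- cohort_spec(
    n_records = config$n_records,
    missing_rate = 0.02,
    label_model = task_label_model(i),
    seed = derive_seed(config$seed, "cohort", i)
  )
  generate_cohort(spec)
}

prepare_hospital <- function(i, config) {
  cohort <- hospital_cohort(i, config)
  prep <- preprocess_pipeline(cohort)
  graph_tcg <- tcg_from_table(prep$table)
  feats <- extract_tcg_features(graph_tcg)
  K <- build_node_matrix(prep$table, feats)
  list(id = paste0("H", i), task = i, data = K, tcg = graph_tcg,
       report = prep$report)
}

#' Run the full federated simulation
#'
#' End-to-end loop: hospital registration and login, one baseline local
#' training pass per hospital (the "before federation" reference), then
#' `rounds` federated rounds. Each round samples `ceiling(ratio * n)`
#' hospitals; every participant trains locally from its current parameters,
#' ships its robust-log-scaled, masked and signed gradient, the server
#' authenticates (tampered submissions are excluded), unmasks, inverts the
#' scaling, cluster-aggregates with CHI-initialized Zhonghua k-means,
#' evaluates the per-cluster global model on a server-held validation
#' cohort, and dispatches the cluster gradient to its members, who apply the
#' polynomial-decay replay update. Every step appends a ledger transaction
#' (with a logical clock, so the whole run is bit-reproducible per seed).
#'
#' @param config A [federation_config()].
#' @param tamper List mapping round index to hospital ids that submit a
#'   perturbed identity that round (for exclusion tests); default none.
#' @return An object of class `federation_result`: `round_log` tibble,
#'   `hospital_metrics` tibble (before/after accuracy, precision, recall,
#'   F), `summary` list (mean accuracies, Jain index, cluster quality, loss
#'   convergence rate, ledger verification), the `ledger`, and final
#'   `clustering`.
#' @export
run_simulation <- function(config = federation_config(), tamper = list()) {
  ledger <- ledger_new()
  registry <- hospital_registry(
    salt_seed = paste0("fedcep-", config$seed))
  clock <- 0L
  tick <- function() {
    clock <<- clock + 1L
    sprintf("t%06d", clock)
  }

  hospitals <- lapply(seq_len(config$n_hospitals), prepare_hospital,
                      config = config)
  input_dim <- ncol(hospitals[[1]]$data) - 1L
  init <- gnn_params(input_dim, config$hidden, config$layers,
                     seed = config$seed)

  for (i in seq_along(hospitals)) {
    h <- hospitals[[i]]
    keys <- hrlse_keygen(derive_seed(config$seed, "keys", i))
    password <- paste0("pw-", h$id, "-", config$seed)
    register_hospital(registry, h$id, password, keys$public)
    ledger <- ledger_append(ledger, ledger_transaction(
      h$id, "registration", list(id = h$id), tick()))
    stopifnot(login_hospital(registry, h$id, password))
    ledger <- ledger_append(ledger, ledger_transaction(
      h$id, "login", list(id = h$id), tick()))
    hospitals[[i]]$keys <- keys
    hospitals[[i]]$params <- init
    hospitals[[i]]$buffer <- replay_buffer(config$buffer_capacity)
    hospitals[[i]]$decay <- decay_config(config$lambda, config$tau)
  }

  # server-held validation cohort: an even mixture of the hospital tasks
  val_tabs <- lapply(seq_len(config$n_hospitals), function(i) {
    spec <- cohort_spec(n_records = max(40, config$n_records %/% 5),
                        missing_rate = 0,
                        label_model = task_label_model(i),
                        seed = derive_seed(config$seed, "validation", i))
    generate_cohort(spec)
  })
  val_prep <- preprocess_pipeline(dplyr::bind_rows(val_tabs))
  val_tcg <- tcg_from_table(val_prep$table)
  val_K <- build_node_matrix(val_prep$table, extract_tcg_features(val_tcg))
  val_graph <- build_ehr_graph(val_K, config$k_neighbours)
  global_params <- flatten_params(init)

  eval_params <- function(flat) {
    pred <- gnn_forward(val_graph, unflatten_params(flat, init))
    mean(pred$label == val_graph$labels)
  }

  fit_metrics <- function(fit) {
    pred <- predict(fit)
    cc <- confusion_counts(pred$label[fit$test_idx],
                           fit$graph$labels[fit$test_idx])
    cm <- classification_metrics(cc$TP, cc$TN, cc$FP, cc$FN)
    cm$test_accuracy <- fit$metrics$test_accuracy
    cm
  }

  # baseline local training (the "before federation" state)
  before <- vector("list", config$n_hospitals)
  for (i in seq_along(hospitals)) {
    cfg <- train_config(config$learning_rate, config$batch_size,
                        config$baseline_epochs,
                        seed = derive_seed(config$seed, "baseline", i))
    fit <- train_local(hospitals[[i]]$data, cfg, config$hidden,
                       config$layers, config$k_neighbours,
                       init_params = hospitals[[i]]$params)
    hospitals[[i]]$params <- fit$params
    hospitals[[i]]$fit <- fit
    before[[i]] <- fit_metrics(fit)
    ledger <- ledger_append(ledger, ledger_transaction(
      hospitals[[i]]$id, "local_training",
      list(round = 0, loss = fit$metrics$loss), tick()))
  }

  n_participants <- ceiling(config$participation_ratio * config$n_hospitals)
  round_rows <- list()
  first_loss <- mean(vapply(hospitals,
                            function(h) h$fit$metrics$loss[1], numeric(1)))
  clustering <- NULL
  gradient_rows <- NULL

  for (r in seq_len(config$rounds)) {
    participants <- with_seed(derive_seed(config$seed, "participants", r),
                              sort(sample.int(config$n_hospitals,
                                              n_participants)))
    submissions <- list()
    for (i in participants) {
      h <- hospitals[[i]]
      cfg <- train_config(config$learning_rate, config$batch_size,
                          config$epochs_per_client,
                          seed = derive_seed(config$seed, "train", r, i))
      fit <- train_local(h$data, cfg, config$hidden, config$layers,
                         config$k_neighbours, init_params = h$params)
      hospitals[[i]]$params <- fit$params
      hospitals[[i]]$fit <- fit
      ledger <- ledger_append(ledger, ledger_transaction(
        h$id, "local_training", list(round = r), tick()))
      cipher <- protect_gradient(fit$gradient, h$keys,
                                 nonce = paste0(h$id, "-r", r))
      ledger <- ledger_append(ledger, ledger_transaction(
        h$id, "privacy_preservation",
        list(round = r, key_id = cipher$key_id), tick()))
      claimed <- h$id
      if (h$id %in% (tamper[[as.character(r)]] %||% character(0))) {
        claimed <- paste0(h$id, "x")
      }
      sig <- dsa_sign(claimed, h$keys$public)
      submissions[[h$id]] <- list(index = i, cipher = cipher, sig = sig,
                                  claimed = claimed)
    }

    plain <- list()
    excluded <- character(0)
    for (s in submissions) {
      verdict <- dsa_verify(registry, s$sig, s$claimed)
      ledger <- ledger_append(ledger, ledger_transaction(
        "server", "authentication",
        list(round = r, id = s$claimed, result = verdict$result), tick()))
      if (verdict$result == "J1") {
        plain[[hospitals[[s$index]]$id]] <-
          recover_gradient(s$cipher, hospitals[[s$index]]$keys)
      } else {
        excluded <- c(excluded, hospitals[[s$index]]$id)
      }
    }

    if (!length(plain)) {
      warn(paste("round", r, "skipped: no authenticated participants"))
      round_rows[[r]] <- tibble::tibble(
        round = r, participants = length(participants), authenticated = 0,
        excluded = paste(excluded, collapse = ","), chi = NA_real_,
        val_accuracy = NA_real_, mean_test_accuracy = NA_real_)
      next
    }

    G <- do.call(rbind, plain)
    clustering <- cluster_aggregate(
      G, p = min(config$p_clusters, nrow(G)),
      seed = derive_seed(config$seed, "cluster", r))
    gradient_rows <- G
    ledger <- ledger_append(ledger, ledger_transaction(
      "server", "aggregation",
      list(round = r, clusters = nrow(clustering$X),
           members = as.list(clustering$assignment)), tick()))

    val_acc <- vapply(seq_len(nrow(clustering$X)), function(k) {
      eval_params(global_params + clustering$X[k, ])
    }, numeric(1))
    global_params <- global_params + colMeans(clustering$X)
    ledger <- ledger_append(ledger, ledger_transaction(
      "server", "global_prediction",
      list(round = r, accuracy = val_acc), tick()))

    for (id in names(clustering$assignment)) {
      k <- clustering$assignment[[id]]
      i <- which(vapply(hospitals, `[[`, character(1), "id") == id)
      upd <- continual_update(flatten_params(hospitals[[i]]$params),
                              hospitals[[i]]$buffer, clustering$X[k, ],
                              hospitals[[i]]$decay)
      hospitals[[i]]$params <- unflatten_params(upd$params, init)
      hospitals[[i]]$buffer <- upd$buffer
      hospitals[[i]]$decay <- upd$config
      ledger <- ledger_append(ledger, ledger_transaction(
        id, "continual_update", list(round = r, decay = upd$decay), tick()))
    }

    mean_test <- mean(vapply(hospitals, function(h) {
      pred <- gnn_forward(h$fit$graph, h$params)
      mean(pred$label[h$fit$test_idx] ==
             h$fit$graph$labels[h$fit$test_idx])
    }, numeric(1)))
    round_rows[[r]] <- tibble::tibble(
      round = r, participants = length(participants),
      authenticated = length(plain),
      excluded = paste(excluded, collapse = ","),
      chi = clustering$chi, val_accuracy = mean(val_acc),
      mean_test_accuracy = mean_test)
  }

  after <- lapply(hospitals, function(h) {
    pred <- gnn_forward(h$fit$graph, h$params)
    cc <- confusion_counts(pred$label[h$fit$test_idx],
                           h$fit$graph$labels[h$fit$test_idx])
    cm <- classification_metrics(cc$TP, cc$TN, cc$FP, cc$FN)
    cm$test_accuracy <- mean(pred$label[h$fit$test_idx] ==
                               h$fit$graph$labels[h$fit$test_idx])
    cm
  })

  hospital_metrics <- dplyr::bind_rows(
    dplyr::mutate(dplyr::bind_rows(before),
                  hospital = vapply(hospitals, `[[`, character(1), "id"),
                  phase = "before"),
    dplyr::mutate(dplyr::bind_rows(after),
                  hospital = vapply(hospitals, `[[`, character(1), "id"),
                  phase = "after")
  )

  last_loss <- mean(vapply(hospitals, function(h) {
    tail(h$fit$metrics$loss, 1)
  }, numeric(1)))
  round_log <- dplyr::bind_rows(round_rows)
  final_acc <- hospital_metrics$test_accuracy[
    hospital_metrics$phase == "after"]
  quality <- if (!is.null(gradient_rows) &&
                 length(unique(clustering$assignment)) >= 2) {
    cluster_quality(gradient_rows, clustering$assignment)
  } else {
    tibble::tibble(silhouette = NA_real_, davies_bouldin = NA_real_)
  }
  verification <- verify_chain(ledger)

  structure(list(
    round_log = round_log,
    hospital_metrics = hospital_metrics,
    summary = list(
      mean_test_accuracy = mean(final_acc),
      jain_index = regression_and_fairness(
        allocations = final_acc)$jain_index,
      silhouette = quality$silhouette,
      davies_bouldin = quality$davies_bouldin,
      loss_convergence_rate = regression_and_fairness(
        loss_start = first_loss, loss_end = last_loss,
        rounds_start = 0, rounds_end = config$rounds
      )$loss_convergence_rate,
      ledger_ok = verification$ok
    ),
    ledger = ledger,
    clustering = clustering,
    config = config
  ), class = "federation_result")
}

#' @export
print.federation_result <- function(x, ...) {
  cat("Federated simulation:", x$config$n_hospitals, "hospitals,",
      x$config$rounds, "rounds\n")
  cat("  mean final local test accuracy:",
      round(x$summary$mean_test_accuracy, 4), "\n")
  cat("  Jain fairness index:", round(x$summary$jain_index, 4), "\n")
  cat("  ledger:", if (x$summary$ledger_ok) "verified" else "BROKEN", "\n")
  invisible(x)
}

#' Two-task continual-learning experiment
#'
#' Trains a local model on task A, then applies global updates derived from
#' task B either through the polynomial-decay replay blend (the continual
#' update) or by adopting the global gradient outright (decay forced to 0),
#' and measures the accuracy retained on task A. Run over several seeds; the
#' replay arm should retain strictly more.
#'
#' @param n_seeds Number of replicate seeds (default 5).
#' @param n_records Records per task cohort.
#' @param epochs Local epochs per training run.
#' @param update_rounds Number of task-B update rounds.
#' @param base_seed Master seed.
#' @return Tibble with one row per seed: `retained_mepdr`,
#'   `retained_overwrite`.
#' @export
mepdr_two_task_experiment <- function(n_seeds = 5, n_records = 200,
                                      epochs = 30, update_rounds = 3,
                                      base_seed = 1L) {
  one_seed <- function(s) {
    make_task <- function(task, seed) {
      spec <- cohort_spec(n_records = n_records, missing_rate = 0,
                          label_model = task_label_model(task), seed = seed)
      prep <- preprocess_pipeline(generate_cohort(spec))
      K <- build_node_matrix(prep$table,
                             extract_tcg_features(tcg_from_table(prep$table)))
      K
    }
    KA <- make_task(1, derive_seed(base_seed, "mepdr-A", s))
    KB <- make_task(6, derive_seed(base_seed, "mepdr-B", s))
    cfgA <- train_config(epochs = epochs,
                         seed = derive_seed(base_seed, "fitA", s))
    fitA <- train_local(KA, cfgA, hidden = 16, layers = 2, k_neighbours = 5)

    acc_on_A <- function(flat) {
      pred <- gnn_forward(fitA$graph, unflatten_params(flat, fitA$params))
      mean(pred$label[fitA$test_idx] == fitA$graph$labels[fitA$test_idx])
    }

    run_arm <- function(use_replay) {
      flat <- flatten_params(fitA$params)
      buffer <- replay_buffer(20)
      buffer <- buffer_push(buffer, fitA$gradient, round = 0, weight = 1)
      decay <- decay_config(b = 1L)
      paramsB <- fitA$params
      for (r in seq_len(update_rounds)) {
        cfgB <- train_config(epochs = 10,
                             seed = derive_seed(base_seed, "fitB", s, r))
        fitB <- train_local(KB, cfgB, hidden = 16, layers = 2,
                            k_neighbours = 5, init_params = paramsB)
        paramsB <- fitB$params
        Y <- fitB$gradient
        if (use_replay) {
          upd <- continual_update(flat, buffer, Y, decay)
          flat <- upd$params
          buffer <- upd$buffer
          decay <- upd$config
        } else {
          flat <- flat + Y
        }
      }
      acc_on_A(flat)
    }
    tibble::tibble(seed = s, retained_mepdr = run_arm(TRUE),
                   retained_overwrite = run_arm(FALSE))
  }
  dplyr::bind_rows(lapply(seq_len(n_seeds), one_seed))
}
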