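#' Federation configuration
#'
#' Study defaults: 10 hospital clients, full participation each round,
#' 20 communication rounds. Four strategy arms are supported: full-model
#' FedAvg, full-model FedProx, and their LoRA variants that exchange only
#' adapter (plus optionally head) weights.
#'
#' @param n_clients number of clients K.
#' @param client_fraction fraction of clients selected per round, in (0, 1].
#' @param rounds communication rounds.
#' @param strategy one of `"fedavg"`, `"fedavg_lora"`, `"fedprox"`,
#'   `"fedprox_lora"`.
#' @param mu proximal coefficient for the FedProx arms.
#' @param lora a [lora_config()] for the LoRA arms.
#' @param local a [fedprox_config()] template for client optimisation
#'   (its `mu` is overridden per strategy).
#' @param bit_precision bits per transmitted weight (payload accounting).
#' @param seed integer seed for client selection and per-round shuffling.
#' @return an object of class `federation_config`.
#' @export
federation_config <- function(n_clients = 10L, client_fraction = 1.0,
                              rounds = 20L,
                              strategy = c("fedprox_lora", "fedavg",
                                           "fedavg_lora", "fedprox"),
                              mu = 0.5, lora = lora_config(train_head = TRUE),
                              local = fedprox_config(), bit_precision = 32L,
                              seed = 0L) {
  strategy <- match.arg(strategy)
  if (client_fraction <= 0 || client_fraction > 1)
    stop("client_fraction must be in (0, 1]", call. = FALSE)
  if (n_clients < 1) stop("need at least one client", call. = FALSE)
  structure(list(n_clients = as.integer(n_clients),
                 client_fraction = client_fraction,
                 rounds = as.integer(rounds), strategy = strategy, mu = mu,
                 lora = lora, local = local,
                 bit_precision = as.integer(bit_precision),
                 seed = as.integer(seed)),
            class = "federation_config")
}

strategy_uses_lora <- function(strategy) grepl("lora", strategy)
strategy_uses_prox <- function(strategy) grepl("fedprox", strategy)

#' Sample-weighted aggregation of client updates
#'
#' The server update rule: each exchanged tensor is averaged across clients
#' with weights `n_i / n`, `n = sum(n_i)`. A convex combination, so
#' identical updates aggregate to themselves and client order is
#' irrelevant.
#'
#' @param updates list of `client_update` objects (or lists with `weights`
#'   and `n`).
#' @return named tensor list of the aggregated weights.
#' @export
aggregate_updates <- function(updates) {
  updates <- Filter(function(u) !isTRUE(u$skipped) && u$n > 0, updates)
  if (length(updates) == 0) stop("empty round: no client updates", call. = FALSE)
  ref <- updates[[1]]$weights
  n_total <- sum(vapply(updates, function(u) as.numeric(u$n), numeric(1)))
  out <- lapply(ref, function(x) x * 0)
  for (u in updates) {
    check_same_keys(ref, u$weights, "client updates")
    wgt <- u$n / n_total
    for (nm in names(ref)) out[[nm]] <- out[[nm]] + wgt * u$weights[[nm]]
  }
  out
}

#' Per-round client selection
#'
#' Draws `ceiling(fraction * K)` distinct clients, deterministically for a
#' given (round, seed) pair; full participation returns all clients.
#'
#' @param n_clients K.
#' @param fraction participation fraction in (0, 1].
#' @param round round index (1-based).
#' @param seed federation seed.
#' @return sorted integer vector of client ids (1..K).
#' @export
select_clients <- function(n_clients, fraction = 1.0, round = 1L, seed = 0L) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  if (fraction == 1) return(seq_len(n_clients))
  m <- max(1L, ceiling(fraction * n_clients))
  withr::with_seed((as.integer(seed) * 1000003L + as.integer(round)) %% .Machine$integer.max,
                   sort(sample.int(n_clients, m)))
}

# Accuracy of argmax decisions on an evaluation set (list x, labels y).
evaluate_accuracy <- function(model, eval_set) {
  if (length(eval_set$y) == 0) return(NA_real_)
  pred <- integer(length(eval_set$y))
  for (j in seq_along(eval_set$y)) {
    lg <- vit_forward_one(model, eval_set$x[[j]])$logits
    pred[j] <- which.max(lg) - 1L
  }
  mean(pred == eval_set$y)
}

# Scores (positive-class probability) on an evaluation set.
evaluate_scores <- function(model, eval_set) {
  vapply(seq_along(eval_set$y), function(j) {
    p <- softmax_rows(matrix(vit_forward_one(model, eval_set$x[[j]])$logits, 1))
    p[1, 2]
  }, numeric(1))
}

#' Run one communication round
#'
#' Broadcast the global trainable weights, train the selected clients
#' locally, aggregate by [aggregate_updates()], evaluate the new global
#' model, and log payload bytes for both directions.
#'
#' @param model the current global `vit_model`.
#' @param shards list of `client_shard`s (one per client).
#' @param cfg a [federation_config()].
#' @param round round index (1-based).
#' @param eval_set held-out set (list with `x`, `y`) or `NULL`.
#' @return list with `model` (updated global model) and `log` (one-row
#'   data.frame: round, n_clients, accuracy, mean_local_loss,
#'   uplink_bytes, downlink_bytes, payload_bytes).
#' @export
run_round <- function(model, shards, cfg, round, eval_set = NULL) {
  sel <- select_clients(cfg$n_clients, cfg$client_fraction, round, cfg$seed)
  mu <- if (strategy_uses_prox(cfg$strategy)) cfg$mu else 0
  updates <- list()
  losses <- numeric(0)
  for (cid in sel) {
    lcfg <- cfg$local
    lcfg$mu <- mu
    lcfg$seed <- (cfg$seed * 7919L + round * 104729L + cid) %% .Machine$integer.max
    u <- local_train(shards[[cid]], model, lcfg)
    if (!isTRUE(u$skipped)) {
      updates[[length(updates) + 1L]] <- u
      if (length(u$loss_trace)) losses <- c(losses, u$loss_trace[length(u$loss_trace)])
    }
  }
  agg <- aggregate_updates(updates)
  model$params[names(agg)] <- agg
  per_client <- communication_cost(tensor_elements(agg), cfg$bit_precision,
                                   convention = "bytes")
  uplink <- per_client * length(updates)
  downlink <- per_client * length(sel)
  acc <- if (is.null(eval_set)) NA_real_ else evaluate_accuracy(model, eval_set)
  log <- data.frame(round = round, n_clients = length(sel), accuracy = acc,
                    mean_local_loss = if (length(losses)) mean(losses) else NA_real_,
                    uplink_bytes = uplink, downlink_bytes = downlink,
                    payload_bytes = uplink + downlink)
  list(model = model, log = log)
}

#' Run a full federated training simulation
#'
#' Implements the round loop: initialise the global model (optionally with
#' LoRA adapters for the LoRA arms), then repeat broadcast / local FedProx
#' or FedAvg training / weighted aggregation / evaluation for
#' `cfg$rounds` rounds.
#'
#' @param cfg a [federation_config()].
#' @param shards list of `client_shard`s.
#' @param eval_set held-out evaluation set (list with `x`, `y`) or `NULL`.
#' @param vit a [vit_config()] for the backbone.
#' @param model optional pre-built starting model (overrides `vit`).
#' @return an object of class `federation_run`: list with the final `model`,
#'   `history` (data.frame, one row per round) and `config`.
#' @export
run_federated_training <- function(cfg, shards, eval_set = NULL,
                                   vit = vit_config(), model = NULL) {
  stopifnot(inherits(cfg, "federation_config"))
  if (length(shards) != cfg$n_clients)
    stop("need one shard per client", call. = FALSE)
  if (is.null(model)) {
    model <- build_model(vit, seed = cfg$seed)
    if (strategy_uses_lora(cfg$strategy))
      model <- inject_lora(model, cfg$lora, seed = cfg$seed + 1L)
  }
  history <- NULL
  if (cfg$rounds > 0) {
    for (r in seq_len(cfg$rounds)) {
      rr <- run_round(model, shards, cfg, r, eval_set)
      model <- rr$model
      history <- rbind(history, rr$log)
    }
  } else {
    history <- data.frame(round = integer(0), n_clients = integer(0),
                          accuracy = numeric(0), mean_local_loss = numeric(0),
                          uplink_bytes = numeric(0), downlink_bytes = numeric(0),
                          payload_bytes = numeric(0))
  }
  structure(list(model = model, history = history, config = cfg),
            class = "federation_run")
}

#' @export
print.federation_run <- function(x, ...) {
  h <- x$history
  cat(sprintf("federated run: %s, %d round(s), %d client(s)\n",
              x$config$strategy, nrow(h), x$config$n_clients))
  if (nrow(h)) {
    cat(sprintf("final accuracy %.4f; cumulative payload %.2f MiB\n",
                h$accuracy[nrow(h)], sum(h$payload_bytes) / 2^20))
  }
  invisible(x)
}

#' Rounds to reach a performance level
#'
#' First round whose logged metric reaches `threshold`, or `NA` if never.
#'
#' @param history a `federation_run` history data.frame.
#' @param metric column name (default `"accuracy"`).
#' @param threshold target level.
#' @return integer round index or `NA`.
#' @export
convergence_rounds <- function(history, metric = "accuracy", threshold) {
  if (!nrow(history)) stop("empty history", call. = FALSE)
  if (!metric %in% names(history))
    stop("unknown metric: ", metric, call. = FALSE)
  hit <- which(history[[metric]] >= threshold)
  if (length(hit)) history$round[hit[1]] else NA_integer_
}
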