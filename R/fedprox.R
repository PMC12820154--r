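#' Local-training configuration (FedProx client)
#'
#' Optimiser and objective settings used by every client. Defaults follow
#' the study configuration: AdamW (lr 1e-4, weight decay 0.01),
#' cross-entropy loss, cosine-annealed learning rate, proximal coefficient
#' mu = 0.5. Setting `mu = 0` recovers the plain FedAvg local objective.
#'
#' @param mu proximal coefficient (>= 0).
#' @param local_epochs passes over the local shard per round.
#' @param batch_size minibatch size.
#' @param learning_rate AdamW step size.
#' @param weight_decay decoupled weight decay.
#' @param scheduler `"cosine"` (annealed over `local_epochs`) or `"none"`.
#' @param seed integer controlling shuffling and dropout.
#' @return an object of class `fedprox_config`.
#' @export
fedprox_config <- function(mu = 0.5, local_epochs = 1L, batch_size = 32L,
                           learning_rate = 1e-4, weight_decay = 0.01,
                           scheduler = c("cosine", "none"), seed = 0L) {
  scheduler <- match.arg(scheduler)
  if (mu < 0) stop("mu must be >= 0", call. = FALSE)
  structure(list(mu = mu, local_epochs = as.integer(local_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 scheduler = scheduler, seed = as.integer(seed)),
            class = "fedprox_config")
}

#' FedProx objective value
#'
#' `ce + (mu/2) * sum ||w - w_global||^2`, the l2 norm taken over the
#' concatenation of all exchanged trainable tensors. With `mu = 0` or
#' `w = w_global` this reduces to the plain cross-entropy term.
#'
#' @param ce scalar local loss (mean cross-entropy).
#' @param w named list of trainable tensors.
#' @param w_global same-keyed list of global tensors.
#' @param mu proximal coefficient.
#' @return scalar objective.
#' @export
fedprox_loss <- function(ce, w, w_global, mu) {
  check_same_keys(w, w_global, "trainable weights")
  dev <- sum(vapply(names(w), function(nm)
    sum((as.numeric(w[[nm]]) - as.numeric(w_global[[nm]]))^2), numeric(1)))
  ce + mu / 2 * dev
}

#' Gradient of the proximal penalty
#'
#' The proximal part of the FedProx objective has gradient
#' `mu * (w - w_global)` per tensor.
#'
#' @inheritParams fedprox_loss
#' @return named list of tensors matching `w`.
#' @export
prox_gradient <- function(w, w_global, mu) {
  check_same_keys(w, w_global, "trainable weights")
  stats::setNames(lapply(names(w), function(nm) mu * (w[[nm]] - w_global[[nm]])),
                  names(w))
}

#' Mean cross-entropy over a shard
#'
#' Local empirical risk: the mean per-sample cross-entropy of the model's
#' softmax outputs over a client shard.
#'
#' @param model a `vit_model`.
#' @param shard a `client_shard` (see [partition_noniid()]) or any list with
#'   `x` (list of images/patch matrices) and `y` (0/1 labels).
#' @return scalar mean loss.
#' @export
local_empirical_risk <- function(model, shard) {
  if (length(shard$y) == 0) stop("empty shard", call. = FALSE)
  total <- 0
  for (j in seq_along(shard$y)) {
    fwd <- vit_forward_one(model, shard$x[[j]])
    total <- total + ce_loss_grad(fwd$logits, shard$y[j])$loss
  }
  total / length(shard$y)
}

# --- AdamW with decoupled weight decay over a named tensor subset ---------

adamw_init <- function(tensors) {
  list(m = lapply(tensors, function(x) x * 0),
       v = lapply(tensors, function(x) x * 0),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                           weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

# Cosine-annealed learning rate; epoch in 0:(T_max-1), eta_min = 0.
cosine_lr <- function(lr0, epoch, T_max) {
  if (T_max <= 1) return(lr0)
  lr0 * 0.5 * (1 + cos(pi * epoch / (T_max - 1 + 1e-12)))
}

#' One client's local FedProx training pass
#'
#' Loads the broadcast global weights, runs `local_epochs` of minibatch
#' AdamW on the FedProx objective (cross-entropy plus the proximal pull
#' toward the received global weights, taken over the trainable set), and
#' returns the updated trainable weights with the local sample count.
#' Frozen tensors are untouched. Deterministic for a fixed `cfg$seed`.
#'
#' @param shard a `client_shard` with fields `client_id`, `x`, `y`.
#' @param model a `vit_model` whose trainable tensors define the exchanged
#'   set; its current trainable values are treated as the global weights.
#' @param cfg a [fedprox_config()].
#' @return an object of class `client_update`: list with `weights` (named
#'   tensor list), `n` (shard size), `client_id`, `loss_trace` (mean
#'   objective per epoch).
#' @export
local_train <- function(shard, model, cfg) {
  n <- length(shard$y)
  if (n == 0) {
    return(structure(list(weights = NULL, n = 0L,
                          client_id = shard$client_id, loss_trace = numeric(0),
                          skipped = TRUE), class = "client_update"))
  }
  tn <- names(model$params)[model$trainable[names(model$params)]]
  w_global <- model$params[tn]
  trace <- numeric(0)
  if (cfg$local_epochs > 0) {
    opt <- adamw_init(w_global)
    withr::with_seed(cfg$seed, {
      for (ep in seq_len(cfg$local_epochs)) {
        lr <- if (cfg$scheduler == "cosine")
          cosine_lr(cfg$learning_rate, ep - 1L, cfg$local_epochs)
        else cfg$learning_rate
        ord <- sample.int(n)
        ep_loss <- 0
        nb <- 0L
        for (start in seq(1L, n, by = cfg$batch_size)) {
          idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
          bg <- batch_loss_grads(model, shard$x[idx], shard$y[idx],
                                 train = TRUE)
          w <- model$params[tn]
          pg <- prox_gradient(w, w_global, cfg$mu)
          grads <- stats::setNames(lapply(tn, function(nm)
            bg$grads[[nm]] + pg[[nm]]), tn)
          if (!all(is.finite(bg$loss)) ||
              !all(vapply(grads, function(g) all(is.finite(g)), logical(1))))
            stop("divergence: non-finite loss/gradients in local training",
                 call. = FALSE)
          st <- adamw_step(w, grads, opt, lr, cfg$weight_decay)
          opt <- st$state
          model$params[tn] <- st$params
          ep_loss <- ep_loss + fedprox_loss(bg$loss, st$params, w_global, cfg$mu)
          nb <- nb + 1L
        }
        trace <- c(trace, ep_loss / nb)
      }
    })
  }
  structure(list(weights = model$params[tn], n = n,
                 client_id = shard$client_id, loss_trace = trace,
                 skipped = FALSE),
            class = "client_update")
}
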