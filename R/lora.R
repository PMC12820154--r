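#' LoRA adapter configuration
#'
#' Low-rank adaptation settings: a frozen base weight `W0` receives a
#' trainable update `ΔW = A B` with `A` d x r and `B` r x k, scaled by
#' `s = alpha/r` (default convention) or `s = alpha` (`alpha_literal`).
#' Defaults are rank 16, alpha 32, dropout 0.1, targets query and value —
#' giving 147,456 trainable parameters on the 12-block, 192-dim backbone.
#'
#' @param rank adapter rank r (>= 1, far below min(d, k)).
#' @param alpha scaling numerator.
#' @param dropout drop probability on the adapter input path, training only.
#' @param target_modules character subset of `c("query", "value")`.
#' @param scaling_convention `"alpha_over_r"` (s = alpha/r) or
#'   `"alpha_literal"` (s = alpha).
#' @param train_head logical; keep the classifier head trainable alongside
#'   the adapters. Off by default so the trainable set is exactly the
#'   adapter matrices.
#' @return an object of class `lora_config`.
#' @export
lora_config <- function(rank = 16L, alpha = 32, dropout = 0.1,
                        target_modules = c("query", "value"),
                        scaling_convention = c("alpha_over_r", "alpha_literal"),
                        train_head = FALSE) {
  scaling_convention <- match.arg(scaling_convention)
  if (rank < 1) stop("rank must be >= 1", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0,1)", call. = FALSE)
  bad <- setdiff(target_modules, c("query", "value"))
  if (length(bad))
    stop("unknown LoRA target module(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(rank = as.integer(rank), alpha = alpha, dropout = dropout,
                 target_modules = target_modules,
                 scaling_convention = scaling_convention,
                 train_head = isTRUE(train_head)),
            class = "lora_config")
}

lora_scale <- function(cfg) {
  if (cfg$scaling_convention == "alpha_over_r") cfg$alpha / cfg$rank
  else cfg$alpha
}

# Parameter names of the adapter pair for (block i, target tg).
adapter_pair_names <- function(i, tg) {
  paste0("block", i, ".attn.", tg, ".", c("A", "B"))
}

# All adapter tensor names for a model with LoRA attached.
adapter_names <- function(model) {
  stopifnot(!is.null(model$lora))
  unlist(lapply(seq_len(model$config$depth), function(i)
    unlist(lapply(model$lora$target_modules, adapter_pair_names, i = i))))
}

#' Inject LoRA adapters into the attention projections
#'
#' Freezes every base tensor and attaches one A/B pair per (block, target).
#' `A` is initialised Gaussian with sd `1/rank` and `B` to zero, so the
#' adapted model reproduces the base model's outputs exactly at injection
#' time. The query/value targets address the corresponding slices of the
#' fused QKV projection.
#'
#' @param model a `vit_model` without adapters.
#' @param cfg a [lora_config()].
#' @param seed seed for the A initialisation.
#' @return the adapted `vit_model`; only adapter tensors (plus the head if
#'   `cfg$train_head`) are trainable.
#' @export
inject_lora <- function(model, cfg, seed = 0L) {
  stopifnot(inherits(model, "vit_model"), inherits(cfg, "lora_config"))
  if (!is.null(model$lora))
    stop("model already carries LoRA adapters", call. = FALSE)
  d <- model$config$embed_dim
  k <- d  # query/value projections are d x d slices of the fused QKV weight
  model$trainable[] <- FALSE
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(model$config$depth)) {
      for (tg in cfg$target_modules) {
        nm <- adapter_pair_names(i, tg)
        model$params[[nm[1]]] <- matrix(stats::rnorm(d * cfg$rank,
                                                     sd = 1 / cfg$rank),
                                        d, cfg$rank)
        model$params[[nm[2]]] <- matrix(0, cfg$rank, k)
        model$trainable[nm] <- TRUE
      }
    }
  })
  if (cfg$train_head) model$trainable[c("head.W", "head.b")] <- TRUE
  model$lora <- cfg
  model
}

#' Adapted linear map
#'
#' Computes `x (W0 + s A B)` where `s` follows the configured scaling
#' convention; dropout (training mode only) applies to the adapter path
#' input, never to the frozen base path.
#'
#' @param x input vector (length d) or matrix (n x d).
#' @param W0 frozen base weight, d x k.
#' @param A,B adapter pair, d x r and r x k.
#' @param cfg a [lora_config()].
#' @param train logical; enables adapter dropout.
#' @return vector/matrix `x W0 + s drop(x) A B`.
#' @export
lora_forward <- function(x, W0, A, B, cfg, train = FALSE) {
  xm <- if (is.matrix(x)) x else matrix(x, 1L)
  if (ncol(xm) != nrow(W0) || nrow(A) != nrow(W0) || ncol(A) != nrow(B) ||
      ncol(B) != ncol(W0))
    stop("lora_forward: inconsistent shapes", call. = FALSE)
  base <- xm %*% W0
  xd <- xm
  if (train && cfg$dropout > 0) xd <- xm * dropout_mask(dim(xm), cfg$dropout)
  out <- base + lora_scale(cfg) * (xd %*% A %*% B)
  if (is.matrix(x)) out else as.numeric(out)
}

#' Closed-form trainable-parameter count of a LoRA configuration
#'
#' `depth * |targets| * (d*r + r*k)` with `k = d` for the attention
#' query/value slices; 147,456 for the rank-16 default on DeiT-tiny.
#'
#' @param vit a [vit_config()].
#' @param cfg a [lora_config()].
#' @return integer count (adapters only, excluding any trainable head).
#' @export
count_lora_parameters <- function(vit, cfg) {
  d <- vit$embed_dim; k <- d
  vit$depth * length(cfg$target_modules) * (d * cfg$rank + cfg$rank * k)
}

#' Extract / load the transmitted adapter state
#'
#' `extract_adapter_state` returns the named list of adapter tensors (plus
#' the head if it is configured trainable) — the exact weight set a client
#' transmits. `load_adapter_state` writes such a state back into a model.
#'
#' @param model an adapted `vit_model`.
#' @return named list of tensors.
#' @export
extract_adapter_state <- function(model) {
  if (is.null(model$lora)) stop("model has no adapters", call. = FALSE)
  nms <- adapter_names(model)
  if (model$lora$train_head) nms <- c(nms, "head.W", "head.b")
  model$params[nms]
}

#' @rdname extract_adapter_state
#' @param state a named tensor list from `extract_adapter_state`.
#' @export
load_adapter_state <- function(model, state) {
  if (is.null(model$lora)) stop("model has no adapters", call. = FALSE)
  expected <- adapter_names(model)
  if (model$lora$train_head) expected <- c(expected, "head.W", "head.b")
  check_same_keys(stats::setNames(vector("list", length(expected)), expected),
                  state, "adapter state")
  for (nm in names(state)) {
    if (!identical(dim(model$params[[nm]]), dim(state[[nm]])) &&
        length(model$params[[nm]]) != length(state[[nm]]))
      stop("adapter state shape mismatch for ", nm, call. = FALSE)
    model$params[[nm]] <- state[[nm]]
  }
  model
}

#' Fold adapters into the base weights
#'
#' Returns an adapter-free model whose fused QKV projection carries
#' `W0 + s A B` in the adapted slices. Forward outputs agree with the
#' adapted model (eval mode); merging a model without adapters is a no-op,
#' so the operation is idempotent.
#'
#' @param model a `vit_model`.
#' @return a plain `vit_model` with all tensors trainable.
#' @export
merge_adapters <- function(model) {
  if (is.null(model$lora)) return(model)
  cfg <- model$lora
  d <- model$config$embed_dim
  s <- lora_scale(cfg)
  slice <- list(query = 1:d, value = (2 * d + 1):(3 * d))
  for (i in seq_len(model$config$depth)) {
    wn <- paste0("block", i, ".attn.qkv.W")
    for (tg in cfg$target_modules) {
      nm <- adapter_pair_names(i, tg)
      model$params[[wn]][, slice[[tg]]] <-
        model$params[[wn]][, slice[[tg]]] +
        s * (model$params[[nm[1]]] %*% model$params[[nm[2]]])
      model$params[[nm[1]]] <- NULL
      model$params[[nm[2]]] <- NULL
    }
  }
  model$trainable <- stats::setNames(rep(TRUE, length(model$params)),
                                     names(model$params))
  model$lora <- NULL
  model
}
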