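#' Vision Transformer configuration
#'
#' Architecture hyperparameters for the DeiT-tiny family of classifiers.
#' The defaults describe DeiT-tiny adapted to a two-class head with a single
#' CLS token (no distillation token): 224x224x3 input, 16x16 patches
#' (196 patches), embedding dimension 192, 12 pre-norm encoder blocks with
#' 3 attention heads and a 4x MLP expansion.
#'
#' @param image_size input side length in pixels.
#' @param patch_size patch side length; must divide `image_size`.
#' @param in_channels input channels (radiographs are replicated to 3).
#' @param embed_dim token embedding dimension d; must be divisible by
#'   `num_heads`.
#' @param depth number of encoder blocks L.
#' @param num_heads attention heads per block.
#' @param mlp_ratio MLP hidden width as a multiple of `embed_dim`.
#' @param num_classes classifier outputs (2: normal vs pneumonia).
#' @param use_distillation_token logical; kept for completeness, the
#'   classifier used here has a single CLS token.
#' @return an object of class `vit_config`.
#' @export
vit_config <- function(image_size = 224L, patch_size = 16L, in_channels = 3L,
                       embed_dim = 192L, depth = 12L, num_heads = 3L,
                       mlp_ratio = 4L, num_classes = 2L,
                       use_distillation_token = FALSE) {
  if (image_size %% patch_size != 0)
    stop("image_size must be divisible by patch_size", call. = FALSE)
  if (embed_dim %% num_heads != 0)
    stop("embed_dim must be divisible by num_heads", call. = FALSE)
  if (isTRUE(use_distillation_token))
    stop("distillation token not supported: the parameter-audited ",
         "architecture has a single CLS token", call. = FALSE)
  cfg <- list(image_size = as.integer(image_size),
              patch_size = as.integer(patch_size),
              in_channels = as.integer(in_channels),
              embed_dim = as.integer(embed_dim),
              depth = as.integer(depth),
              num_heads = as.integer(num_heads),
              mlp_ratio = as.integer(mlp_ratio),
              num_classes = as.integer(num_classes),
              use_distillation_token = FALSE)
  cfg$num_patches <- (cfg$image_size %/% cfg$patch_size)^2
  cfg$patch_dim <- cfg$patch_size^2 * cfg$in_channels
  class(cfg) <- "vit_config"
  cfg
}

#' @export
print.vit_config <- function(x, ...) {
  cat(sprintf(
    "ViT config: %dx%d/%d, dim %d, depth %d, heads %d, %d classes (%d patches)\n",
    x$image_size, x$image_size, x$patch_size, x$embed_dim, x$depth,
    x$num_heads, x$num_classes, x$num_patches))
  invisible(x)
}

# Names of the parameter tensors of one encoder block.
block_param_names <- function(i) {
  paste0("block", i, ".",
         c("ln1.gamma", "ln1.beta", "attn.qkv.W", "attn.qkv.b",
           "attn.out.W", "attn.out.b", "ln2.gamma", "ln2.beta",
           "mlp.fc1.W", "mlp.fc1.b", "mlp.fc2.W", "mlp.fc2.b"))
}

#' Build a Vision Transformer classifier
#'
#' Creates the full weight set of the configured model. Projections are
#' initialised truncated-normal (sd 0.02), biases and the positional table's
#' companion biases zero, layer-norm scales one. All tensors start trainable.
#' Passing `checkpoint` loads previously saved weights instead (see
#' [save_checkpoint()]).
#'
#' @param config a [vit_config()].
#' @param seed integer seed making initialisation reproducible.
#' @param checkpoint optional path to a checkpoint written by
#'   [save_checkpoint()].
#' @return an object of class `vit_model`: a list with `config`, a named
#'   list `params` of weight tensors, a named logical `trainable` mask, and
#'   (after [inject_lora()]) LoRA bookkeeping.
#' @export
build_model <- function(config, seed = 0L, checkpoint = NULL) {
  stopifnot(inherits(config, "vit_config"))
  if (!is.null(checkpoint)) {
    model <- load_checkpoint(checkpoint)
    return(model)
  }
  d <- config$embed_dim; Np <- config$num_patches
  hid <- config$mlp_ratio * d
  withr::with_seed(as.integer(seed), {
    params <- list()
    params[["patch_proj.W"]] <- matrix(trunc_normal(config$patch_dim * d),
                                       config$patch_dim, d)
    params[["patch_proj.b"]] <- numeric(d)
    params[["cls_token"]] <- trunc_normal(d)
    params[["pos_embed"]] <- matrix(trunc_normal((Np + 1) * d), Np + 1, d)
    for (i in seq_len(config$depth)) {
      p <- paste0("block", i, ".")
      params[[paste0(p, "ln1.gamma")]] <- rep(1, d)
      params[[paste0(p, "ln1.beta")]] <- numeric(d)
      params[[paste0(p, "attn.qkv.W")]] <- matrix(trunc_normal(d * 3 * d), d, 3 * d)
      params[[paste0(p, "attn.qkv.b")]] <- numeric(3 * d)
      params[[paste0(p, "attn.out.W")]] <- matrix(trunc_normal(d * d), d, d)
      params[[paste0(p, "attn.out.b")]] <- numeric(d)
      params[[paste0(p, "ln2.gamma")]] <- rep(1, d)
      params[[paste0(p, "ln2.beta")]] <- numeric(d)
      params[[paste0(p, "mlp.fc1.W")]] <- matrix(trunc_normal(d * hid), d, hid)
      params[[paste0(p, "mlp.fc1.b")]] <- numeric(hid)
      params[[paste0(p, "mlp.fc2.W")]] <- matrix(trunc_normal(hid * d), hid, d)
      params[[paste0(p, "mlp.fc2.b")]] <- numeric(d)
    }
    params[["norm.gamma"]] <- rep(1, d)
    params[["norm.beta"]] <- numeric(d)
    params[["head.W"]] <- matrix(trunc_normal(d * config$num_classes),
                                 d, config$num_classes)
    params[["head.b"]] <- numeric(config$num_classes)
  })
  trainable <- stats::setNames(rep(TRUE, length(params)), names(params))
  structure(list(config = config, params = params, trainable = trainable,
                 lora = NULL),
            class = "vit_model")
}

#' @export
print.vit_model <- function(x, ...) {
  print(x$config)
  cat(sprintf("parameters: %s total, %s trainable%s\n",
              format(count_parameters(x), big.mark = ","),
              format(count_parameters(x, trainable_only = TRUE), big.mark = ","),
              if (is.null(x$lora)) "" else
                sprintf(" (LoRA r=%d on %s)", x$lora$rank,
                        paste(x$lora$target_modules, collapse = "/"))))
  invisible(x)
}

#' Flatten an image into patch vectors
#'
#' Splits an H x W x C array into non-overlapping `patch_size` patches in
#' row-major patch order; within a patch, pixels are flattened row-major and
#' channels vary slowest. Grayscale matrices are treated as single-channel.
#'
#' @param image numeric H x W x C array (or H x W matrix).
#' @param patch_size patch side length.
#' @return `num_patches` x `patch_size^2*C` matrix, one patch per row.
#' @export
patchify <- function(image, patch_size) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  H <- dim(image)[1]; W <- dim(image)[2]; C <- dim(image)[3]
  if (H %% patch_size != 0 || W %% patch_size != 0)
    stop("image dimensions not divisible by patch size", call. = FALSE)
  gh <- H %/% patch_size; gw <- W %/% patch_size
  out <- matrix(0, gh * gw, patch_size^2 * C)
  k <- 1L
  for (r in seq_len(gh)) {
    rows <- ((r - 1L) * patch_size + 1L):(r * patch_size)
    for (cix in seq_len(gw)) {
      cols <- ((cix - 1L) * patch_size + 1L):(cix * patch_size)
      block <- image[rows, cols, , drop = FALSE]
      # row-major by pixel within the patch, channel slowest
      v <- numeric(patch_size^2 * C)
      for (ch in seq_len(C)) {
        v[((ch - 1L) * patch_size^2 + 1L):(ch * patch_size^2)] <-
          as.numeric(t(block[, , ch]))
      }
      out[k, ] <- v
      k <- k + 1L
    }
  }
  out
}

#' Embed an image into the token sequence
#'
#' Computes the input token matrix: each flattened patch is linearly
#' projected, the CLS token is prepended, and the learned positional table
#' is added.
#'
#' @param image H x W x C array matching the model's configuration, or a
#'   pre-computed patch matrix from [patchify()].
#' @param model a [build_model()] result.
#' @return `(num_patches+1)` x `embed_dim` token matrix; row 1 is CLS.
#' @export
embed_patches <- function(image, model) {
  cfg <- model$config
  if (is.matrix(image) && ncol(image) == cfg$patch_dim &&
      nrow(image) == cfg$num_patches) {
    xp <- image
  } else {
    if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
    dm <- dim(image)
    if (dm[1] != cfg$image_size || dm[2] != cfg$image_size ||
        dm[3] != cfg$in_channels)
      stop(sprintf("image shape %s does not match config %dx%dx%d",
                   paste(dm, collapse = "x"), cfg$image_size, cfg$image_size,
                   cfg$in_channels), call. = FALSE)
    xp <- patchify(image, cfg$patch_size)
  }
  proj <- xp %*% model$params[["patch_proj.W"]]
  proj <- sweep(proj, 2L, model$params[["patch_proj.b"]], "+")
  z <- rbind(model$params[["cls_token"]], proj)
  z + model$params[["pos_embed"]]
}

# Layer norm over the feature axis of a token matrix; returns value + cache.
layer_norm <- function(x, gamma, beta, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat * 1, 2L, gamma, "*")
  y <- sweep(y, 2L, beta, "+")
  list(y = y, xhat = xhat, inv = inv)
}

layer_norm_backward <- function(dy, cache, gamma) {
  dxhat <- sweep(dy, 2L, gamma, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dx = dx,
       dgamma = colSums(dy * cache$xhat),
       dbeta = colSums(dy))
}

# Dropout mask helper (inverted dropout); p = drop probability.
dropout_mask <- function(dimv, p) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(prod(dimv), 1L, 1 - p) / (1 - p), dimv[1], dimv[2])
}

# One pre-norm encoder block. Returns output tokens plus, optionally, the
# cache needed for backprop and the head-averaged attention matrix.
encoder_block_forward <- function(tokens, model, i, train = FALSE,
                                  keep_cache = FALSE, keep_attention = FALSE) {
  p <- paste0("block", i, ".")
  prm <- model$params
  cfg <- model$config
  d <- cfg$embed_dim; H <- cfg$num_heads; dh <- d %/% H
  Tn <- nrow(tokens)

  ln1 <- layer_norm(tokens, prm[[paste0(p, "ln1.gamma")]],
                    prm[[paste0(p, "ln1.beta")]])
  h <- ln1$y
  qkv <- sweep(h %*% prm[[paste0(p, "attn.qkv.W")]], 2L,
               prm[[paste0(p, "attn.qkv.b")]], "+")
  Q <- qkv[, 1:d, drop = FALSE]
  K <- qkv[, (d + 1):(2 * d), drop = FALSE]
  V <- qkv[, (2 * d + 1):(3 * d), drop = FALSE]

  lora_cache <- NULL
  if (!is.null(model$lora)) {
    lc <- model$lora
    s <- lora_scale(lc)
    lora_cache <- list(s = s)
    for (tg in lc$target_modules) {
      an <- paste0(p, "attn.", tg, ".A"); bn <- paste0(p, "attn.", tg, ".B")
      if (is.null(prm[[an]])) next
      hd <- h
      msk <- NULL
      if (train && lc$dropout > 0) {
        msk <- dropout_mask(dim(h), lc$dropout)
        hd <- h * msk
      }
      xa <- hd %*% prm[[an]]
      upd <- s * (xa %*% prm[[bn]])
      if (tg == "query") Q <- Q + upd else V <- V + upd
      lora_cache[[tg]] <- list(hd = hd, xa = xa, mask = msk)
    }
  }

  O <- matrix(0, Tn, d)
  Ps <- vector("list", H)
  scale <- 1 / sqrt(dh)
  for (hh in seq_len(H)) {
    idx <- ((hh - 1L) * dh + 1L):(hh * dh)
    S <- (Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE])) * scale
    P <- softmax_rows(S)
    O[, idx] <- P %*% V[, idx, drop = FALSE]
    Ps[[hh]] <- P
  }
  attn_out <- sweep(O %*% prm[[paste0(p, "attn.out.W")]], 2L,
                    prm[[paste0(p, "attn.out.b")]], "+")
  x1 <- tokens + attn_out

  ln2 <- layer_norm(x1, prm[[paste0(p, "ln2.gamma")]],
                    prm[[paste0(p, "ln2.beta")]])
  h2 <- ln2$y
  U <- sweep(h2 %*% prm[[paste0(p, "mlp.fc1.W")]], 2L,
             prm[[paste0(p, "mlp.fc1.b")]], "+")
  G <- gelu(U)
  M <- sweep(G %*% prm[[paste0(p, "mlp.fc2.W")]], 2L,
             prm[[paste0(p, "mlp.fc2.b")]], "+")
  out <- x1 + M

  res <- list(out = out)
  if (keep_attention) res$attention <- Reduce(`+`, Ps) / H
  if (keep_cache) {
    res$cache <- list(tokens = tokens, ln1 = ln1, h = h, Q = Q, K = K, V = V,
                      Ps = Ps, O = O, x1 = x1, ln2 = ln2, h2 = h2, U = U,
                      G = G, lora = lora_cache)
  }
  res
}

#' Apply one transformer encoder block
#'
#' Pre-norm residual block: `x + MHSA(LN(x))` followed by `x + MLP(LN(x))`,
#' with multi-head scaled-dot-product attention and a GELU MLP. When the
#' model carries LoRA adapters, the query and value projections include the
#' low-rank update.
#'
#' @param tokens token matrix from [embed_patches()].
#' @param model the model holding the block's weights.
#' @param block_index block number in `1:depth`.
#' @param train logical; enables adapter-path dropout.
#' @return token matrix of identical shape.
#' @export
encoder_block <- function(tokens, model, block_index, train = FALSE) {
  encoder_block_forward(tokens, model, block_index, train = train)$out
}

# Full forward pass for one image (patch matrix or array); optionally keeps
# per-block caches for backprop and per-block attention for rollout.
vit_forward_one <- function(model, image, train = FALSE, keep_cache = FALSE,
                            keep_attention = FALSE) {
  cfg <- model$config
  z <- embed_patches(image, model)
  caches <- if (keep_cache) vector("list", cfg$depth) else NULL
  attns <- if (keep_attention) vector("list", cfg$depth) else NULL
  for (i in seq_len(cfg$depth)) {
    r <- encoder_block_forward(z, model, i, train = train,
                               keep_cache = keep_cache,
                               keep_attention = keep_attention)
    z <- r$out
    if (keep_cache) caches[[i]] <- r$cache
    if (keep_attention) attns[[i]] <- r$attention
  }
  lnf <- layer_norm(z, model$params[["norm.gamma"]], model$params[["norm.beta"]])
  cls <- lnf$y[1L, ]
  logits <- as.numeric(cls %*% model$params[["head.W"]]) +
    model$params[["head.b"]]
  list(logits = logits, z = z, lnf = lnf, caches = caches, attns = attns)
}

#' Class scores for a batch of images
#'
#' Runs the full model: patch embedding, `depth` encoder blocks, final
#' layer-norm, and the linear head applied to the CLS token only.
#'
#' @param images a list of H x W x C arrays (or pre-patchified matrices), a
#'   single array, or a 4-D array with the batch in the 4th dimension.
#' @param model a [build_model()] result.
#' @param train logical; enables adapter dropout (training mode).
#' @return batch x `num_classes` matrix of logits.
#' @export
forward_logits <- function(images, model, train = FALSE) {
  images <- as_image_list(images)
  out <- matrix(0, length(images), model$config$num_classes)
  for (b in seq_along(images)) {
    out[b, ] <- vit_forward_one(model, images[[b]], train = train)$logits
  }
  out
}

# Normalise the accepted batch shapes to a list of per-image arrays.
as_image_list <- function(images) {
  if (is.list(images)) return(images)
  if (is.array(images) && length(dim(images)) == 4L) {
    return(lapply(seq_len(dim(images)[4]), function(b) images[, , , b]))
  }
  list(images)
}

#' Softmax class probabilities
#'
#' @inheritParams forward_logits
#' @return batch x `num_classes` matrix of probabilities (rows sum to 1).
#' @export
predict_proba <- function(images, model) {
  softmax_rows(forward_logits(images, model))
}

#' Count model parameters
#'
#' Exact element count over all weight tensors, optionally restricted to
#' tensors flagged trainable. For the default two-class DeiT-tiny this is
#' 5,524,802 (base) and, after [inject_lora()] with rank 16 on query/value,
#' 5,672,258 total of which 147,456 are trainable.
#'
#' @param model a `vit_model`.
#' @param trainable_only count only trainable tensors.
#' @return integer-valued count.
#' @export
count_parameters <- function(model, trainable_only = FALSE) {
  keep <- if (trainable_only) names(model$params)[model$trainable[names(model$params)]]
          else names(model$params)
  sum(vapply(model$params[keep], length, integer(1)))
}
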