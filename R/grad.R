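# Reverse-mode gradients for the transformer, written directly against the
# forward caches in vit.R. Gradients are produced for every parameter tensor
# (the optimiser later selects the trainable subset); they are verified
# against central differences in the test suite.

# Backprop through one encoder block. dy is the gradient at the block output.
# Returns list(dx = grad wrt block input tokens, grads = named tensor grads).
encoder_block_backward <- function(model, i, cache, dy) {
  p <- paste0("block", i, ".")
  prm <- model$params
  cfg <- model$config
  d <- cfg$embed_dim; H <- cfg$num_heads; dh <- d %/% H
  g <- list()

  # ---- MLP branch: out = x1 + M, M = gelu(h2 W1 + b1) W2 + b2
  dM <- dy
  g[[paste0(p, "mlp.fc2.W")]] <- t(cache$G) %*% dM
  g[[paste0(p, "mlp.fc2.b")]] <- colSums(dM)
  dG <- dM %*% t(prm[[paste0(p, "mlp.fc2.W")]])
  dU <- dG * gelu_grad(cache$U)
  g[[paste0(p, "mlp.fc1.W")]] <- t(cache$h2) %*% dU
  g[[paste0(p, "mlp.fc1.b")]] <- colSums(dU)
  dh2 <- dU %*% t(prm[[paste0(p, "mlp.fc1.W")]])
  ln2b <- layer_norm_backward(dh2, cache$ln2, prm[[paste0(p, "ln2.gamma")]])
  g[[paste0(p, "ln2.gamma")]] <- ln2b$dgamma
  g[[paste0(p, "ln2.beta")]] <- ln2b$dbeta
  dx1 <- dy + ln2b$dx          # residual + normalised path

  # ---- attention branch: x1 = tokens + O Wout + bout
  dattn_out <- dx1
  g[[paste0(p, "attn.out.W")]] <- t(cache$O) %*% dattn_out
  g[[paste0(p, "attn.out.b")]] <- colSums(dattn_out)
  dO <- dattn_out %*% t(prm[[paste0(p, "attn.out.W")]])

  Tn <- nrow(dy)
  dQ <- matrix(0, Tn, d); dK <- matrix(0, Tn, d); dV <- matrix(0, Tn, d)
  scale <- 1 / sqrt(dh)
  for (hh in seq_len(H)) {
    idx <- ((hh - 1L) * dh + 1L):(hh * dh)
    P <- cache$Ps[[hh]]
    dOj <- dO[, idx, drop = FALSE]
    dP <- dOj %*% t(cache$V[, idx, drop = FALSE])
    dV[, idx] <- t(P) %*% dOj
    dS <- P * (dP - rowSums(dP * P))
    dQ[, idx] <- (dS %*% cache$K[, idx, drop = FALSE]) * scale
    dK[, idx] <- (t(dS) %*% cache$Q[, idx, drop = FALSE]) * scale
  }

  dh_total <- matrix(0, Tn, d)    # grad wrt LN1 output h
  # adapter paths feed Q/V directly and read h (after dropout)
  if (!is.null(cache$lora)) {
    lc <- model$lora
    s <- cache$lora$s
    for (tg in lc$target_modules) {
      cc <- cache$lora[[tg]]
      if (is.null(cc)) next
      an <- paste0(p, "attn.", tg, ".A"); bn <- paste0(p, "attn.", tg, ".B")
      dupd <- if (tg == "query") dQ else dV
      g[[bn]] <- s * (t(cc$xa) %*% dupd)
      dxa <- s * (dupd %*% t(prm[[bn]]))
      g[[an]] <- t(cc$hd) %*% dxa
      dhd <- dxa %*% t(prm[[an]])
      if (!is.null(cc$mask)) dhd <- dhd * cc$mask
      dh_total <- dh_total + dhd
    }
  }

  dqkv <- cbind(dQ, dK, dV)
  g[[paste0(p, "attn.qkv.W")]] <- t(cache$h) %*% dqkv
  g[[paste0(p, "attn.qkv.b")]] <- colSums(dqkv)
  dh_total <- dh_total + dqkv %*% t(prm[[paste0(p, "attn.qkv.W")]])

  ln1b <- layer_norm_backward(dh_total, cache$ln1, prm[[paste0(p, "ln1.gamma")]])
  g[[paste0(p, "ln1.gamma")]] <- ln1b$dgamma
  g[[paste0(p, "ln1.beta")]] <- ln1b$dbeta
  dx <- dx1 + ln1b$dx

  list(dx = dx, grads = g)
}

# Gradient of the scalar loss wrt every parameter for one sample, given the
# forward result of vit_forward_one(keep_cache = TRUE) and dlogits.
vit_backward_one <- function(model, image, fwd, dlogits) {
  cfg <- model$config
  g <- list()
  lnf_y <- fwd$lnf$y
  cls <- lnf_y[1L, ]
  g[["head.W"]] <- outer(cls, dlogits)
  g[["head.b"]] <- dlogits
  # only the CLS row of the final LN receives gradient
  dlnf <- matrix(0, nrow(lnf_y), cfg$embed_dim)
  dlnf[1L, ] <- as.numeric(model$params[["head.W"]] %*% dlogits)
  lnb <- layer_norm_backward(dlnf, fwd$lnf, model$params[["norm.gamma"]])
  g[["norm.gamma"]] <- lnb$dgamma
  g[["norm.beta"]] <- lnb$dbeta
  dz <- lnb$dx
  for (i in rev(seq_len(cfg$depth))) {
    bb <- encoder_block_backward(model, i, fwd$caches[[i]], dz)
    dz <- bb$dx
    g <- c(g, bb$grads)
  }
  # patch embedding: z0 = [cls; Xp E + b] + pos
  g[["pos_embed"]] <- dz
  g[["cls_token"]] <- dz[1L, ]
  dproj <- dz[-1L, , drop = FALSE]
  xp <- if (is.matrix(image) && ncol(image) == cfg$patch_dim &&
            nrow(image) == cfg$num_patches) image else
    patchify(if (is.matrix(image)) array(image, c(dim(image), 1L)) else image,
             cfg$patch_size)
  g[["patch_proj.W"]] <- t(xp) %*% dproj
  g[["patch_proj.b"]] <- colSums(dproj)
  g
}

# Softmax cross-entropy and its logit gradient for one sample.
# label is 0-based (0 = normal, 1 = pneumonia).
ce_loss_grad <- function(logits, label) {
  m <- max(logits)
  lse <- m + log(sum(exp(logits - m)))
  p <- exp(logits - lse)
  k <- label + 1L
  loss <- lse - logits[k]
  dlogits <- p
  dlogits[k] <- dlogits[k] - 1
  list(loss = loss, dlogits = dlogits)
}

# Mean loss and mean parameter gradients over a minibatch.
# images: list of patch matrices/arrays; labels: 0/1 vector.
batch_loss_grads <- function(model, images, labels, train = FALSE) {
  n <- length(images)
  total <- 0
  acc <- NULL
  for (b in seq_len(n)) {
    fwd <- vit_forward_one(model, images[[b]], train = train, keep_cache = TRUE)
    lg <- ce_loss_grad(fwd$logits, labels[b])
    total <- total + lg$loss
    g <- vit_backward_one(model, images[[b]], fwd, lg$dlogits)
    if (is.null(acc)) acc <- g else {
      for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
    }
  }
  list(loss = total / n, grads = lapply(acc, function(x) x / n))
}
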