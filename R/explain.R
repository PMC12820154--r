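#' Attention-rollout saliency heatmap
#'
#' For each encoder block the head-averaged attention matrix A is mixed
#' with the identity (0.5 A + 0.5 I, modelling the residual path) and
#' row-normalised; the mixed matrices are multiplied across blocks in
#' order. The CLS row of the product, restricted to the patch tokens, is
#' reshaped to the patch grid, bilinearly upsampled to image resolution and
#' min-max normalised.
#'
#' @param model a `vit_model`.
#' @param image model-ready image array or patch matrix.
#' @param head_agg `"mean"` (default) or `"max"` aggregation across heads.
#' @return object of class `heatmap`: list with `grid` (H x W matrix in
#'   \[0,1\]), `source = "rollout"`, `patch_grid` (the pre-upsampling
#'   patch-level map).
#' @export
attention_rollout <- function(model, image, head_agg = c("mean", "max")) {
  head_agg <- match.arg(head_agg)
  cfg <- model$config
  fwd <- vit_forward_one(model, image, keep_attention = (head_agg == "mean"),
                         keep_cache = (head_agg == "max"))
  Tn <- cfg$num_patches + 1L
  roll <- diag(Tn)
  for (i in seq_len(cfg$depth)) {
    A <- if (head_agg == "mean") fwd$attns[[i]]
    else Reduce(pmax, fwd$caches[[i]]$Ps)
    A <- 0.5 * A + 0.5 * diag(Tn)
    A <- A / rowSums(A)
    roll <- A %*% roll
  }
  cls_row <- roll[1L, -1L]
  g <- as.integer(sqrt(cfg$num_patches))
  patch_map <- matrix(cls_row, g, g, byrow = TRUE)  # row-major patch order
  grid <- bilinear_resize(patch_map, cfg$image_size, cfg$image_size)
  normalize_heatmap(grid, "rollout", patch_grid = patch_map)
}

normalize_heatmap <- function(grid, source, patch_grid = NULL) {
  rng <- range(grid)
  if (rng[2] > rng[1]) grid <- (grid - rng[1]) / (rng[2] - rng[1])
  else grid <- grid * 0
  structure(list(grid = grid, source = source, patch_grid = patch_grid),
            class = "heatmap")
}

#' @export
print.heatmap <- function(x, ...) {
  cat(sprintf("%s heatmap %dx%d (max at [%s])\n", x$source, nrow(x$grid),
              ncol(x$grid),
              paste(which(x$grid == max(x$grid), arr.ind = TRUE)[1, ],
                    collapse = ",")))
  invisible(x)
}

#' RISE randomised-mask saliency
#'
#' Randomised Input Sampling Explanation: `n_masks` coarse binary grids
#' (`cell_grid` x `cell_grid` cells kept with probability `keep_prob`) are
#' bilinearly upsampled with random sub-cell offsets into soft masks; the
#' model scores each masked image for the class predicted on the unmasked
#' image, and the saliency map is the score-weighted mean mask divided by
#' `keep_prob`. Deterministic per seed.
#'
#' @param model a `vit_model`.
#' @param image H x W x 3 model-ready array (pixel space; masks are applied
#'   multiplicatively per pixel).
#' @param n_masks number of random masks.
#' @param cell_grid coarse grid side length.
#' @param keep_prob probability a cell is kept.
#' @param seed integer seed.
#' @param scorer optional function(image_array) -> scalar score; defaults
#'   to the model's predicted-class softmax probability.
#' @return a `heatmap` with `source = "rise"`.
#' @export
rise_saliency <- function(model, image, n_masks = 200L, cell_grid = 7L,
                          keep_prob = 0.5, seed = 0L, scorer = NULL) {
  if (n_masks < 1) stop("n_masks must be >= 1", call. = FALSE)
  if (is.matrix(image)) {
    stop("rise_saliency needs the pixel-space image array, not a patch matrix",
         call. = FALSE)
  }
  H <- dim(image)[1]; W <- dim(image)[2]
  if (is.null(scorer)) {
    pred_class <- which.max(vit_forward_one(model, image)$logits)
    scorer <- function(img) {
      lg <- vit_forward_one(model, img)$logits
      softmax_rows(matrix(lg, 1))[1, pred_class]
    }
  }
  acc <- matrix(0, H, W)
  cov <- matrix(0, H, W)
  cell_h <- ceiling(H / cell_grid); cell_w <- ceiling(W / cell_grid)
  up_h <- (cell_grid + 1L) * cell_h; up_w <- (cell_grid + 1L) * cell_w
  withr::with_seed(as.integer(seed), {
    for (m in seq_len(n_masks)) {
      cells <- matrix(stats::rbinom((cell_grid + 1L)^2, 1L, keep_prob),
                      cell_grid + 1L, cell_grid + 1L)
      big <- bilinear_resize(cells, up_h, up_w)
      oy <- sample.int(cell_h, 1L); ox <- sample.int(cell_w, 1L)
      msk <- big[oy:(oy + H - 1L), ox:(ox + W - 1L)]
      masked <- image
      for (ch in seq_len(dim(image)[3])) masked[, , ch] <- image[, , ch] * msk
      sc <- scorer(masked)
      acc <- acc + sc * msk
      cov <- cov + msk
    }
  })
  # exact-coverage correction: normalise by realised per-pixel mask mass
  sal <- acc / pmax(cov, .Machine$double.eps)
  normalize_heatmap(sal, "rise")
}

#' Render a heatmap overlay
#'
#' Alpha-blends a colour-mapped heatmap over a grayscale image and
#' optionally writes a PNG.
#'
#' @param image H x W matrix in \[0,1\] (or H x W x 3 array).
#' @param heatmap a `heatmap` (grid must match the image size).
#' @param alpha blend weight of the colormap in \[0,1\].
#' @param file optional PNG output path.
#' @return H x W x 3 array of the rendered overlay (invisibly if written).
#' @export
overlay <- function(image, heatmap, alpha = 0.5, file = NULL) {
  grid <- if (inherits(heatmap, "heatmap")) heatmap$grid else heatmap
  if (length(dim(image)) == 2L) {
    img3 <- array(rep(image, 3L), c(dim(image), 3L))
  } else img3 <- image
  if (!all(dim(img3)[1:2] == dim(grid)))
    stop("heatmap and image sizes differ", call. = FALSE)
  ramp <- grDevices::colorRamp(c("navy", "cyan", "yellow", "red"))
  cols <- ramp(as.vector(grid)) / 255
  heat3 <- array(cols, c(dim(grid), 3L))
  out <- (1 - alpha) * img3 + alpha * heat3
  out <- pmin(pmax(out, 0), 1)
  if (!is.null(file)) {
    png::writePNG(out, file)
    return(invisible(out))
  }
  out
}
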