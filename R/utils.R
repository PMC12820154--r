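# Numerical helpers shared across modules.

#' Row-wise softmax
#'
#' Numerically stable softmax applied to each row of a matrix.
#'
#' @param x numeric matrix.
#' @return matrix of the same shape; each row sums to 1.
#' @keywords internal
softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# Exact (erf-based) GELU and its derivative.
gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

#' Bilinear resampling of a 2-D grid
#'
#' Resizes a matrix (image plane or heatmap) to a new height/width by
#' bilinear interpolation with half-pixel centre alignment, the convention
#' used both for image preprocessing and for upsampling patch-level saliency
#' grids to pixel resolution.
#'
#' @param m numeric matrix (rows = height).
#' @param out_h,out_w target dimensions.
#' @return `out_h` x `out_w` matrix.
#' @export
bilinear_resize <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  if (in_h == out_h && in_w == out_w) return(m)
  # half-pixel centres, clamped to the source extent
  ys <- (seq_len(out_h) - 0.5) * in_h / out_h - 0.5
  xs <- (seq_len(out_w) - 0.5) * in_w / out_w - 0.5
  ys <- pmin(pmax(ys, 0), in_h - 1)
  xs <- pmin(pmax(xs, 0), in_w - 1)
  y0 <- pmin(floor(ys), in_h - 1); y1 <- pmin(y0 + 1, in_h - 1)
  x0 <- pmin(floor(xs), in_w - 1); x1 <- pmin(x0 + 1, in_w - 1)
  wy <- ys - y0; wx <- xs - x0
  a <- m[y0 + 1, x0 + 1, drop = FALSE]; b <- m[y0 + 1, x1 + 1, drop = FALSE]
  c <- m[y1 + 1, x0 + 1, drop = FALSE]; d <- m[y1 + 1, x1 + 1, drop = FALSE]
  top <- a * (1 - rep(wx, each = out_h)) + b * rep(wx, each = out_h)
  bot <- c * (1 - rep(wx, each = out_h)) + d * rep(wx, each = out_h)
  top * (1 - wy) + bot * wy
}

# Truncated normal (resample outside +-2 sd), the DeiT-style projection init.
trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, sd = sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), sd = sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

# Flatten a named list of tensors into one numeric vector (fixed key order).
flatten_tensors <- function(tensors) {
  unlist(lapply(tensors, as.numeric), use.names = FALSE)
}

# Total element count of a named list of tensors.
tensor_elements <- function(tensors) {
  sum(vapply(tensors, length, integer(1)))
}

# Elementwise combination of two same-keyed tensor lists.
map_tensors <- function(f, a, b = NULL) {
  if (is.null(b)) return(lapply(a, f))
  stopifnot(identical(names(a), names(b)))
  out <- Map(f, a, b)
  out
}

check_same_keys <- function(a, b, what = "weight sets") {
  if (!setequal(names(a), names(b))) {
    stop(sprintf("incompatible %s: keys differ (%s vs %s)", what,
                 paste(utils::head(setdiff(names(a), names(b)), 3), collapse = ","),
                 paste(utils::head(setdiff(names(b), names(a)), 3), collapse = ",")),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Round half up to `digits` decimals (matches reported-percentage formatting).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  trunc(x * p + 0.5 * sign(x)) / p
}
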