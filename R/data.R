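#' Synthetic chest-radiograph generator configuration
#'
#' Parameters of the two-class grayscale generator used for desk-scale
#' simulation in place of real radiographs. Images show a dark thorax with
#' two bright elliptical lung fields; the pneumonia class adds
#' `effect_size`-scaled Gaussian opacity blobs inside the lung fields.
#'
#' @param n_images number of images.
#' @param prevalence fraction of pneumonia labels, in (0, 1); the draw is
#'   stratified so exactly `round(n * prevalence)` images are positive.
#' @param image_size side length in pixels.
#' @param effect_size opacity amplitude separating the classes (image
#'   intensity units; images live in \[0, 1\]).
#' @param client_shift max absolute per-client intensity offset applied by
#'   [make_federated_synthetic()].
#' @param noise_sd Gaussian pixel-noise standard deviation.
#' @param seed integer seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_images = 100L, prevalence = 0.5,
                             image_size = 64L, effect_size = 0.3,
                             client_shift = 0.05, noise_sd = 0.05,
                             seed = 0L) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be in (0, 1)", call. = FALSE)
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  structure(list(n_images = as.integer(n_images), prevalence = prevalence,
                 image_size = as.integer(image_size),
                 effect_size = effect_size, client_shift = client_shift,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Binary mask of the two elliptical lung fields for a given image size.
lung_field_mask <- function(size) {
  xs <- matrix(rep(seq_len(size), each = size), size, size)  # column index
  ys <- matrix(rep(seq_len(size), times = size), size, size) # row index
  ell <- function(cx, cy, ax, ay)
    ((xs - cx) / ax)^2 + ((ys - cy) / ay)^2 <= 1
  ell(0.32 * size, 0.55 * size, 0.16 * size, 0.28 * size) |
    ell(0.68 * size, 0.55 * size, 0.16 * size, 0.28 * size)
}

#' Generate a synthetic chest-radiograph set
#'
#' Deterministic per seed. Background intensity 0.1, lung fields +0.45;
#' pneumonia images receive 2–4 Gaussian opacity blobs (amplitude
#' `effect_size`, sd 6% of the image side) centred inside the lung fields;
#' i.i.d. Gaussian pixel noise everywhere; intensities clipped to \[0, 1\].
#' Labels are stratified: exactly `round(n * prevalence)` positives,
#' shuffled.
#'
#' @param cfg a [synthetic_config()].
#' @return object of class `labeled_image_set`: list with `images` (list of
#'   H x W matrices in \[0,1\]), `labels` (0/1 integer vector), `split`
#'   (`"synthetic"`), and attribute `lung_mask` (logical matrix, the
#'   ground-truth region where class evidence is planted).
#' @export
generate_synthetic_cxr <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  size <- cfg$image_size
  mask <- lung_field_mask(size)
  in_idx <- which(mask, arr.ind = TRUE)
  n_pos <- round(cfg$n_images * cfg$prevalence)
  base <- matrix(0.1, size, size)
  base[mask] <- base[mask] + 0.45
  withr::with_seed(cfg$seed, {
    labels <- sample(c(rep(1L, n_pos), rep(0L, cfg$n_images - n_pos)))
    images <- vector("list", cfg$n_images)
    for (i in seq_len(cfg$n_images)) {
      img <- base
      if (labels[i] == 1L && cfg$effect_size > 0) {
        nb <- sample(2:4, 1L)
        ctr <- in_idx[sample.int(nrow(in_idx), nb), , drop = FALSE]
        for (b in seq_len(nb)) {
          cy <- ctr[b, 1]; cx <- ctr[b, 2]
          sd_px <- 0.06 * size
          gy <- exp(-((seq_len(size) - cy)^2) / (2 * sd_px^2))
          gx <- exp(-((seq_len(size) - cx)^2) / (2 * sd_px^2))
          img <- img + cfg$effect_size * outer(gy, gx) * mask
        }
      }
      img <- img + matrix(stats::rnorm(size^2, sd = cfg$noise_sd), size, size)
      images[[i]] <- pmin(pmax(img, 0), 1)
    }
  })
  structure(list(images = images, labels = labels, split = "synthetic"),
            class = "labeled_image_set", lung_mask = mask)
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat(sprintf("labeled image set '%s': %d images (%d positive)\n",
              x$split, length(x$labels), sum(x$labels == 1L)))
  invisible(x)
}

#' Read an image-folder dataset
#'
#' Expects the split/class directory layout
#' (`root/{train,val,test}/{NORMAL,PNEUMONIA}/img.png`). Class directories
#' named (case-insensitively) "normal" map to label 0 and "pneumonia" to 1;
#' otherwise the lexicographically first class is 0. PNG and TIFF files are
#' read; items are ordered lexicographically for reproducibility.
#'
#' @param root dataset root directory.
#' @param splits split subdirectories to read.
#' @return named list of `labeled_image_set`s, one per split.
#' @export
load_image_folder <- function(root, splits = c("train", "val", "test")) {
  if (!dir.exists(root)) stop("dataset root not found: ", root, call. = FALSE)
  out <- list()
  for (sp in splits) {
    spdir <- file.path(root, sp)
    if (!dir.exists(spdir))
      stop("missing split directory: ", spdir, call. = FALSE)
    classes <- sort(list.dirs(spdir, recursive = FALSE, full.names = FALSE))
    if (length(classes) == 0)
      stop("no class directories under ", spdir, call. = FALSE)
    lab_of <- function(cl) {
      cl_low <- tolower(cl)
      if (cl_low == "normal") 0L
      else if (cl_low == "pneumonia") 1L
      else match(cl, classes) - 1L
    }
    images <- list(); labels <- integer(0)
    for (cl in classes) {
      files <- sort(list.files(file.path(spdir, cl),
                               pattern = "\\.(png|tif|tiff)$",
                               ignore.case = TRUE, full.names = TRUE))
      if (length(files) == 0)
        warning("empty class folder: ", file.path(spdir, cl), call. = FALSE)
      for (f in files) {
        img <- tryCatch(read_gray_image(f),
                        error = function(e) stop("unreadable image ", f, ": ",
                                                 conditionMessage(e),
                                                 call. = FALSE))
        images[[length(images) + 1L]] <- img
        labels <- c(labels, lab_of(cl))
      }
    }
    out[[sp]] <- structure(list(images = images, labels = labels, split = sp),
                           class = "labeled_image_set")
  }
  out
}

# Read a PNG/TIFF file as a grayscale [0,1] matrix (mean over colour planes).
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF input")
    tiff::readTIFF(path)
  } else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3]),
                                               drop = FALSE], c(1, 2), mean)
  img
}

#' Export a labelled set to the image-folder layout
#'
#' Writes PNG files under `root/split/{NORMAL,PNEUMONIA}/`.
#'
#' @param set a `labeled_image_set`.
#' @param root output directory.
#' @return invisibly, the vector of written file paths.
#' @export
export_image_folder <- function(set, root) {
  cls <- c("NORMAL", "PNEUMONIA")
  paths <- character(length(set$labels))
  for (cl in cls) dir.create(file.path(root, set$split, cl),
                             recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(set$labels)) {
    p <- file.path(root, set$split, cls[set$labels[i] + 1L],
                   sprintf("img%05d.png", i))
    png::writePNG(set$images[[i]], p)
    paths[i] <- p
  }
  invisible(paths)
}

# ImageNet channel statistics used by pretrained DeiT preprocessing.
IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_SD <- c(0.229, 0.224, 0.225)

#' Preprocess an image for the transformer
#'
#' Resizes to `size`, replicates grayscale across three channels, and
#' standardises each channel with the ImageNet mean/sd
#' (0.485/0.456/0.406, 0.229/0.224/0.225). In training mode, augmentation
#' (rotation up to +-10 degrees, horizontal flip p=0.5, brightness/contrast
#' jitter +-0.1) is applied before standardisation; evaluation mode is
#' deterministic.
#'
#' @param image H x W matrix in \[0,1\] (or H x W x 3 array).
#' @param size target side length.
#' @param train logical; apply augmentation.
#' @return `size` x `size` x 3 standardised array.
#' @export
preprocess <- function(image, size = 224L, train = FALSE) {
  if (length(dim(image)) == 3L) image <- apply(image, c(1, 2), mean)
  if (train) image <- augment_image(image)
  image <- bilinear_resize(image, size, size)
  out <- array(0, c(size, size, 3L))
  for (ch in 1:3) out[, , ch] <- (image - IMAGENET_MEAN[ch]) / IMAGENET_SD[ch]
  out
}

# Random rotation (+-10 deg, bilinear, edge-clamped), hflip, jitter.
augment_image <- function(image, max_deg = 10, flip_p = 0.5, jitter = 0.1) {
  th <- stats::runif(1, -max_deg, max_deg) * pi / 180
  H <- nrow(image); W <- ncol(image)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(rep(seq_len(H), times = W), H, W)
  xx <- matrix(rep(seq_len(W), each = H), H, W)
  sy <- cy + (yy - cy) * cos(th) - (xx - cx) * sin(th)
  sx <- cx + (yy - cy) * sin(th) + (xx - cx) * cos(th)
  sy <- pmin(pmax(sy, 1), H); sx <- pmin(pmax(sx, 1), W)
  y0 <- floor(sy); x0 <- floor(sx)
  y1 <- pmin(y0 + 1, H); x1 <- pmin(x0 + 1, W)
  wy <- sy - y0; wx <- sx - x0
  at <- function(r, c) image[cbind(as.vector(r), as.vector(c))]
  v <- (1 - wy) * ((1 - wx) * at(y0, x0) + wx * at(y0, x1)) +
    wy * ((1 - wx) * at(y1, x0) + wx * at(y1, x1))
  img <- matrix(v, H, W)
  if (stats::runif(1) < flip_p) img <- img[, rev(seq_len(W))]
  img <- img * (1 + stats::runif(1, -jitter, jitter)) +
    stats::runif(1, -jitter, jitter)
  pmin(pmax(img, 0), 1)
}

#' Re-pool and re-split train/validation
#'
#' Pools the original train and validation sets (the test set is left
#' untouched), then draws `round(val_fraction * |pool|)` items into the new
#' validation set by stratified seeded sampling; the remainder becomes the
#' new training set. Applied to the published 5,216/16/624 split with the
#' default 15% this reconstructs the 4,447/785/624 working split.
#'
#' @param train,val,test `labeled_image_set`s (disjoint).
#' @param val_fraction fraction of the pool for validation, in (0, 1).
#' @param seed integer seed.
#' @return named list `train`, `val`, `test` of `labeled_image_set`s.
#' @export
redistribute_splits <- function(train, val, test, val_fraction = 0.15,
                                seed = 0L) {
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be in (0, 1)", call. = FALSE)
  pool_x <- c(train$images, val$images)
  pool_y <- c(train$labels, val$labels)
  n_pool <- length(pool_y)
  n_val <- round(val_fraction * n_pool)
  val_idx <- integer(0)
  if (n_val > 0) {
    withr::with_seed(as.integer(seed), {
      # stratified: per-class allocation proportional to class frequency
      for (cl in sort(unique(pool_y))) {
        cls_idx <- which(pool_y == cl)
        k <- round(n_val * length(cls_idx) / n_pool)
        val_idx <- c(val_idx, sample(cls_idx, min(k, length(cls_idx))))
      }
      # rounding can leave a small deficit/excess; fix it up
      while (length(val_idx) < n_val)
        val_idx <- c(val_idx, sample(setdiff(seq_len(n_pool), val_idx), 1L))
      if (length(val_idx) > n_val) val_idx <- val_idx[seq_len(n_val)]
    })
  }
  tr_idx <- setdiff(seq_len(n_pool), val_idx)
  mk <- function(idx, tag) structure(
    list(images = pool_x[idx], labels = pool_y[idx], split = tag),
    class = "labeled_image_set")
  list(train = mk(tr_idx, "train"), val = mk(val_idx, "val"), test = test)
}

#' Dirichlet label-skew partition into client shards
#'
#' For each class, per-client proportions are drawn from
#' `Dirichlet(beta * 1_K)` and the class's items are allocated accordingly
#' (seeded, disjoint, exhaustive). Small `beta` concentrates each class on
#' few clients (strong non-IID label skew); large `beta` approaches the
#' uniform IID split. Resamples (bounded retries) until every shard is
#' non-empty.
#'
#' @param set a `labeled_image_set` (training data).
#' @param n_clients K.
#' @param beta Dirichlet concentration (> 0); default 0.5.
#' @param seed integer seed.
#' @param max_retries resampling attempts before giving up.
#' @return list of `client_shard`s: each a list with `client_id`, `x`
#'   (images), `y` (labels), `n`.
#' @export
partition_noniid <- function(set, n_clients = 10L, beta = 0.5, seed = 0L,
                             max_retries = 100L) {
  n <- length(set$labels)
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  if (n_clients < 1 || n_clients > n)
    stop("n_clients must be in 1..n_items", call. = FALSE)
  classes <- sort(unique(set$labels))
  assign_once <- function() {
    cl_of <- vector("list", n_clients)
    for (cl in classes) {
      idx <- sample(which(set$labels == cl))
      # Dirichlet(beta 1_K) via normalised gammas
      p <- stats::rgamma(n_clients, shape = beta)
      if (sum(p) == 0) p <- rep(1, n_clients)
      p <- p / sum(p)
      cuts <- round(cumsum(p) * length(idx))
      starts <- c(0L, cuts[-n_clients])
      for (k in seq_len(n_clients)) {
        if (cuts[k] > starts[k])
          cl_of[[k]] <- c(cl_of[[k]], idx[(starts[k] + 1L):cuts[k]])
      }
    }
    cl_of
  }
  withr::with_seed(as.integer(seed), {
    for (attempt in seq_len(max_retries)) {
      cl_of <- assign_once()
      if (all(vapply(cl_of, length, integer(1)) > 0)) break
      cl_of <- NULL
    }
  })
  if (is.null(cl_of))
    stop("could not produce non-empty shards in ", max_retries, " attempts",
         call. = FALSE)
  lapply(seq_len(n_clients), function(k) {
    idx <- sort(cl_of[[k]])
    structure(list(client_id = k, x = set$images[idx], y = set$labels[idx],
                   n = length(idx)),
              class = "client_shard")
  })
}

#' Write a partition manifest
#'
#' CSV with one row per item: `item`, `label`, `client_id`.
#'
#' @param shards list of `client_shard`s.
#' @param path output CSV path.
#' @return invisibly, the manifest data.frame.
#' @export
write_partition_manifest <- function(shards, path) {
  df <- do.call(rbind, lapply(shards, function(s)
    data.frame(item = if (!is.null(names(s$x))) names(s$x)
               else sprintf("client%d_item%04d", s$client_id, seq_along(s$y)),
               label = s$y, client_id = s$client_id)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Build a ready-to-train federated synthetic benchmark
#'
#' Generates a synthetic radiograph set, Dirichlet-partitions the training
#' portion across clients, applies a per-client intensity shift (feature
#' skew drawn uniformly from +-`client_shift`), and preprocesses everything
#' to model-ready standardised patch matrices.
#'
#' @param cfg a [synthetic_config()] (n_images covers train+test).
#' @param n_clients K.
#' @param beta Dirichlet concentration.
#' @param test_fraction held-out fraction.
#' @param vit a [vit_config()] describing the consuming model (image size
#'   and patch size drive preprocessing).
#' @return list with `shards` (client shards of patch matrices), `test`
#'   (list `x`, `y`), `raw` (the generated `labeled_image_set`).
#' @export
make_federated_synthetic <- function(cfg, n_clients = 10L, beta = 0.5,
                                     test_fraction = 0.25,
                                     vit = vit_config(image_size = 64L,
                                                      embed_dim = 48L,
                                                      depth = 4L)) {
  set <- generate_synthetic_cxr(cfg)
  n <- length(set$labels)
  n_test <- round(test_fraction * n)
  withr::with_seed(cfg$seed + 1L, test_idx <- sample.int(n, n_test))
  tr_idx <- setdiff(seq_len(n), test_idx)
  train <- structure(list(images = set$images[tr_idx],
                          labels = set$labels[tr_idx], split = "train"),
                     class = "labeled_image_set")
  shards <- partition_noniid(train, n_clients, beta, seed = cfg$seed + 2L)
  prep <- function(img) patchify(preprocess(img, size = vit$image_size),
                                 vit$patch_size)
  withr::with_seed(cfg$seed + 3L, {
    shifts <- stats::runif(n_clients, -cfg$client_shift, cfg$client_shift)
  })
  for (k in seq_len(n_clients)) {
    shards[[k]]$x <- lapply(shards[[k]]$x, function(im)
      prep(pmin(pmax(im + shifts[k], 0), 1)))
  }
  test <- list(x = lapply(set$images[test_idx], prep),
               y = set$labels[test_idx])
  list(shards = shards, test = test, raw = set)
}

#' Inter-client heterogeneity score
#'
#' Embeds all client feature vectors into 2-D, computes per-client
#' centroids, and returns the mean pairwise Euclidean distance between
#' centroids — larger values indicate stronger non-IID heterogeneity.
#' The default embedding is the first two principal components
#' (deterministic); `"identity"` uses the first two feature columns
#' unchanged, making the centroid arithmetic exactly testable.
#'
#' @param client_features list (one entry per client) of numeric matrices,
#'   rows = per-item feature vectors.
#' @param embedding `"pca"` or `"identity"`.
#' @return scalar mean pairwise centroid distance.
#' @export
heterogeneity_score <- function(client_features, embedding = c("pca", "identity")) {
  embedding <- match.arg(embedding)
  if (length(client_features) < 2)
    stop("need at least two clients", call. = FALSE)
  if (any(vapply(client_features, nrow, integer(1)) < 1))
    stop("every client needs at least one feature vector", call. = FALSE)
  all_f <- do.call(rbind, client_features)
  emb <- if (embedding == "identity") {
    if (ncol(all_f) < 2) cbind(all_f, 0) else all_f[, 1:2, drop = FALSE]
  } else {
    pc <- stats::prcomp(all_f, center = TRUE, scale. = FALSE, rank. = 2)
    e <- pc$x
    if (ncol(e) < 2) e <- cbind(e, 0)
    e
  }
  sizes <- vapply(client_features, nrow, integer(1))
  grp <- rep(seq_along(client_features), sizes)
  cents <- t(vapply(seq_along(client_features), function(k)
    colMeans(emb[grp == k, , drop = FALSE]), numeric(2)))
  mean(stats::dist(cents))
}
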