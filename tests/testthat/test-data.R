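test_that("the synthetic generator stratifies labels and is seed-deterministic", {
  cfg <- synthetic_config(n_images = 100L, prevalence = 0.5, seed = 51L)
  set <- generate_synthetic_cxr(cfg)
  expect_identical(sum(set$labels == 1L), 50L)
  expect_identical(length(set$images), 100L)
  expect_true(all(sapply(set$images, function(im) all(im >= 0 & im <= 1))))
  set2 <- generate_synthetic_cxr(cfg)
  expect_equal(set2$images, set$images, tolerance = 0)
  expect_identical(set2$labels, set$labels)
  # uneven prevalence rounds to the nearest count
  set3 <- generate_synthetic_cxr(synthetic_config(n_images = 101L,
                                                  prevalence = 0.3, seed = 1L))
  expect_identical(sum(set3$labels == 1L), 30L)
})

test_that("zero effect size removes the class signal", {
  cfg <- synthetic_config(n_images = 500L, prevalence = 0.5, effect_size = 0,
                          seed = 52L)
  set <- generate_synthetic_cxr(cfg)
  means <- sapply(set$images, mean)
  pred <- as.integer(means > stats::median(means))
  expect_lt(abs(mean(pred == set$labels) - 0.5), 0.1)
})

test_that("a strong opacity effect separates classes via in-lung intensity", {
  cfg <- synthetic_config(n_images = 300L, prevalence = 0.5,
                          effect_size = 0.3, noise_sd = 0.05, seed = 53L)
  set <- generate_synthetic_cxr(cfg)
  mask <- attr(set, "lung_mask")
  score <- sapply(set$images, function(im) mean(im[mask]))
  expect_gt(roc_auc(score, set$labels), 0.95)
})

test_that("class separability is non-decreasing in effect size", {
  aucs <- sapply(c(0, 0.1, 0.3), function(es) {
    set <- generate_synthetic_cxr(synthetic_config(
      n_images = 200L, effect_size = es, noise_sd = 0.05, seed = 54L))
    mask <- attr(set, "lung_mask")
    roc_auc(sapply(set$images, function(im) mean(im[mask])), set$labels)
  })
  expect_true(all(diff(aucs) >= -0.02))
  expect_gt(aucs[3], aucs[1])
})

test_that("Dirichlet partitions are disjoint, exhaustive and skew-sensitive", {
  cfg <- synthetic_config(n_images = 120L, seed = 55L)
  set <- generate_synthetic_cxr(cfg)
  for (seed in 1:10) {
    shards <- partition_noniid(set, n_clients = 6L, beta = 0.5, seed = seed)
    sizes <- sapply(shards, function(s) s$n)
    expect_true(all(sizes > 0))
    expect_identical(sum(sizes), 120L)
  }
  # near-infinite concentration approaches the global class fractions
  sh_iid <- partition_noniid(set, n_clients = 4L, beta = 1e6, seed = 56L)
  for (s in sh_iid)
    expect_lt(abs(mean(s$y) - mean(set$labels)), 0.05)
  # mean pairwise total-variation distance is larger under strong skew
  tv_of <- function(beta, seed) {
    sh <- partition_noniid(set, n_clients = 4L, beta = beta, seed = seed)
    fr <- sapply(sh, function(s) mean(s$y))
    mean(abs(outer(fr, fr, "-")))  # binary labels: TV = |p_i - p_j|
  }
  reps <- 20L
  tv_low <- sapply(seq_len(reps), function(i) tv_of(0.1, 100 + i))
  tv_high <- sapply(seq_len(reps), function(i) tv_of(10, 100 + i))
  expect_gt(mean(tv_low), mean(tv_high))
  expect_error(partition_noniid(set, n_clients = 1000L), "1..n_items")
})

test_that("re-splitting pools train and validation and conserves every item", {
  dummy_set <- function(n, tag, label = 0L) structure(
    list(images = as.list(seq_len(n)), labels = rep(label, n), split = tag),
    class = "labeled_image_set")
  # the published counts: 5,216 train + 16 val pool to 5,232; 15% -> 785
  tr <- dummy_set(5216L, "train"); vl <- dummy_set(16L, "val")
  te <- dummy_set(624L, "test")
  out <- redistribute_splits(tr, vl, te, val_fraction = 0.15, seed = 1L)
  expect_identical(length(out$train$labels), 4447L)
  expect_identical(length(out$val$labels), 785L)
  expect_identical(length(out$test$labels), 624L)
  # conservation on random sizes, with stratification intact
  withr::with_seed(57L, {
    for (i in 1:5) {
      n1 <- sample(50:150, 1); n2 <- sample(5:30, 1)
      tr2 <- dummy_set(n1, "train", 0L); vl2 <- dummy_set(n2, "val", 1L)
      out2 <- redistribute_splits(tr2, vl2, dummy_set(10L, "test"),
                                  val_fraction = 0.2, seed = i)
      expect_identical(length(out2$train$labels) + length(out2$val$labels),
                       as.integer(n1 + n2))
      expect_setequal(c(out2$train$images, out2$val$images),
                      c(tr2$images, vl2$images))
    }
  })
  # a fraction that rounds to zero sends the whole pool to training
  out3 <- redistribute_splits(dummy_set(100L, "train"), dummy_set(0L, "val"),
                              dummy_set(5L, "test"), val_fraction = 0.004,
                              seed = 1L)
  expect_identical(length(out3$val$labels), 0L)
  expect_identical(length(out3$train$labels), 100L)
  expect_error(redistribute_splits(tr, vl, te, val_fraction = 1.2), "val_fraction")
})

test_that("preprocessing standardises with the ImageNet statistics", {
  img <- matrix(0.485, 20, 20)
  out <- preprocess(img, size = 32L)
  expect_identical(dim(out), c(32L, 32L, 3L))
  expect_equal(max(abs(out[, , 1])), 0, tolerance = 1e-12)
  expect_equal(out[1, 1, 2], (0.485 - 0.456) / 0.224, tolerance = 1e-12)
  # eval-mode preprocessing is deterministic
  img2 <- matrix(runif(900), 30, 30)
  expect_identical(preprocess(img2, 24L), preprocess(img2, 24L))
  # any input size maps to the requested output size
  expect_identical(dim(preprocess(matrix(0.5, 7, 13), 16L)), c(16L, 16L, 3L))
})

test_that("image folders round-trip through export and load", {
  root <- withr::local_tempdir()
  set <- generate_synthetic_cxr(synthetic_config(n_images = 5L,
                                                 prevalence = 0.4,
                                                 image_size = 16L, seed = 58L))
  set$split <- "train"
  export_image_folder(set, root)
  # load_image_folder requires every requested split
  expect_error(load_image_folder(root, splits = c("train", "test")),
               "missing split")
  loaded <- load_image_folder(root, splits = "train")$train
  expect_identical(length(loaded$labels), 5L)
  expect_identical(sum(loaded$labels == 1L), 2L)
  # PNG quantisation keeps pixels within half a grey level
  ord_orig <- order(set$labels)
  ord_load <- order(loaded$labels)
  expect_lt(max(abs(loaded$images[[ord_load[1]]] -
                      set$images[[ord_orig[1]]])), 1 / 255)
  expect_error(load_image_folder(file.path(root, "nope")), "root")
  # empty class directory warns but does not fail
  dir.create(file.path(root, "train", "EMPTYCLASS"))
  expect_warning(load_image_folder(root, splits = "train"), "empty class")
})

test_that("partition manifests record item, label and client", {
  set <- generate_synthetic_cxr(synthetic_config(n_images = 30L, seed = 59L))
  shards <- partition_noniid(set, n_clients = 3L, beta = 0.5, seed = 1L)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_partition_manifest(shards, path)
  back <- utils::read.csv(path)
  expect_identical(nrow(back), 30L)
  expect_identical(sort(unique(back$client_id)), 1:3)
  expect_identical(sum(back$label), sum(set$labels))
})

test_that("heterogeneity scoring reduces to centroid geometry", {
  f1 <- matrix(c(0, 0, 0, 0), 2, 2, byrow = TRUE)
  f2 <- matrix(c(2, 0, 2, 0), 2, 2, byrow = TRUE)
  # identical feature sets collapse to a zero score
  expect_lt(heterogeneity_score(list(f1, f1), embedding = "identity"), 1e-12)
  # two clients with centroids 2 apart score exactly 2 under identity
  expect_equal(heterogeneity_score(list(f1, f2), embedding = "identity"), 2,
               tolerance = 1e-12)
  expect_error(heterogeneity_score(list(f1)), "two clients")
  # label-skewed partitions score higher than IID ones on class-informative
  # features (in-lung mean intensity + overall mean)
  set <- generate_synthetic_cxr(synthetic_config(n_images = 200L,
                                                 effect_size = 0.3,
                                                 seed = 60L))
  mask <- attr(set, "lung_mask")
  feats_of <- function(shards) lapply(shards, function(s)
    t(sapply(s$x, function(im) c(mean(im[mask]), mean(im)))))
  sc_skew <- heterogeneity_score(feats_of(
    partition_noniid(set, 5L, beta = 0.1, seed = 61L)), embedding = "pca")
  sc_iid <- heterogeneity_score(feats_of(
    partition_noniid(set, 5L, beta = 1e6, seed = 61L)), embedding = "pca")
  expect_gt(sc_skew, sc_iid)
})
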