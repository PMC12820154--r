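mk_update <- function(weights, n, id = 1L) {
  structure(list(weights = weights, n = n, client_id = id,
                 loss_trace = numeric(0), skipped = FALSE),
            class = "client_update")
}

test_that("aggregation is an n-weighted convex combination", {
  w <- list(a = matrix(1:4 / 10, 2), b = c(1, -1))
  # identical updates aggregate to themselves for any n_i
  agg <- aggregate_updates(list(mk_update(w, 1), mk_update(w, 7),
                                mk_update(w, 2)))
  expect_equal(agg, w, tolerance = 1e-12)
  # hand arithmetic: scalars 0 and 4 with n = (1, 3) -> 3
  agg2 <- aggregate_updates(list(mk_update(list(s = 0), 1),
                                 mk_update(list(s = 4), 3)))
  expect_equal(agg2$s, 3.0, tolerance = 1e-12)
  expect_error(aggregate_updates(list()), "empty round")
  expect_error(aggregate_updates(list(mk_update(w, 1),
                                      mk_update(w[1], 1))),
               "incompatible")
})

test_that("aggregation matches a per-element loop and ignores client order", {
  withr::with_seed(41L, {
    ups <- lapply(1:10, function(i)
      mk_update(list(a = matrix(rnorm(6), 2), b = rnorm(3)),
                n = sample(1:20, 1), id = i))
  })
  agg <- aggregate_updates(ups)
  n_tot <- sum(sapply(ups, `[[`, "n"))
  for (nm in c("a", "b")) {
    ref <- ups[[1]]$weights[[nm]] * 0
    for (u in ups) {
      for (k in seq_along(ref)) ref[k] <- ref[k] + u$n / n_tot * u$weights[[nm]][k]
    }
    expect_equal(agg[[nm]], ref, tolerance = 1e-12)
  }
  expect_equal(aggregate_updates(rev(ups)), agg, tolerance = 1e-12)
})

test_that("client selection is deterministic and respects the fraction", {
  expect_identical(select_clients(10L, 1.0, round = 3L, seed = 1L), 1:10)
  half <- select_clients(10L, 0.5, round = 2L, seed = 1L)
  expect_identical(length(half), 5L)
  expect_identical(anyDuplicated(half), 0L)
  expect_identical(select_clients(10L, 0.5, round = 2L, seed = 1L), half)
  expect_false(identical(select_clients(10L, 0.5, round = 3L, seed = 1L),
                         half) &&
                 identical(select_clients(10L, 0.5, round = 2L, seed = 9L),
                           half))
  expect_error(select_clients(10L, 0), "fraction")
})

test_that("a round increments state and a single client dictates the aggregate", {
  m <- tiny_model(seed = 42L, lora = TRUE, train_head = TRUE)
  shard <- tiny_shard(n = 6L)
  cfg <- federation_config(n_clients = 1L, rounds = 1L,
                           strategy = "fedprox_lora", mu = 0.5,
                           lora = lora_config(rank = 2, alpha = 4, dropout = 0,
                                              train_head = TRUE),
                           local = fedprox_config(local_epochs = 1L,
                                                  batch_size = 4L,
                                                  learning_rate = 1e-3),
                           seed = 7L)
  rr <- run_round(m, list(shard), cfg, round = 1L)
  expect_identical(rr$log$round, 1L)
  # with one client the global update equals that client's update
  lcfg <- cfg$local
  lcfg$mu <- 0.5
  lcfg$seed <- (cfg$seed * 7919L + 1L * 104729L + 1L) %% .Machine$integer.max
  up <- local_train(shard, m, lcfg)
  expect_equal(rr$model$params[names(up$weights)], up$weights, tolerance = 0)
  # payload accounting: elements of the exchanged set, both directions
  n_el <- ns$tensor_elements(up$weights)
  expect_equal(rr$log$uplink_bytes, n_el * 4)
  expect_equal(rr$log$payload_bytes, 2 * n_el * 4)
})

test_that("full-size LoRA uplink is 589,824 bytes per client per round", {
  st <- extract_adapter_state(full_lora_model())
  bytes <- communication_cost(ns$tensor_elements(st), 32L, "bytes")
  expect_equal(bytes, 589824)   # 147,456 x 4 bytes; displays as 0.56 MiB
  expect_equal(ns$round_half_up(bytes / 2^20, 2), 0.56)
})

test_that("zero rounds leave the initialisation untouched", {
  m <- tiny_model(seed = 43L)
  cfg <- federation_config(n_clients = 2L, rounds = 0L, strategy = "fedavg",
                           local = fedprox_config(local_epochs = 1L), seed = 1L)
  shards <- list(tiny_shard(seed = 1L), tiny_shard(seed = 2L))
  run <- run_federated_training(cfg, shards, model = m)
  expect_identical(nrow(run$history), 0L)
  expect_equal(run$model$params, m$params, tolerance = 0)
})

test_that("cumulative payload follows rounds x clients x per-client cost", {
  m <- tiny_model(seed = 44L, lora = TRUE, train_head = TRUE)
  cfg <- federation_config(n_clients = 2L, rounds = 3L,
                           strategy = "fedprox_lora", mu = 0.5,
                           lora = lora_config(rank = 2, alpha = 4, dropout = 0,
                                              train_head = TRUE),
                           local = fedprox_config(local_epochs = 1L,
                                                  batch_size = 4L,
                                                  learning_rate = 1e-3),
                           seed = 2L)
  shards <- list(tiny_shard(n = 5L, seed = 3L), tiny_shard(n = 7L, seed = 4L))
  run <- run_federated_training(cfg, shards, model = m)
  tn <- names(m$params)[m$trainable[names(m$params)]]
  per_client <- ns$tensor_elements(m$params[tn]) * 4
  expect_equal(sum(run$history$uplink_bytes), 3 * 2 * per_client)
  expect_identical(run$history$round, 1:3)
})

test_that("payload ratio of LoRA to full-model arms gives the 97.40% reduction", {
  lora_el <- 147456
  full_el <- 5672258
  expect_equal(ns$round_half_up(100 * (1 - lora_el / full_el), 2), 97.40)
  expect_equal(ns$round_half_up(
    100 * (1 - communication_cost(lora_el, 32, "binary_mib") /
             communication_cost(full_el, 32, "binary_mib")), 2), 97.40)
})

test_that("convergence_rounds finds the first threshold crossing", {
  h <- data.frame(round = 1:3, accuracy = c(0.5, 0.7, 0.9))
  expect_identical(convergence_rounds(h, "accuracy", 0.8), 3L)
  expect_identical(convergence_rounds(h, "accuracy", 0.99), NA_integer_)
  expect_error(convergence_rounds(h, "f1", 0.5), "unknown metric")
  expect_error(convergence_rounds(h[0, ], "accuracy", 0.5), "empty")
  withr::with_seed(45L, {
    for (i in 1:20) {
      acc <- runif(6)
      thr <- runif(1)
      h2 <- data.frame(round = 1:6, accuracy = acc)
      scan <- NA_integer_
      for (r in 1:6) if (acc[r] >= thr) { scan <- r; break }
      expect_identical(convergence_rounds(h2, "accuracy", thr), scan)
    }
  })
})
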