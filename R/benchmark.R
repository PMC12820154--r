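# The packaged synthetic non-IID benchmark: a fixed desk-scale configuration
# on which the four federation strategies can be compared end to end.

#' Build the packaged synthetic federated benchmark
#'
#' A reproducible desk-scale setting for strategy comparisons: a reduced
#' transformer (64-px input, 4 blocks, dim 48, 3 heads), 400 synthetic
#' radiographs (class effect 0.3 = 6x the pixel noise sd) split 300/100
#' train/test, Dirichlet(0.5) label-skew over 10 clients with a per-client
#' intensity shift, and a backbone pretrained to convergence on a disjoint
#' 300-image synthetic set. LoRA fine-tuning presumes a pretrained
#' backbone, so every strategy arm starts from this common checkpoint —
#' mirroring the full-scale protocol, where the backbone is
#' ImageNet-pretrained before federated fine-tuning.
#'
#' @param seed integer seed controlling data generation, partitioning and
#'   pretraining.
#' @param n_images benchmark set size (train + test).
#' @param n_clients number of clients.
#' @param pretrain_epochs centralized epochs for the backbone checkpoint.
#' @return list with `vit` (the reduced [vit_config()]), `shards`, `test`,
#'   `model` (the pretrained backbone), `pretrain_loss` (loss trace), and
#'   the generator config `synthetic`.
#' @export
synthetic_benchmark <- function(seed = 11L, n_images = 400L, n_clients = 10L,
                                pretrain_epochs = 10L) {
  vit <- vit_config(image_size = 64L, patch_size = 16L, in_channels = 3L,
                    embed_dim = 48L, depth = 4L, num_heads = 3L)
  scfg <- synthetic_config(n_images = as.integer(n_images), prevalence = 0.5,
                           image_size = 64L, effect_size = 0.3,
                           client_shift = 0.05, noise_sd = 0.05,
                           seed = as.integer(seed))
  bench <- make_federated_synthetic(scfg, n_clients = n_clients, beta = 0.5,
                                    test_fraction = 0.25, vit = vit)
  # disjoint pretraining set (different seed stream, same conditions)
  pre_cfg <- synthetic_config(n_images = 300L, prevalence = 0.5,
                              image_size = 64L, effect_size = 0.3,
                              noise_sd = 0.05, seed = as.integer(seed) + 7777L)
  pre_set <- generate_synthetic_cxr(pre_cfg)
  pre_shard <- structure(
    list(client_id = 0L,
         x = lapply(pre_set$images, function(im)
           patchify(preprocess(im, vit$image_size), vit$patch_size)),
         y = pre_set$labels, n = length(pre_set$labels)),
    class = "client_shard")
  model <- build_model(vit, seed = as.integer(seed))
  pt <- fedprox_config(mu = 0, local_epochs = as.integer(pretrain_epochs),
                       batch_size = 16L, learning_rate = 1e-3,
                       seed = as.integer(seed))
  up <- local_train(pre_shard, model, pt)
  model$params[names(up$weights)] <- up$weights
  list(vit = vit, shards = bench$shards, test = bench$test, model = model,
       pretrain_loss = up$loss_trace, synthetic = scfg)
}

#' Run one strategy arm on the packaged benchmark
#'
#' Starts from the benchmark's pretrained backbone (LoRA arms inject
#' adapters into it) and runs the federated round loop with the benchmark
#' optimisation settings: AdamW lr 1e-4 (the configured fine-tuning rate),
#' batch 16, 1 local epoch, mu 0.5 for the FedProx arms, LoRA rank 8 /
#' alpha 16 with a trainable exchanged head.
#'
#' @param bm a [synthetic_benchmark()] result.
#' @param strategy one of the four strategy arms.
#' @param seed federation seed (client ordering, shuffling, adapter init).
#' @param rounds communication rounds.
#' @return a `federation_run`.
#' @export
run_benchmark_arm <- function(bm, strategy, seed = 42L, rounds = 10L) {
  local <- fedprox_config(mu = 0.5, local_epochs = 1L, batch_size = 16L,
                          learning_rate = 1e-4, weight_decay = 0.01)
  cfg <- federation_config(n_clients = length(bm$shards), rounds = rounds,
                           strategy = strategy, mu = 0.5,
                           lora = lora_config(rank = 8L, alpha = 16,
                                              dropout = 0, train_head = TRUE),
                           local = local, seed = as.integer(seed))
  model <- bm$model
  if (strategy_uses_lora(strategy))
    model <- inject_lora(model, cfg$lora, seed = as.integer(seed) + 1L)
  run_federated_training(cfg, bm$shards, bm$test, model = model)
}
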