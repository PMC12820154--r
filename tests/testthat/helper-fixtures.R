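# Shared fixtures: tiny architectures keep forward/backward passes cheap
# while exercising every code path (multiple heads, blocks, adapters).

ns <- asNamespace("fedlorasim")

tiny_cfg <- function(...) {
  vit_config(image_size = 16L, patch_size = 8L, in_channels = 1L,
             embed_dim = 8L, depth = 2L, num_heads = 2L, num_classes = 2L, ...)
}

tiny_model <- function(seed = 3L, lora = FALSE, rank = 2L, dropout = 0,
                       train_head = FALSE, nonzero_B = FALSE) {
  m <- build_model(tiny_cfg(), seed = seed)
  if (lora) {
    m <- inject_lora(m, lora_config(rank = rank, alpha = 2 * rank,
                                    dropout = dropout,
                                    train_head = train_head),
                     seed = seed + 1L)
    if (nonzero_B) {
      withr::with_seed(seed + 2L, {
        for (nm in grep("\\.B$", names(m$params), value = TRUE))
          m$params[[nm]] <- matrix(rnorm(length(m$params[[nm]]), sd = 0.1),
                                   nrow(m$params[[nm]]))
      })
    }
  }
  m
}

tiny_image <- function(seed = 5L, size = 16L, channels = 1L) {
  withr::with_seed(seed, array(runif(size * size * channels),
                               c(size, size, channels)))
}

# A linearly separable toy shard for the tiny model: class 1 images are
# brighter in a fixed quadrant.
tiny_shard <- function(n = 8L, seed = 9L) {
  withr::with_seed(seed, {
    y <- rep(0:1, length.out = n)
    x <- lapply(seq_len(n), function(i) {
      img <- array(runif(16 * 16, 0, 0.3), c(16, 16, 1))
      if (y[i] == 1L) img[1:8, 1:8, 1] <- img[1:8, 1:8, 1] + 0.6
      img
    })
  })
  structure(list(client_id = 1L, x = x, y = y, n = n), class = "client_shard")
}

# Full-size DeiT-tiny models are expensive to build; construct once per run.
full_base_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_model(vit_config(), seed = 1L)
    cache
  }
})

full_lora_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- inject_lora(full_base_model(), lora_config(), seed = 2L)
    cache
  }
})
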