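# Memoised miniature training run shared by inference tests: one 32^3
# paired phantom, patch 16, a few dozen iterations.
.mini_cache <- new.env(parent = emptyenv())

mini_trained <- function() {
  if (!is.null(.mini_cache$run)) return(.mini_cache$run)
  pd <- tiny_paired(n = 32, seed = 6)
  sc <- pd$provenance$scheme
  tr <- train(list(pd), sc,
              train_config(patch_size = 16, batch_size = 2,
                           max_iterations = 60, learning_rate = 3e-3,
                           seed = 11),
              loss_config(),
              spec = network_spec(depth = 2, base_channels = 4, seed = 11))
  .mini_cache$run <- list(training = tr, paired = pd, scheme = sc)
  .mini_cache$run
}
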