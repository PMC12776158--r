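# Small normalized dataset with a deterministic split layout, for training
# tests (16 x 16 patches satisfy the teacher's divisible-by-8 grid).
make_train_fixture <- function(n_patches = 12, patch = 16, seed = 31,
                               density = 13) {
  pairs <- lapply(1:2, function(i) {
    fld <- simulate_emitter_field(40, 40, 0.1, density, rng_seed = seed + i)
    render_pair(fld, rng_seed = seed + 10 + i)
  })
  ds <- build_patch_dataset(pairs, patch, ceiling(n_patches / 2),
                            rng_seed = seed, y_scale = 1 / 1000)
  n <- length(ds$x)
  stopifnot(n >= 6)
  ds$split <- factor(rep(c("train", "val", "test"),
                         times = c(n - 4, 2, 2)),
                     levels = c("train", "val", "test"))
  normalize_dataset(ds)
}
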