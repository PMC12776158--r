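#!/usr/bin/env Rscript
# Generate the synthetic dense-emitter study data.
#
# Emulates the localization-microscopy simulation protocol: emitter fields
# at 13 emitters/um^2 on a 0.1 um/px grid, pixel-integrated Gaussian PSF
# (sigma 1.6 px), uniform background of 200 counts with Poisson shot noise,
# random paired patches split 80:10:10, inputs z-scored over the whole set.
# Writes the dataset bundle and a generation summary under results/.

suppressPackageStartupMessages(library(stormdistill))
seed <- 1L
out <- "results/01_simulate"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

run_stage(list(stage = "simulate", out_dir = out, seed = seed,
               density_per_um2 = 13, background_level = 200))
ds <- read_dataset(file.path(out, "dataset"))

summary_df <- data.frame(
  n_patches = length(ds$x),
  patch_size = ds$patch_size,
  train = sum(ds$split == "train"),
  val = sum(ds$split == "val"),
  test = sum(ds$split == "test"),
  norm_mean = ds$norm_mean,
  norm_std = ds$norm_std,
  mean_spike_pixels = mean(vapply(ds$y, function(y) sum(y > 0), numeric(1)))
)
write.csv(summary_df, file.path(out, "dataset_summary.csv"),
          row.names = FALSE)
print(summary_df, row.names = FALSE)
cat("Dense-emitter desk-scale dataset written to", out, "\n")
cat("Each patch holds on average", round(summary_df$mean_spike_pixels),
    "ground-truth emitter pixels - overlapping-PSF conditions.\n")
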