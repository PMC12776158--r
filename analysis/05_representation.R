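#!/usr/bin/env Rscript
# Compare 32-channel hint-layer representations across four models
# (untrained student, trained student, hint-learned student, teacher):
# joint 2-D embedding of pooled features plus matched pairwise distances
# to the teacher, summarized by the hint-minus-plain shift.

suppressPackageStartupMessages(library(stormdistill))
seed <- 1L
out <- "results/05_representation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
ds <- read_dataset("results/01_simulate/dataset")
teacher <- load_model("results/02_baselines/teacher")
student <- load_model("results/02_baselines/student")
hinted <- load_model("results/04_hint/student_hint_learned")
untrained <- build_srcnn(seed + 20L)
untrained$name <- "SRCNN untrained"
student$name <- "SRCNN trained"
hinted$name <- "SRCNN hint-learned"

te <- dataset_split(ds, "test")
sets <- lapply(list(untrained, student, hinted, teacher),
               extract_features, patches = te$x, ids = te$index)

emb <- tryCatch(
  embed_models(sets, method = "umap", seed = seed + 50L),
  error = function(e) {
    message("UMAP bridge unavailable (", conditionMessage(e),
            "); falling back to PCA")
    embed_models(sets, method = "pca")
  })
write.csv(emb, file.path(out, "embedding.csv"), row.names = FALSE)
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(emb, aes(u1, u2, color = model)) + geom_point(size = 1) +
    theme_bw() + labs(title = "Hint-layer features, joint 2-D embedding")
  ggsave(file.path(out, "embedding.png"), p, width = 5, height = 4,
         dpi = 150)
}

d_plain <- pairwise_distances(sets[[4]], sets[[2]])
d_hint <- pairwise_distances(sets[[4]], sets[[3]])
write.csv(data.frame(patch = te$index, teacher_vs_student = d_plain,
                     teacher_vs_hint = d_hint),
          file.path(out, "pairwise_distances.csv"), row.names = FALSE)
sh <- distance_shift_summary(d_hint, d_plain)
cat("mean distance to teacher: hint-learned", round(sh$mean_hint, 4),
    "vs plain", round(sh$mean_plain, 4), "\n")
cat("shift (hint minus plain):", round(sh$shift$mean, 4),
    "- negative means hint learning pulled features toward the teacher\n")
jsonlite::write_json(sh, file.path(out, "distance_shift.json"),
                     auto_unbox = TRUE, digits = NA)
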