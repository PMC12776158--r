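#!/usr/bin/env Rscript
# Hint learning: train the student body to mimic the teacher's 32-channel
# hint representation, then freeze the body and fine-tune only the
# reconstruction head with the imitation loss. Writes histories, the
# hint-learned checkpoint and its test metrics.

suppressPackageStartupMessages(library(stormdistill))
seed <- 1L
out <- "results/04_hint"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
ds <- read_dataset("results/01_simulate/dataset")
teacher <- load_model("results/02_baselines/teacher")

hint_fit <- train_hint(build_srcnn(seed + 22L), teacher, ds,
                       train_config(epochs = 20L, rng_seed = seed + 41L))
write.csv(hint_fit$history, file.path(out, "hint_history.csv"),
          row.names = FALSE)
cat("hint MSE:", round(hint_fit$history$train_loss[1], 4), "->",
    round(tail(hint_fit$history$train_loss, 1), 4), "over",
    nrow(hint_fit$history), "epochs\n")

tr <- dataset_split(ds, "train")
tpred <- lapply(tr$x, function(x) model_forward(teacher, x))
eT <- teacher_error_vector(tpred, tr$y, 100)
ctx <- ail_context(100, 0.6, eT)
hinted <- freeze_body(hint_fit$model)
head_fit <- train_head_after_hint(hinted, teacher, ds, alpha = 0.6,
                                  train_config(epochs = 30L,
                                               rng_seed = seed + 42L),
                                  ctx = ctx)
save_model(head_fit$model, file.path(out, "student_hint_learned"))
write.csv(head_fit$history, file.path(out, "head_history.csv"),
          row.names = FALSE)

rep <- evaluate(head_fit$model, ds, "test")
print(rep)
write.csv(data.frame(patch = rep$patch_index, nmse = rep$nmse,
                     ssim = rep$ssim),
          file.path(out, "test_metrics.csv"), row.names = FALSE)
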