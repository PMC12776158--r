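#' Hyperparameter sweeps
#'
#' `sweep_lambda()` retrains a fresh model per sparsity weight
#' \eqn{\lambda} and collects the test-split metric distributions;
#' `sweep_alpha()` does the same over the attention weight \eqn{\alpha} of
#' the imitation loss, distilling a fresh student from the same frozen
#' teacher each time. Every run is independently seeded from the config
#' seed plus the grid index, so rows are reproducible in isolation.
#'
#' @param model_builder function(rng_seed) returning a fresh
#'   `factorized_model`.
#' @param dataset a normalized `patch_dataset` with a test split.
#' @param lambda_values numeric vector of \eqn{\lambda} values; the study
#'   grid is `c(10, 50, 100, 200, 400, 800)` with a wider
#'   `c(5, 25, 50, 100, 200, 400, 800)` variant used when low-\eqn{\lambda}
#'   behavior is of interest.
#' @param cfg a [train_config()]; its `lam` is overridden per row.
#' @return data frame with one row per grid value (`lambda` or `alpha`,
#'   `mean_nmse`, `mean_ssim`, `median_nmse`, `median_ssim`); full
#'   per-patch metric vectors are attached as the `"distributions"`
#'   attribute (a named list of `metrics_report`s).
#' @export
sweep_lambda <- function(model_builder, dataset,
                         lambda_values = c(10, 50, 100, 200, 400, 800),
                         cfg = train_config()) {
  stopifnot(length(lambda_values) >= 1L)
  reports <- list()
  rows <- lapply(seq_along(lambda_values), function(j) {
    lam <- lambda_values[j]
    cfg_j <- cfg
    cfg_j$lam <- lam
    cfg_j$rng_seed <- cfg$rng_seed + j - 1L
    fit <- train_baseline(model_builder(cfg_j$rng_seed), dataset, cfg_j)
    rep <- evaluate(fit$model, dataset, split = "test")
    reports[[as.character(lam)]] <<- rep
    data.frame(lambda = lam, mean_nmse = mean(rep$nmse),
               mean_ssim = mean(rep$ssim), median_nmse = median(rep$nmse),
               median_ssim = median(rep$ssim))
  })
  out <- do.call(rbind, rows)
  attr(out, "distributions") <- reports
  out
}

#' @rdname sweep_lambda
#' @param student_builder function(rng_seed) returning a fresh student.
#' @param teacher a trained, frozen `factorized_model`.
#' @param alpha_values attention-weight grid (default 0.1 to 0.8 in 0.1
#'   steps; 0.9 is available by passing it explicitly).
#' @param ctx an [ail_context()] from the teacher's error vector.
#' @export
sweep_alpha <- function(student_builder, teacher, dataset,
                        alpha_values = seq(0.1, 0.8, by = 0.1),
                        cfg = train_config(), ctx) {
  stopifnot(length(alpha_values) >= 1L)
  reports <- list()
  rows <- lapply(seq_along(alpha_values), function(j) {
    a <- alpha_values[j]
    cfg_j <- cfg
    cfg_j$rng_seed <- cfg$rng_seed + j - 1L
    fit <- train_with_ail(student_builder(cfg_j$rng_seed), teacher, dataset,
                          alpha = a, cfg = cfg_j, ctx = ctx)
    rep <- evaluate(fit$model, dataset, split = "test")
    reports[[as.character(a)]] <<- rep
    data.frame(alpha = a, mean_nmse = mean(rep$nmse),
               mean_ssim = mean(rep$ssim), median_nmse = median(rep$nmse),
               median_ssim = median(rep$ssim))
  })
  out <- do.call(rbind, rows)
  attr(out, "distributions") <- reports
  out
}
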