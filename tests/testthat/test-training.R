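test_that("zero-epoch training returns the model unchanged", {
  ds <- make_train_fixture()
  m <- build_srcnn(1)
  fit <- train_baseline(m, ds, train_config(epochs = 0))
  expect_identical(fit$model$params, m$params)
  expect_equal(nrow(fit$history), 0)
})

test_that("a single memorizable patch is overfit substantially", {
  ds <- make_train_fixture(n_patches = 12)
  one <- ds
  n <- length(one$x)
  one$split <- factor(c("train", "val", rep("test", n - 2)),
                      levels = c("train", "val", "test"))
  fit <- train_baseline(build_srcnn(2), one,
                        train_config(epochs = 50, rng_seed = 3))
  expect_lt(tail(fit$history$train_loss, 1),
            0.5 * fit$history$train_loss[1])
  # history bookkeeping
  expect_equal(nrow(fit$history), 50)
  expect_true(all(diff(fit$history$lr) <= 0))
})

test_that("plateaued loss drops the learning rate by one order of magnitude", {
  ds <- make_train_fixture()
  # a vanishing learning rate guarantees no observable improvement
  cfg <- train_config(epochs = 7, learning_rate = 1e-12, rng_seed = 4)
  fit <- train_baseline(build_srcnn(3), ds, cfg)
  expect_equal(fit$history$lr[1:6], rep(1e-12, 6))
  expect_equal(fit$history$lr[7], 1e-13)
})

test_that("AIL training at alpha = 1 reproduces baseline bit-for-bit", {
  ds <- make_train_fixture()
  teacher <- build_drlstorm(5)
  tr <- dataset_split(ds, "train")
  tpred <- lapply(tr$x, function(x) model_forward(teacher, x))
  eT <- teacher_error_vector(tpred, tr$y, 100)
  ctx <- ail_context(100, 1, eT)
  cfg <- train_config(epochs = 3, rng_seed = 6)
  base <- train_baseline(build_srcnn(7), ds, cfg)
  dist <- train_with_ail(build_srcnn(7), teacher, ds, alpha = 1,
                         cfg = cfg, ctx = ctx)
  expect_identical(dist$model$params, base$model$params)
  expect_equal(dist$history$train_loss, base$history$train_loss)
  expect_error(train_with_ail(build_srcnn(7), teacher, ds, 0.5, cfg),
               "ail_context")
})

test_that("the teacher never changes during distillation", {
  ds <- make_train_fixture()
  teacher <- build_drlstorm(8)
  digest_before <- stormdistill:::weights_digest(teacher)
  tr <- dataset_split(ds, "train")
  eT <- teacher_error_vector(lapply(tr$x, function(x)
    model_forward(teacher, x)), tr$y, 100)
  ctx <- ail_context(100, 0.3, eT)
  fit <- train_with_ail(build_srcnn(9), teacher, ds, alpha = 0.3,
                        cfg = train_config(epochs = 2, rng_seed = 9),
                        ctx = ctx)
  expect_identical(stormdistill:::weights_digest(teacher), digest_before)
  expect_true(all(is.finite(fit$history$val_loss)))
})

test_that("hint learning: fixed point at an identical teacher, and descent", {
  ds <- make_train_fixture()
  twin <- build_srcnn(10)
  # student initialized as an exact copy of a same-architecture teacher
  fit0 <- train_hint(build_srcnn(10), twin, ds,
                     train_config(epochs = 2, learning_rate = 0,
                                  rng_seed = 11))
  expect_equal(fit0$history$train_loss, c(0, 0))
  expect_identical(fit0$model$params, build_srcnn(10)$params)

  teacher <- build_drlstorm(12)
  student <- build_srcnn(13)
  head_before <- student$params$head
  fit <- train_hint(student, teacher, ds,
                    train_config(epochs = 8, rng_seed = 12))
  expect_lte(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  # the head is untouched by hint learning
  expect_identical(fit$model$params$head, head_before)
})

test_that("head fine-tuning trains only the head over a frozen body", {
  ds <- make_train_fixture()
  teacher <- build_drlstorm(14)
  tr <- dataset_split(ds, "train")
  eT <- teacher_error_vector(lapply(tr$x, function(x)
    model_forward(teacher, x)), tr$y, 100)
  ctx <- ail_context(100, 0.6, eT)
  student <- build_srcnn(15)
  expect_error(train_head_after_hint(student, teacher, ds, 0.6,
                                     train_config(epochs = 1), ctx),
               "frozen")
  frozen <- freeze_body(student)
  body_digest <- stormdistill:::weights_digest(frozen, "body")
  fit <- train_head_after_hint(frozen, teacher, ds, 0.6,
                               train_config(epochs = 3, rng_seed = 16), ctx)
  expect_identical(stormdistill:::weights_digest(fit$model, "body"),
                   body_digest)
  expect_false(identical(fit$model$params$head, student$params$head))
  expect_equal(param_count(fit$model, "head"), 801)
  expect_true(is.finite(tail(fit$history$train_loss, 1)))
})

test_that("training is bit-reproducible under a fixed seed", {
  ds <- make_train_fixture()
  cfg <- train_config(epochs = 2, rng_seed = 21)
  a <- train_baseline(build_srcnn(20), ds, cfg)
  b <- train_baseline(build_srcnn(20), ds, cfg)
  expect_identical(a$model$params, b$model$params)
  expect_identical(a$history, b$history)
})

test_that("sweeps produce one row per grid value with distributions", {
  ds <- make_train_fixture(n_patches = 16)
  cfg <- train_config(epochs = 2, rng_seed = 30)
  tab <- suppressWarnings(sweep_lambda(build_srcnn, ds, c(10, 100), cfg))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$lambda, c(10, 100))
  dists <- attr(tab, "distributions")
  expect_length(dists, 2)
  expect_true(all(vapply(dists, function(r) length(r$ssim) > 0, logical(1))))

  teacher <- build_drlstorm(31)
  tr <- dataset_split(ds, "train")
  eT <- teacher_error_vector(lapply(tr$x, function(x)
    model_forward(teacher, x)), tr$y, 100)
  ctx <- ail_context(100, 0.5, eT)
  ta <- suppressWarnings(sweep_alpha(build_srcnn, teacher, ds,
                                     alpha_values = c(0.1, 0.9),
                                     cfg = cfg, ctx = ctx))
  expect_equal(nrow(ta), 2)
  # a length-1 grid equals a single distillation run
  t1 <- suppressWarnings(sweep_alpha(build_srcnn, teacher, ds,
                                     alpha_values = 0.4, cfg = cfg,
                                     ctx = ctx))
  single <- train_with_ail(build_srcnn(cfg$rng_seed), teacher, ds, 0.4,
                           cfg = cfg, ctx = ctx)
  rep_single <- suppressWarnings(evaluate(single$model, ds, "test"))
  expect_equal(t1$mean_ssim, mean(rep_single$ssim), tolerance = 1e-12)
  expect_equal(t1$mean_nmse, mean(rep_single$nmse), tolerance = 1e-12)

  # default alpha grid is 0.1..0.8
  expect_equal(eval(formals(sweep_alpha)$alpha_values),
               seq(0.1, 0.8, by = 0.1))
})
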