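test_that("gaussian kernel matches direct sampling and is symmetric", {
  k1 <- make_gaussian_kernel(1, 1)
  expect_equal(k1$weights, matrix(1, 1, 1))

  k <- make_gaussian_kernel(3, 1)
  expect_equal(sum(k$weights), 1, tolerance = 1e-12)
  expect_equal(k$weights, oracle_gaussian_kernel(3, 1), tolerance = 1e-12)
  # center weight is exp(0)/Z with Z the sum of the 9 sampled values
  Z <- sum(exp(-(outer(-1:1, -1:1, function(i, j) i^2 + j^2)) / 2))
  expect_equal(k$weights[2, 2], 1 / Z, tolerance = 1e-12)
  expect_equal(k$weights, k$weights[3:1, ])
  expect_equal(k$weights, k$weights[, 3:1])

  k5 <- make_gaussian_kernel(5, 2)
  expect_equal(k5$weights, oracle_gaussian_kernel(5, 2), tolerance = 1e-12)
  expect_error(make_gaussian_kernel(4, 1), "odd")
  expect_error(make_gaussian_kernel(3, 0), "sigma")
})

test_that("l1l2 loss matches its brute-force oracle and analytic cases", {
  z <- matrix(0, 4, 4)
  expect_equal(l1l2_loss(z, z, lam = 100), 0)

  one <- z; one[2, 3] <- 1
  expect_equal(l1l2_loss(one, one, lam = 7), 1)
  expect_equal(l1l2_loss(one, one, lam = 812), 1)

  for (seed in 1:3) {
    pred <- rand_img(4, 4, seed)
    truth <- rand_img(4, 4, seed + 50)
    expect_equal(l1l2_loss(pred, truth, lam = 100),
                 oracle_l1l2(list(pred), list(truth), 100),
                 tolerance = 1e-10)
  }
  # batch of three, 6x5
  preds <- lapply(11:13, function(s) rand_img(6, 5, s))
  truths <- lapply(21:23, function(s) rand_img(6, 5, s))
  expect_equal(l1l2_loss(preds, truths, lam = 50),
               oracle_l1l2(preds, truths, 50), tolerance = 1e-10)
  expect_error(l1l2_loss(rand_img(4, 4, 1), rand_img(5, 5, 1), 10),
               "shape")
})

test_that("l1l2 gradient matches numerical differentiation", {
  kern <- make_gaussian_kernel()
  pred <- rand_img(5, 5, 3)
  truth <- rand_img(5, 5, 4)
  g <- stormdistill:::l1l2_grad_sample(pred, truth, 100, kern)
  eps <- 1e-6
  for (idx in c(1, 7, 13, 25)) {
    p2 <- pred; p2[idx] <- p2[idx] + eps
    p3 <- pred; p3[idx] <- p3[idx] - eps
    ng <- (stormdistill:::l1l2_sample(p2, truth, 100, kern) -
           stormdistill:::l1l2_sample(p3, truth, 100, kern)) / (2 * eps)
    expect_equal(g[idx], ng, tolerance = 1e-4)
  }
})

test_that("teacher error vector is the per-sample l1l2 loss", {
  truths <- lapply(1:3, function(s) rand_img(4, 4, s) * 0)
  preds <- truths
  eT <- teacher_error_vector(preds, truths, lam = 100)
  expect_equal(eT, c(0, 0, 0))

  preds <- lapply(31:34, function(s) rand_img(4, 4, s))
  truths <- lapply(41:44, function(s) rand_img(4, 4, s))
  eT <- teacher_error_vector(preds, truths, lam = 100)
  expect_length(eT, 4)
  for (i in 1:4) {
    expect_equal(eT[i], l1l2_loss(preds[[i]], truths[[i]], 100),
                 tolerance = 1e-12)
  }
  expect_error(teacher_error_vector(list(), list(), 100), "nonempty")
})

test_that("eta and phi follow their definitions", {
  ep <- compute_eta_phi(c(2, 4, 6))
  expect_equal(ep$eta, 4)
  expect_equal(ep$phi, 1.0)
  ep2 <- compute_eta_phi(c(0, 1))
  expect_equal(ep2$eta, 1)
  expect_equal(ep2$phi, 0.5)
  expect_error(compute_eta_phi(c(5, 5, 5)), "degenerate")
  expect_error(compute_eta_phi(3), "at least 2")
})

test_that("AIL matches oracle in both modes and reduces analytically", {
  e_T <- c(1, 2, 6)  # eta 5, phi 0.6
  students <- lapply(1:2, function(s) rand_img(4, 4, s + 60))
  teachers <- lapply(1:2, function(s) rand_img(4, 4, s + 70))
  truths <- lapply(1:2, function(s) rand_img(4, 4, s + 80))

  for (mode in c("as_printed", "imitation")) {
    ctx <- ail_context(100, 0.6, e_T, mode = mode)
    expect_equal(ail_loss(students, teachers, truths, ctx),
                 oracle_ail(students, teachers, truths, 100, 0.6,
                            ctx$phi, mode),
                 tolerance = 1e-10)
  }

  # alpha = 1: reduces exactly to the plain reconstruction loss
  ctx1 <- ail_context(100, 1, e_T)
  expect_identical(ail_loss(students, teachers, truths, ctx1),
                   l1l2_loss(students, truths, 100))

  # phi = 0 scales the remaining term by alpha
  ctx0 <- ail_context(100, 0.3, e_T)
  ctx0$phi <- 0
  expect_equal(ail_loss(students, teachers, truths, ctx0),
               0.3 * l1l2_loss(students, truths, 100), tolerance = 1e-12)

  expect_error(ail_context(100, 1.2, e_T), "alpha")
})

test_that("AIL is affine in alpha and batch-permutation invariant", {
  e_T <- c(1, 3, 9)
  students <- lapply(1:3, function(s) rand_img(5, 5, s))
  teachers <- lapply(4:6, function(s) rand_img(5, 5, s))
  truths <- lapply(7:9, function(s) rand_img(5, 5, s))
  at <- function(a, mode = "as_printed") {
    ail_loss(students, teachers, truths, ail_context(100, a, e_T, mode = mode))
  }
  for (mode in c("as_printed", "imitation")) {
    v <- vapply(c(0.2, 0.5, 0.8), at, numeric(1), mode = mode)
    # three collinear points: midpoint equals mean of the ends
    expect_equal(v[2], (v[1] + v[3]) / 2, tolerance = 1e-10)
  }
  perm <- c(3, 1, 2)
  ctx <- ail_context(100, 0.4, e_T)
  expect_equal(ail_loss(students[perm], teachers[perm], truths[perm], ctx),
               ail_loss(students, teachers, truths, ctx), tolerance = 1e-12)
  expect_equal(l1l2_loss(students[perm], truths[perm], 100),
               l1l2_loss(students, truths, 100), tolerance = 1e-12)
})

test_that("AIL gradient matches numerical differentiation in both modes", {
  e_T <- c(1, 2, 6)
  s <- rand_img(4, 4, 91); tch <- rand_img(4, 4, 92); tr <- rand_img(4, 4, 93)
  for (mode in c("as_printed", "imitation")) {
    ctx <- ail_context(100, 0.6, e_T, mode = mode)
    g <- stormdistill:::ail_grad_sample(s, tch, tr, ctx)
    eps <- 1e-6
    for (idx in c(2, 9, 16)) {
      s2 <- s; s2[idx] <- s2[idx] + eps
      s3 <- s; s3[idx] <- s3[idx] - eps
      f <- function(x) ail_loss(x, tch, tr, ctx)
      expect_equal(g[idx], (f(s2) - f(s3)) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("hint loss follows the mean-MSE convention", {
  a <- array(rand_img(4, 4, 1), c(4, 4, 1))
  a32 <- array(rnorm(4 * 4 * 32), c(4, 4, 32))
  expect_equal(hint_loss(a32, a32), 0)
  expect_equal(hint_loss(a32, a32 + 0.5), 0.25, tolerance = 1e-12)

  withr::with_seed(5, {
    sa <- lapply(1:2, function(i) array(rnorm(3 * 3 * 32), c(3, 3, 32)))
    sb <- lapply(1:2, function(i) array(rnorm(3 * 3 * 32), c(3, 3, 32)))
  })
  expect_equal(hint_loss(sa, sb), oracle_hint_mse(sa, sb),
               tolerance = 1e-12)
  expect_equal(hint_loss(sa, sb, reduction = "sum"),
               oracle_hint_mse(sa, sb) * (2 * 3 * 3 * 32), tolerance = 1e-10)
  # permutation invariance
  expect_equal(hint_loss(sa[2:1], sb[2:1]), hint_loss(sa, sb),
               tolerance = 1e-15)
  bad <- lapply(1:2, function(i) array(rnorm(3 * 3 * 16), c(3, 3, 16)))
  expect_error(hint_loss(sa, bad), "32")
})
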