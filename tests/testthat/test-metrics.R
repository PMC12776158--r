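test_that("NMSE follows the printed convention and its oracle", {
  x <- rand_img(8, 8, 1)
  expect_equal(nmse(x, x), 0)
  expect_equal(nmse(matrix(0, 8, 8), x), sqrt(sum(x^2)), tolerance = 1e-12)

  p <- rand_img(8, 8, 2)
  expect_equal(nmse(p, x), oracle_nmse_printed(p, x), tolerance = 1e-12)
  expect_equal(nmse(p, x, mode = "standard"),
               sum((p - x)^2) / sum(x^2), tolerance = 1e-12)

  # printed-mode scale behavior: scaling both images by k scales NMSE by k
  for (k in c(0.5, 3, 10)) {
    expect_equal(nmse(k * p, k * x), k * nmse(p, x), tolerance = 1e-10)
  }
  expect_error(nmse(p, matrix(0, 8, 8)), "zero-norm")
  expect_error(nmse(rand_img(4, 4, 1), rand_img(5, 5, 1)), "shape")
})

test_that("SSIM: identity, constant-offset closed form, symmetry, oracle", {
  x <- rand_img(12, 12, 3)
  expect_equal(ssim(x, x), 1.0, tolerance = 1e-12)

  # constant truth, constant offset: only the luminance term deviates
  tru <- matrix(5, 12, 12)
  off <- tru + 2
  R <- 10
  c1 <- (0.01 * R)^2
  expected <- (2 * 7 * 5 + c1) / (7^2 + 5^2 + c1)
  expect_equal(ssim(off, tru, data_range = R), expected, tolerance = 1e-12)

  a <- rand_img(10, 10, 4)
  b <- rand_img(10, 10, 5)
  expect_equal(ssim(a, b, data_range = 2), ssim(b, a, data_range = 2),
               tolerance = 1e-12)
  expect_equal(ssim(a, b, data_range = 2),
               oracle_ssim_uniform(a, b, 7, 2), tolerance = 1e-10)
  expect_equal(ssim(a, b, window = 5, data_range = 1.5),
               oracle_ssim_uniform(a, b, 5, 1.5), tolerance = 1e-10)
  expect_error(ssim(a, b, window = 11), "larger than image")
  expect_true(abs(ssim(a, -a, data_range = 4)) <= 1)
})

test_that("evaluate reports per-patch metrics and is deterministic", {
  pairs <- make_tiny_pairs(n = 1, size = 24)
  ds <- build_patch_dataset(pairs, 8, 30, rng_seed = 6)
  ds$split <- factor(rep(c("train", "val", "test"), times = c(20, 4, 6)),
                     levels = c("train", "val", "test"))
  ds <- normalize_dataset(ds)
  n_test <- sum(ds$split == "test")
  # identity stub: returns each patch's own ground truth
  truth_lookup <- function(x) {
    for (i in seq_along(ds$x)) {
      if (identical(ds$x[[i]], x)) return(ds$y[[i]])
    }
    stop("patch not found")
  }
  rep <- suppressWarnings(evaluate(truth_lookup, ds, split = "test"))
  expect_true(all(rep$nmse == 0))
  expect_equal(rep$ssim, rep(1, length(rep$ssim)))
  expect_lte(length(rep$nmse), n_test)

  m <- build_srcnn(3)
  r1 <- suppressWarnings(evaluate(m, ds, split = "test"))
  r2 <- suppressWarnings(evaluate(m, ds, split = "test"))
  expect_identical(r1$nmse, r2$nmse)
  expect_identical(r1$ssim, r2$ssim)
  expect_equal(length(r1$nmse), length(r1$ssim))
  expect_true(all(r1$nmse >= 0))
  expect_true(all(r1$ssim >= -1 & r1$ssim <= 1))
})

test_that("cross profiles interpolate bilinearly", {
  const <- matrix(3.5, 10, 10)
  expect_equal(cross_profile(const, c(1, 5), c(10, 5), 7), rep(3.5, 7))

  img <- matrix(0, 10, 10)
  img[4, ] <- 1:10
  # horizontal segment along row 4 hits that row's values at integer points
  prof <- cross_profile(img, c(1, 4), c(10, 4), 10)
  expect_equal(prof, as.numeric(1:10))

  # diagonal spot checks against hand interpolation
  rimg <- rand_img(10, 10, 8)
  prof2 <- cross_profile(rimg, c(2, 3), c(8, 9), 3)
  # midpoint is at (x, y) = (5, 6), a lattice point
  expect_equal(prof2[2], rimg[6, 5], tolerance = 1e-12)
  # quarter point of a 2-sample profile: start point itself
  expect_equal(prof2[1], rimg[3, 2], tolerance = 1e-12)
  mid <- cross_profile(rimg, c(2.5, 3), c(3.5, 3), 2)
  expect_equal(mid[1], 0.5 * rimg[3, 2] + 0.5 * rimg[3, 3],
               tolerance = 1e-12)
  expect_error(cross_profile(rimg, c(0, 5), c(5, 5)), "inside")
})
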