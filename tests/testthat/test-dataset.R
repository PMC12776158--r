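test_that("patch extraction pairs offsets and honors counts", {
  pairs <- make_tiny_pairs(n = 2, size = 24)
  ds <- build_patch_dataset(pairs, patch_size = 8, patches_per_image = 10,
                            rng_seed = 3)
  expect_length(ds$x, 20)
  expect_length(ds$y, 20)
  expect_true(all(vapply(ds$x, function(p) all(dim(p) == c(8, 8)),
                         logical(1))))

  # each x patch must be croppable from a source at the same offset as its y
  found <- vapply(seq_along(ds$x), function(k) {
    for (p in pairs) {
      for (r in 1:(24 - 8 + 1)) {
        for (cc in 1:(24 - 8 + 1)) {
          if (identical(p$x_dl[r:(r + 7), cc:(cc + 7)], ds$x[[k]]) &&
              identical(p$y_gt[r:(r + 7), cc:(cc + 7)], ds$y[[k]])) {
            return(TRUE)
          }
        }
      }
    }
    FALSE
  }, logical(1))
  expect_true(all(found))

  ds0 <- build_patch_dataset(pairs, 8, 0)
  expect_length(ds0$x, 0)
  expect_error(build_patch_dataset(pairs, 25, 5), "exceeds")
  expect_error(build_patch_dataset(pairs, 8, 5, split_probs = c(0.5, 0.2, 0.2)),
               "sum to 1")
  # determinism
  ds2 <- build_patch_dataset(pairs, 8, 10, rng_seed = 3)
  expect_identical(ds, ds2)
})

test_that("split fractions stay within the binomial 99% CI", {
  pairs <- make_tiny_pairs(n = 1, size = 24)
  n <- 10000
  ds <- build_patch_dataset(pairs, 8, n, rng_seed = 17)
  tab <- table(ds$split) / n
  targets <- c(train = 0.8, val = 0.1, test = 0.1)
  for (lv in names(targets)) {
    p <- targets[[lv]]
    half <- qnorm(0.995) * sqrt(p * (1 - p) / n)
    expect_lt(abs(tab[[lv]] - p), half)
  }
})

test_that("normalization pools stats over all x patches and is idempotent", {
  pairs <- make_tiny_pairs(n = 2, size = 24)
  ds <- build_patch_dataset(pairs, 8, 12, rng_seed = 5)
  y_before <- ds$y
  nds <- normalize_dataset(ds)
  all_x <- unlist(nds$x)
  expect_equal(mean(all_x), 0, tolerance = 1e-6)
  expect_equal(sqrt(mean(all_x^2)), 1, tolerance = 1e-6)
  expect_identical(nds$y, y_before)

  renorm <- normalize_dataset(nds)
  expect_equal(unlist(renorm$x), all_x, tolerance = 1e-6)

  # two-patch toy set against explicit arithmetic
  toy <- structure(list(x = list(matrix(c(1, 2, 3, 4), 2),
                                 matrix(c(5, 6, 7, 8), 2)),
                        y = list(matrix(0, 2, 2), matrix(0, 2, 2)),
                        split = factor(c("train", "train"),
                                       levels = c("train", "val", "test")),
                        patch_size = 2L, norm_mean = NA_real_,
                        norm_std = NA_real_, rng_seed = 1L, meta = list()),
                   class = "patch_dataset")
  m <- mean(1:8)
  s <- sqrt(mean((1:8 - m)^2))
  tn <- normalize_dataset(toy)
  expect_equal(tn$norm_mean, m)
  expect_equal(tn$norm_std, s)
  expect_equal(tn$x[[1]], (matrix(c(1, 2, 3, 4), 2) - m) / s,
               tolerance = 1e-12)

  const <- toy
  const$x <- list(matrix(2, 2, 2), matrix(2, 2, 2))
  expect_error(normalize_dataset(const), "constant")
})

test_that("y_scale rescales targets only", {
  pairs <- make_tiny_pairs(n = 1, size = 24)
  a <- build_patch_dataset(pairs, 8, 6, rng_seed = 2, y_scale = 1)
  b <- build_patch_dataset(pairs, 8, 6, rng_seed = 2, y_scale = 1 / 1000)
  expect_identical(a$x, b$x)
  expect_equal(b$y[[1]], a$y[[1]] / 1000, tolerance = 1e-15)
})

test_that("dataset bundles round-trip bit-exactly and reject truncation", {
  pairs <- make_tiny_pairs(n = 2, size = 24)
  ds <- normalize_dataset(build_patch_dataset(pairs, 8, 7, rng_seed = 4))
  dir <- file.path(tempdir(), "bundle-test")
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(back$x, ds$x)
  expect_identical(back$y, ds$y)
  expect_identical(back$split, ds$split)
  expect_equal(back$norm_mean, ds$norm_mean)
  expect_equal(back$norm_std, ds$norm_std)

  # truncate the x blob -> parse error naming the file
  xbin <- file.path(dir, "x.bin")
  sz <- file.size(xbin)
  con <- file(xbin, "r+b"); truncate_at <- sz - 16
  raw <- readBin(con, "raw", truncate_at); close(con)
  writeBin(raw, xbin)
  expect_error(read_dataset(dir), "x.bin")
  expect_error(read_dataset(tempfile()), "meta.json")
})
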