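# Independent brute-force oracles: explicit nested loops, no shared code
# with the package implementations they check.

oracle_gaussian_kernel <- function(size, sigma) {
  r <- (size - 1) / 2
  w <- matrix(0, size, size)
  for (i in 1:size) {
    for (j in 1:size) {
      w[i, j] <- exp(-(((i - 1 - r)^2) + ((j - 1 - r)^2)) / (2 * sigma^2))
    }
  }
  w / sum(w)
}

# zero-padded same-size correlation with an odd kernel, pure loops
oracle_conv_same <- function(img, kw) {
  H <- nrow(img); W <- ncol(img); r <- (nrow(kw) - 1) / 2
  out <- matrix(0, H, W)
  for (i in 1:H) {
    for (j in 1:W) {
      acc <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
            acc <- acc + kw[di + r + 1, dj + r + 1] * img[ii, jj]
          }
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

oracle_l1l2 <- function(preds, truths, lam, size = 3, sigma = 1) {
  kw <- oracle_gaussian_kernel(size, sigma)
  vals <- numeric(length(preds))
  for (n in seq_along(preds)) {
    d <- oracle_conv_same(preds[[n]], kw) - oracle_conv_same(truths[[n]], kw)
    sq <- 0
    for (v in d) sq <- sq + v * v
    l1 <- 0
    for (v in preds[[n]]) l1 <- l1 + abs(v)
    vals[n] <- (lam / 2) * sq + l1
  }
  mean(vals)
}

oracle_ail <- function(students, teachers, truths, lam, alpha, phi, mode,
                       size = 3, sigma = 1) {
  kw <- oracle_gaussian_kernel(size, sigma)
  vals <- numeric(length(students))
  for (n in seq_along(students)) {
    bs <- oracle_conv_same(students[[n]], kw)
    bt <- oracle_conv_same(teachers[[n]], kw)
    bx <- oracle_conv_same(truths[[n]], kw)
    l1 <- sum(abs(students[[n]]))
    own <- (lam / 2) * sum((bs - bx)^2) + l1
    imit_sq <- if (mode == "as_printed") sum((bt - bx)^2) else sum((bs - bt)^2)
    imit <- (lam / 2) * imit_sq + l1
    vals[n] <- alpha * own + (1 - alpha) * phi * imit
  }
  mean(vals)
}

oracle_hint_mse <- function(a, b) {
  tot <- 0; n <- 0
  for (i in seq_along(a)) {
    for (v in (a[[i]] - b[[i]])) {
      tot <- tot + v * v
      n <- n + 1
    }
  }
  tot / n
}

oracle_nmse_printed <- function(pred, truth) {
  num <- 0; den <- 0
  for (i in seq_along(pred)) {
    num <- num + (pred[i] - truth[i])^2
    den <- den + truth[i]^2
  }
  num / sqrt(den)
}

# windowed SSIM over all fully interior windows, explicit loops
oracle_ssim_uniform <- function(pred, truth, win, data_range) {
  r <- (win - 1) / 2
  H <- nrow(pred); W <- ncol(pred)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  vals <- c()
  for (i in (1 + r):(H - r)) {
    for (j in (1 + r):(W - r)) {
      px <- pred[(i - r):(i + r), (j - r):(j + r)]
      tx <- truth[(i - r):(i + r), (j - r):(j + r)]
      mx <- mean(px); my <- mean(tx)
      vx <- mean(px^2) - mx^2; vy <- mean(tx^2) - my^2
      cxy <- mean(px * tx) - mx * my
      vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                  ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  }
  mean(vals)
}

rand_img <- function(H, W, seed) {
  withr::with_seed(seed, matrix(rnorm(H * W), H, W))
}

# small rendered pair list for dataset tests
make_tiny_pairs <- function(n = 2, size = 24, density = 13, seed = 7) {
  lapply(seq_len(n), function(i) {
    fld <- simulate_emitter_field(size, size, 0.1, density,
                                  rng_seed = seed + i)
    render_pair(fld, rng_seed = seed + 100 + i)
  })
}
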