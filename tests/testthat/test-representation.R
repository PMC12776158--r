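test_that("pooled features have dimension 32 and are deterministic", {
  m <- build_srcnn(4)
  patches <- lapply(1:4, function(s) rand_img(16, 16, s))
  fs <- extract_features(m, patches)
  expect_equal(dim(fs$features), c(4, 32))
  expect_identical(extract_features(m, patches)$features, fs$features)
  # per-channel global average pooling: row equals channel means by hand
  h <- forward_hint(m, patches[[1]])
  expect_equal(fs$features[1, ], apply(h, 3, mean), tolerance = 1e-12)

  fl <- extract_features(m, patches, pooling = "flatten_stride", stride = 8)
  expect_equal(ncol(fl$features), 2 * 2 * 32)
})

test_that("pairwise distances satisfy metric axioms and match loops", {
  m1 <- build_srcnn(1)
  m2 <- build_srcnn(2)
  patches <- lapply(1:5, function(s) rand_img(16, 16, 10 + s))
  a <- extract_features(m1, patches)
  b <- extract_features(m2, patches)
  expect_equal(pairwise_distances(a, a), rep(0, 5))
  d_ab <- pairwise_distances(a, b)
  expect_equal(d_ab, pairwise_distances(b, a), tolerance = 1e-15)
  loops <- vapply(1:5, function(i) {
    s <- 0
    for (j in 1:32) s <- s + (a$features[i, j] - b$features[i, j])^2
    sqrt(s)
  }, numeric(1))
  expect_equal(d_ab, loops, tolerance = 1e-12)

  # unit basis step -> all distances 1
  u <- a
  u$features <- a$features
  u$features[, 1] <- u$features[, 1] + 1
  expect_equal(pairwise_distances(a, u), rep(1, 5), tolerance = 1e-12)

  misaligned <- b
  misaligned$ids <- rev(b$ids)
  expect_error(pairwise_distances(a, misaligned), "misaligned")
})

test_that("distance shift summary reports hint-minus-plain", {
  d <- c(1, 2, 3)
  s0 <- distance_shift_summary(d, d)
  expect_equal(s0$shift$mean, 0)
  s1 <- distance_shift_summary(d - 1, d)
  expect_equal(s1$shift$mean, -1)
  expect_equal(s1$shift$median, -1)
})

test_that("PCA embedding keeps label bookkeeping lossless", {
  m1 <- build_srcnn(1); m1$name <- "A"
  m2 <- build_srcnn(2); m2$name <- "B"
  m3 <- build_drlstorm(3); m3$name <- "C"
  m4 <- build_drlstorm(4); m4$name <- "D"
  patches <- lapply(1:6, function(s) rand_img(16, 16, 20 + s))
  sets <- lapply(list(m1, m2, m3, m4), extract_features, patches = patches)
  emb <- embed_models(sets, method = "pca")
  expect_equal(nrow(emb), 24)
  expect_equal(as.numeric(table(emb$model)[c("A", "B", "C", "D")]),
               rep(6, 4))
  expect_identical(embed_models(sets, method = "pca"), emb)

  # duplicated feature set under two labels: centroids coincide
  dup <- sets[[1]]
  dup$model <- "A2"
  emb2 <- embed_models(list(sets[[1]], dup, sets[[3]]), method = "pca")
  cA <- colMeans(emb2[emb2$model == "A", c("u1", "u2")])
  cA2 <- colMeans(emb2[emb2$model == "A2", c("u1", "u2")])
  cC <- colMeans(emb2[emb2$model == "C", c("u1", "u2")])
  expect_equal(unname(cA), unname(cA2), tolerance = 1e-10)
  spread <- sqrt(sum((cA - cC)^2))
  expect_gt(spread, sqrt(sum((cA - cA2)^2)))

  bad <- sets[[2]]
  bad$features <- bad$features[, 1:10]
  expect_error(embed_models(list(sets[[1]], bad)), "dimension mismatch")
})

test_that("UMAP embedding runs seeded through the python bridge", {
  m1 <- build_srcnn(1); m1$name <- "A"
  m2 <- build_drlstorm(2); m2$name <- "B"
  patches <- lapply(1:10, function(s) rand_img(16, 16, 30 + s))
  sets <- lapply(list(m1, m2), extract_features, patches = patches)
  emb <- embed_models(sets, method = "umap", n_neighbors = 5, seed = 7)
  expect_equal(nrow(emb), 20)
  expect_true(all(is.finite(emb$u1)))
  expect_equal(sort(unique(emb$model)), c("A", "B"))
})
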