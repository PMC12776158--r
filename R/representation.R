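#' Extract pooled hint-layer features
#'
#' Runs the model body on each patch and reduces the H x W x 32 hint
#' representation to a fixed-length vector: per-channel global average
#' pooling by default (d = 32), or a strided flatten that keeps every
#' `stride`-th pixel of every channel.
#'
#' @param model a `factorized_model`.
#' @param patches list of H x W matrices (normalized inputs).
#' @param pooling `"mean"` or `"flatten_stride"`.
#' @param stride subsampling stride for `"flatten_stride"`.
#' @param ids patch identifiers (default sequential).
#' @return object of class `feature_set`: list with `model`, `features`
#'   (n x d matrix) and `ids`.
#' @export
extract_features <- function(model, patches, pooling = c("mean",
                                                         "flatten_stride"),
                             stride = 8L, ids = seq_along(patches)) {
  pooling <- match.arg(pooling)
  if (is.matrix(patches)) patches <- list(patches)
  stopifnot(length(ids) == length(patches))
  feats <- lapply(patches, function(p) {
    h <- forward_hint(model, p)
    if (pooling == "mean") {
      apply(h, 3L, mean)
    } else {
      ri <- seq(1L, dim(h)[1], by = stride)
      ci <- seq(1L, dim(h)[2], by = stride)
      as.numeric(h[ri, ci, ])
    }
  })
  structure(list(model = model$name, features = do.call(rbind, feats),
                 ids = ids),
            class = "feature_set")
}

#' Jointly embed feature sets in 2-D
#'
#' Stacks the feature vectors of several models and embeds them together
#' into two dimensions, preserving the model label of every row, so that
#' the hint-layer representations of different models can be compared as
#' clusters. `method = "umap"` calls the Python `umap-learn` implementation
#' (seeded) through a subprocess; `method = "pca"` uses the first two
#' principal components, a fully deterministic in-process alternative.
#'
#' @param feature_sets list of >= 2 `feature_set`s with a common dimension.
#' @param method `"umap"` or `"pca"`.
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @param seed integer seed for the embedding.
#' @param python path to the Python interpreter used for UMAP.
#' @return data frame with columns `patch_id`, `model`, `u1`, `u2`; the
#'   embedding settings are attached as the `"embed_config"` attribute.
#' @export
embed_models <- function(feature_sets, method = c("umap", "pca"),
                         n_neighbors = 15L, min_dist = 0.1, seed = 42L,
                         python = "python") {
  method <- match.arg(method)
  stopifnot(length(feature_sets) >= 2L)
  d <- ncol(feature_sets[[1]]$features)
  for (fs in feature_sets) {
    if (ncol(fs$features) != d) {
      stop("feature dimension mismatch: ", ncol(fs$features), " vs ", d)
    }
  }
  X <- do.call(rbind, lapply(feature_sets, function(fs) fs$features))
  labels <- unlist(lapply(feature_sets,
                          function(fs) rep(fs$model, nrow(fs$features))))
  ids <- unlist(lapply(feature_sets, function(fs) fs$ids))
  if (method == "pca") {
    # rank-2 PCA with deterministic sign convention
    pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = 2L)
    emb <- pc$x[, 1:2, drop = FALSE]
    for (j in 1:2) if (sum(pc$rotation[, j]) < 0) emb[, j] <- -emb[, j]
  } else {
    emb <- run_umap_subprocess(X, n_neighbors, min_dist, seed, python)
  }
  out <- data.frame(patch_id = ids, model = labels,
                    u1 = emb[, 1], u2 = emb[, 2])
  attr(out, "embed_config") <- list(method = method,
                                    n_neighbors = n_neighbors,
                                    min_dist = min_dist, seed = seed)
  out
}

run_umap_subprocess <- function(X, n_neighbors, min_dist, seed, python) {
  tin <- tempfile(fileext = ".csv"); tout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(tin, tout)), add = TRUE)
  utils::write.table(X, tin, sep = ",", row.names = FALSE, col.names = FALSE)
  script <- paste(
    "import sys, numpy as np, umap",
    "X = np.loadtxt(sys.argv[1], delimiter=',', ndmin=2)",
    sprintf(paste0("e = umap.UMAP(n_neighbors=%d, min_dist=%s, ",
                   "random_state=%d).fit_transform(X)"),
            as.integer(n_neighbors), format(min_dist), as.integer(seed)),
    "np.savetxt(sys.argv[2], e, delimiter=',')",
    sep = "\n")
  status <- system2(python, c("-c", shQuote(script), shQuote(tin),
                              shQuote(tout)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(tout)) {
    stop("UMAP subprocess failed (is Python with umap-learn on the PATH?); ",
         "consider method = 'pca'")
  }
  as.matrix(utils::read.table(tout, sep = ","))
}

#' Matched pairwise feature distances
#'
#' Euclidean distance between the feature vectors of two models for each
#' common input patch (sets must carry aligned patch identifiers).
#'
#' @param set_a,set_b `feature_set`s over the same patches.
#' @return numeric vector of per-patch distances.
#' @export
pairwise_distances <- function(set_a, set_b) {
  if (!identical(set_a$ids, set_b$ids)) {
    stop("misaligned patch identifiers between feature sets")
  }
  if (ncol(set_a$features) != ncol(set_b$features)) {
    stop("feature dimension mismatch")
  }
  sqrt(rowSums((set_a$features - set_b$features)^2))
}

#' Summary of the distance shift between two distillation variants
#'
#' Compares the teacher-distance distributions of a hint-learned student
#' and a plain student: negative shifts mean the hint-learned student's
#' features sit closer to the teacher's.
#'
#' @param dist_hint distances teacher vs hint-learned student.
#' @param dist_plain distances teacher vs plain student.
#' @return list with per-vector means/medians and `shift` (list with
#'   `mean` and `median`, each hint minus plain).
#' @export
distance_shift_summary <- function(dist_hint, dist_plain) {
  stopifnot(length(dist_hint) > 0L, length(dist_plain) > 0L)
  list(mean_hint = mean(dist_hint), mean_plain = mean(dist_plain),
       median_hint = median(dist_hint), median_plain = median(dist_plain),
       shift = list(mean = mean(dist_hint) - mean(dist_plain),
                    median = median(dist_hint) - median(dist_plain)))
}
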