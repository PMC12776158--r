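#' Build a patch dataset from rendered image pairs
#'
#' Draws `patches_per_image` random patches (uniform offsets, with
#' replacement, so patches may overlap) from each diffraction-limited /
#' ground-truth pair, cropping X and Y at identical offsets, and assigns
#' every patch independently to train / val / test by a categorical draw
#' with `split_probs`. `y_scale` optionally rescales the ground-truth
#' patches (e.g. to express spike amplitudes in units of the nominal photon
#' count so loss magnitudes are O(1)); the rendered pairs themselves are
#' never modified.
#'
#' @param pairs list of `image_pair` objects (see [render_pair()]).
#' @param patch_size square patch side in pixels; must not exceed either
#'   image dimension.
#' @param patches_per_image number of random patches per source pair.
#' @param split_probs length-3 probabilities for (train, val, test); must
#'   sum to 1.
#' @param rng_seed integer seed; offsets and split labels are deterministic
#'   given the seed.
#' @param y_scale multiplicative factor applied to Y patches (default 1).
#' @return object of class `patch_dataset`: lists `x` and `y` of
#'   `patch_size x patch_size` matrices, a factor `split`, normalization
#'   stats (`norm_mean`, `norm_std`, `NA` until [normalize_dataset()]), the
#'   seed, and a `meta` list.
#' @export
build_patch_dataset <- function(pairs, patch_size, patches_per_image,
                                split_probs = c(train = 0.8, val = 0.1,
                                                test = 0.1),
                                rng_seed = 1L, y_scale = 1) {
  if (inherits(pairs, "image_pair")) pairs <- list(pairs)
  stopifnot(length(pairs) >= 1L, patches_per_image >= 0L)
  if (abs(sum(split_probs) - 1) > 1e-8) stop("split_probs must sum to 1")
  patch_size <- as.integer(patch_size)
  for (p in pairs) {
    if (patch_size > nrow(p$x_dl) || patch_size > ncol(p$x_dl)) {
      stop("patch_size (", patch_size, ") exceeds an image dimension (",
           nrow(p$x_dl), "x", ncol(p$x_dl), ")")
    }
  }
  levels3 <- c("train", "val", "test")
  xs <- list(); ys <- list(); split <- character(0)
  withr::with_seed(rng_seed, {
    for (p in pairs) {
      H <- nrow(p$x_dl); W <- ncol(p$x_dl)
      if (patches_per_image == 0L) next
      r0 <- sample.int(H - patch_size + 1L, patches_per_image, replace = TRUE)
      c0 <- sample.int(W - patch_size + 1L, patches_per_image, replace = TRUE)
      lab <- sample(levels3, patches_per_image, replace = TRUE,
                    prob = split_probs)
      for (k in seq_len(patches_per_image)) {
        ri <- r0[k]:(r0[k] + patch_size - 1L)
        ci <- c0[k]:(c0[k] + patch_size - 1L)
        xs[[length(xs) + 1L]] <- p$x_dl[ri, ci]
        ys[[length(ys) + 1L]] <- p$y_gt[ri, ci] * y_scale
      }
      split <- c(split, lab)
    }
  })
  structure(list(x = xs, y = ys,
                 split = factor(split, levels = levels3),
                 patch_size = patch_size,
                 norm_mean = NA_real_, norm_std = NA_real_,
                 rng_seed = as.integer(rng_seed),
                 meta = list(n_source_images = length(pairs),
                             patches_per_image = patches_per_image,
                             split_probs = as.numeric(split_probs),
                             y_scale = y_scale)),
            class = "patch_dataset")
}

#' Z-score the input patches of a dataset
#'
#' Replaces every X patch by `(x - m) / s` where `m` and `s` are the mean
#' and standard deviation pooled over all X patches of the entire dataset
#' (all splits). Y patches are untouched. The stats are stored on the
#' dataset for inference-time reuse on new frames. Renormalizing an
#' already-normalized dataset recomputes (near-zero, near-one) stats, so the
#' operation is idempotent up to floating point.
#'
#' @param dataset a `patch_dataset`.
#' @return the dataset with normalized X patches and `norm_mean`,
#'   `norm_std` filled in.
#' @export
normalize_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "patch_dataset"))
  if (length(dataset$x) == 0L) stop("dataset is empty")
  all_x <- unlist(dataset$x, use.names = FALSE)
  m <- mean(all_x)
  n <- length(all_x)
  s <- sqrt(sum((all_x - m)^2) / n)  # population sd over the pooled pixels
  if (s <= 0) stop("zero pooled standard deviation: constant dataset")
  dataset$x <- lapply(dataset$x, function(p) (p - m) / s)
  dataset$norm_mean <- m
  dataset$norm_std <- s
  dataset
}

#' Extract one split of a patch dataset
#'
#' @param dataset a `patch_dataset`.
#' @param which `"train"`, `"val"` or `"test"`.
#' @return list with `x`, `y` (patch lists) and `index` (positions in the
#'   full dataset, usable as patch identifiers).
#' @export
dataset_split <- function(dataset, which = c("train", "val", "test")) {
  which <- match.arg(which)
  idx <- which(dataset$split == which)
  list(x = dataset$x[idx], y = dataset$y[idx], index = idx)
}

#' Persist / load a patch dataset bundle
#'
#' Writes the dataset to a directory: `meta.json` (patch size, splits,
#' normalization stats, seed, generation metadata), `labels.csv` (one row
#' per patch), and raw little-endian doubles `x.bin` / `y.bin`
#' (patch-major, column-major within a patch), so the round trip is
#' bit-exact.
#'
#' @param dataset a `patch_dataset`.
#' @param path directory to create/fill.
#' @return `read_dataset()` returns the reconstructed `patch_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "patch_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset$x)
  meta <- list(n_patches = n, patch_size = dataset$patch_size,
               norm_mean = dataset$norm_mean, norm_std = dataset$norm_std,
               rng_seed = dataset$rng_seed, meta = dataset$meta)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  utils::write.csv(data.frame(patch = seq_len(n),
                              split = as.character(dataset$split)),
                   file.path(path, "labels.csv"), row.names = FALSE)
  for (nm in c("x", "y")) {
    con <- file(file.path(path, paste0(nm, ".bin")), "wb")
    writeBin(unlist(dataset[[nm]], use.names = FALSE), con, size = 8,
             endian = "little")
    close(con)
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("not a dataset bundle: missing meta.json")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  n <- meta$n_patches
  ps <- meta$patch_size
  labels <- utils::read.csv(file.path(path, "labels.csv"))
  if (nrow(labels) != n) {
    stop("malformed bundle: labels.csv has ", nrow(labels),
         " rows, meta.json promises ", n)
  }
  read_patches <- function(nm) {
    f <- file.path(path, paste0(nm, ".bin"))
    expect <- n * ps * ps
    if (!file.exists(f) || file.size(f) != expect * 8) {
      stop("malformed bundle: ", nm, ".bin is truncated or missing (",
           "expected ", expect * 8, " bytes)")
    }
    con <- file(f, "rb")
    vals <- readBin(con, numeric(), n = expect, size = 8, endian = "little")
    close(con)
    lapply(seq_len(n), function(i) {
      matrix(vals[((i - 1) * ps * ps + 1):(i * ps * ps)], ps, ps)
    })
  }
  structure(list(x = read_patches("x"), y = read_patches("y"),
                 split = factor(labels$split,
                                levels = c("train", "val", "test")),
                 patch_size = as.integer(ps),
                 norm_mean = if (is.null(meta$norm_mean)) NA_real_ else meta$norm_mean,
                 norm_std = if (is.null(meta$norm_std)) NA_real_ else meta$norm_std,
                 rng_seed = as.integer(meta$rng_seed),
                 meta = meta$meta),
            class = "patch_dataset")
}
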