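#' Normalized mean square error
#'
#' In the default `"printed"` convention the value is
#' \eqn{\lVert\hat{x}-x\rVert_2^2 / \lVert x\rVert_2} — squared error over
#' the *unsquared* norm of the truth; the `"standard"` mode divides by
#' \eqn{\lVert x\rVert_2^2} instead. Values are returned as fractions
#' (multiply by 100 to render percent).
#'
#' @param pred,truth equally-shaped numeric matrices.
#' @param mode `"printed"` (default) or `"standard"`.
#' @return nonnegative scalar.
#' @export
nmse <- function(pred, truth, mode = c("printed", "standard")) {
  mode <- match.arg(mode)
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  denom <- sqrt(sum(truth^2))
  if (denom == 0) stop("zero-norm ground truth: NMSE undefined")
  err <- sum((pred - truth)^2)
  if (mode == "printed") err / denom else err / denom^2
}

#' Structural similarity index (SSIM)
#'
#' Windowed SSIM with stabilizing constants \eqn{C_1 = (0.01 R)^2},
#' \eqn{C_2 = (0.03 R)^2} for data range \eqn{R}, averaged over all fully
#' interior windows. The default window is a 7x7 uniform average; a
#' Gaussian-weighted window is available.
#'
#' @param pred,truth equally-shaped numeric matrices.
#' @param window odd window side (default 7).
#' @param data_range intensity range \eqn{R}; defaults to
#'   `max(truth) - min(truth)`, falling back to the prediction's range and
#'   then to 1 when degenerate.
#' @param gaussian use a Gaussian-weighted window (sd = 1.5) instead of
#'   uniform.
#' @return scalar in \[-1, 1\].
#' @export
ssim <- function(pred, truth, window = 7L, data_range = NULL,
                 gaussian = FALSE) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window > min(dim(pred))) {
    stop("window (", window, ") larger than image (",
         paste(dim(pred), collapse = "x"), ")")
  }
  if (is.null(data_range)) {
    data_range <- max(truth) - min(truth)
    if (data_range == 0) data_range <- max(pred) - min(pred)
    if (data_range == 0) data_range <- 1
  }
  if (data_range <= 0) stop("data_range must be positive")
  if (gaussian) {
    k <- make_gaussian_kernel(window, 1.5)
  } else {
    k <- list(size = window,
              weights = matrix(1 / window^2, window, window))
    class(k) <- "gaussian_kernel"
  }
  r <- (window - 1L) / 2L
  H <- nrow(pred); W <- ncol(pred)
  interior <- function(m) m[(r + 1):(H - r), (r + 1):(W - r), drop = FALSE]
  mu_x <- interior(blur2(pred, k))
  mu_y <- interior(blur2(truth, k))
  xx <- interior(blur2(pred * pred, k)) - mu_x^2
  yy <- interior(blur2(truth * truth, k)) - mu_y^2
  xy <- interior(blur2(pred * truth, k)) - mu_x * mu_y
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  s <- ((2 * mu_x * mu_y + c1) * (2 * xy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (xx + yy + c2))
  mean(s)
}

#' Evaluate a model on a dataset split
#'
#' Runs the model over every patch of the given split (inputs are already
#' in the dataset's normalized units) and collects per-patch NMSE and SSIM
#' against the ground-truth patches, plus summary statistics. Patches whose
#' ground truth is identically zero are dropped with a warning (NMSE is
#' undefined there).
#'
#' @param model a `factorized_model`, or any function taking and returning
#'   an H x W matrix (useful for stub oracles).
#' @param dataset a normalized `patch_dataset`.
#' @param split `"train"`, `"val"` or `"test"`.
#' @param nmse_mode,ssim_window,ssim_gaussian metric settings, see [nmse()]
#'   and [ssim()].
#' @return object of class `metrics_report`: list with `model`, `split`,
#'   vectors `nmse` and `ssim`, and a `summary` data frame.
#' @export
evaluate <- function(model, dataset, split = "test", nmse_mode = "printed",
                     ssim_window = 7L, ssim_gaussian = FALSE) {
  check_dataset_ready(dataset, need_val = FALSE)
  sp <- dataset_split(dataset, split)
  if (length(sp$x) == 0L) stop("split '", split, "' is empty")
  fwd <- if (is.function(model)) model else function(x) model_forward(model, x)
  keep <- vapply(sp$y, function(y) sum(y^2) > 0, logical(1))
  if (!all(keep)) {
    warning(sum(!keep), " patch(es) with all-zero ground truth dropped")
  }
  xs <- sp$x[keep]; ys <- sp$y[keep]; ids <- sp$index[keep]
  nm <- numeric(length(xs)); ss <- numeric(length(xs))
  for (i in seq_along(xs)) {
    p <- fwd(xs[[i]])
    nm[i] <- nmse(p, ys[[i]], mode = nmse_mode)
    ss[i] <- ssim(p, ys[[i]], window = ssim_window, gaussian = ssim_gaussian)
  }
  model_name <- if (is.function(model)) "stub" else model$name
  summarize <- function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    c(mean = mean(v), q25 = q[1], median = q[2], q75 = q[3])
  }
  structure(list(model = model_name, split = split, patch_index = ids,
                 nmse = nm, ssim = ss,
                 summary = data.frame(metric = c("nmse", "ssim"),
                                      rbind(summarize(nm), summarize(ss)))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Metrics for", x$model, "on", x$split, "split (",
      length(x$nmse), "patches )\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Intensity cross-profile along a line segment
#'
#' Samples image intensity at `n_samples` evenly spaced points along the
#' segment from `start_px` to `end_px` (x = column, y = row, 1-based pixel
#' centers) using bilinear interpolation; the standard way to compare
#' apparent feature widths between reconstructions.
#'
#' @param image numeric matrix.
#' @param start_px,end_px numeric length-2 vectors `c(x, y)` inside the
#'   image.
#' @param n_samples number of samples (>= 2).
#' @return numeric vector of interpolated intensities.
#' @export
cross_profile <- function(image, start_px, end_px, n_samples = 100L) {
  H <- nrow(image); W <- ncol(image)
  pts <- rbind(start_px, end_px)
  if (any(pts[, 1] < 1 | pts[, 1] > W | pts[, 2] < 1 | pts[, 2] > H)) {
    stop("segment endpoints must lie inside the image")
  }
  t <- seq(0, 1, length.out = n_samples)
  xs <- start_px[1] + t * (end_px[1] - start_px[1])
  ys <- start_px[2] + t * (end_px[2] - start_px[2])
  x0 <- pmin(pmax(floor(xs), 1L), W - 1L); y0 <- pmin(pmax(floor(ys), 1L), H - 1L)
  fx <- xs - x0; fy <- ys - y0
  v00 <- image[cbind(y0, x0)]
  v01 <- image[cbind(y0, x0 + 1L)]
  v10 <- image[cbind(y0 + 1L, x0)]
  v11 <- image[cbind(y0 + 1L, x0 + 1L)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}
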