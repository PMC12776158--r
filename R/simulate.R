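#' Photon-count models for simulated emitters
#'
#' `photon_model_fixed()` gives every emitter the same photon count (the
#' default, 1000 photons, a typical bright-fluorophore budget);
#' `photon_model_lognormal()` draws counts from a lognormal, the usual shape
#' of measured single-molecule brightness distributions.
#'
#' @param photons fixed photon count (> 0).
#' @param meanlog,sdlog lognormal parameters on the log scale.
#' @return a photon model object consumed by [simulate_emitter_field()].
#' @export
photon_model_fixed <- function(photons = 1000) {
  stopifnot(photons > 0)
  structure(list(type = "fixed", photons = photons), class = "photon_model")
}

#' @rdname photon_model_fixed
#' @export
photon_model_lognormal <- function(meanlog = log(1000), sdlog = 0.5) {
  structure(list(type = "lognormal", meanlog = meanlog, sdlog = sdlog),
            class = "photon_model")
}

draw_photons <- function(model, n) {
  if (n == 0L) return(numeric(0))
  switch(model$type,
         fixed = rep(model$photons, n),
         lognormal = rlnorm(n, model$meanlog, model$sdlog),
         stop("unknown photon model type: ", model$type))
}

#' Construct / validate an emitter field
#'
#' An `emitter_field` holds ground-truth fluorophore positions (continuous,
#' in pixel units, origin at the field corner) and photon counts on a
#' physical grid of `width_px x height_px` pixels of side `pixel_size_um`
#' micrometers.
#'
#' @param width_px,height_px field size in pixels (>= 1).
#' @param pixel_size_um pixel side length in micrometers (> 0).
#' @param x_px,y_px,photons emitter coordinates (in \[0, width) and
#'   \[0, height)) and photon counts (> 0).
#' @return object of class `emitter_field`.
#' @export
emitter_field <- function(width_px, height_px, pixel_size_um,
                          x_px = numeric(0), y_px = numeric(0),
                          photons = numeric(0)) {
  width_px <- as.integer(width_px); height_px <- as.integer(height_px)
  if (width_px < 1L || height_px < 1L) stop("field dimensions must be >= 1")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (length(x_px) != length(y_px) || length(x_px) != length(photons)) {
    stop("x_px, y_px and photons must have equal length")
  }
  if (any(x_px < 0 | x_px >= width_px) || any(y_px < 0 | y_px >= height_px)) {
    stop("emitter positions must lie inside the field")
  }
  if (any(photons <= 0)) stop("photon counts must be positive")
  structure(list(width_px = width_px, height_px = height_px,
                 pixel_size_um = pixel_size_um,
                 x_px = as.numeric(x_px), y_px = as.numeric(y_px),
                 photons = as.numeric(photons)),
            class = "emitter_field")
}

#' Simulate a random emitter field at a given density
#'
#' Draws a Poisson number of emitters with mean `density_per_um2` times the
#' field area in square micrometers, places them uniformly over the field and
#' assigns photon counts from `photon_model`. Dense-emitter STORM conditions
#' correspond to densities around 13 emitters per square micrometer, sparse
#' ones to about 5.
#'
#' @inheritParams emitter_field
#' @param density_per_um2 expected emitters per square micrometer (>= 0).
#' @param photon_model see [photon_model_fixed()].
#' @param rng_seed integer seed; the draw is deterministic given the seed.
#' @return an `emitter_field`.
#' @export
simulate_emitter_field <- function(width_px, height_px, pixel_size_um = 0.1,
                                   density_per_um2,
                                   photon_model = photon_model_fixed(),
                                   rng_seed = 1L) {
  if (width_px < 1 || height_px < 1) stop("field dimensions must be >= 1")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (density_per_um2 < 0) stop("density_per_um2 must be nonnegative")
  area_um2 <- width_px * height_px * pixel_size_um^2
  withr::with_seed(rng_seed, {
    n <- rpois(1L, density_per_um2 * area_um2)
    x <- runif(n, 0, width_px)
    y <- runif(n, 0, height_px)
    p <- draw_photons(photon_model, n)
  })
  # runif can in principle return the upper bound; clamp into [0, w)
  x <- pmin(x, width_px * (1 - 1e-12))
  y <- pmin(y, height_px * (1 - 1e-12))
  emitter_field(width_px, height_px, pixel_size_um, x, y, p)
}

# pixel-integrated Gaussian PSF: photons deposited in pixel (r, c) are the
# product of error-function differences along each axis
render_ideal_image <- function(field, psf_sigma_px) {
  H <- field$height_px; W <- field$width_px
  img <- matrix(0, H, W)
  if (length(field$x_px) == 0L) return(img)
  r <- ceiling(4 * psf_sigma_px)
  for (e in seq_along(field$x_px)) {
    x <- field$x_px[e]; y <- field$y_px[e]; p <- field$photons[e]
    # pixel (row i, col j), 1-based, covers [i-1, i) x [j-1, j)
    i0 <- max(1L, floor(y) + 1L - r); i1 <- min(H, floor(y) + 1L + r)
    j0 <- max(1L, floor(x) + 1L - r); j1 <- min(W, floor(x) + 1L + r)
    rows <- i0:i1; cols <- j0:j1
    fy <- pnorm(rows, mean = y, sd = psf_sigma_px) -
      pnorm(rows - 1, mean = y, sd = psf_sigma_px)
    fx <- pnorm(cols, mean = x, sd = psf_sigma_px) -
      pnorm(cols - 1, mean = x, sd = psf_sigma_px)
    img[rows, cols] <- img[rows, cols] + p * outer(fy, fx)
  }
  img
}

#' Render a diffraction-limited / ground-truth image pair
#'
#' The diffraction-limited frame `x_dl` is the emitters' photon flux spread
#' by a pixel-integrated 2-D Gaussian point spread function, plus a uniform
#' background, with per-pixel Poisson shot noise (the dominant noise source
#' of an sCMOS/EMCCD frame at these signal levels); `noise_model = "none"`
#' returns the noiseless expectation for oracle tests. The ground truth
#' `y_gt` lives on the same pixel grid (magnification 1): each emitter's
#' photon count is deposited entirely in the pixel containing it, giving a
#' sparse spike image.
#'
#' @param field an `emitter_field`.
#' @param psf_sigma_px Gaussian PSF standard deviation in pixels (> 0).
#' @param background_level uniform background, mean counts per pixel (>= 0).
#' @param noise_model `"poisson"` or `"none"`.
#' @param rng_seed integer seed for the shot noise.
#' @return object of class `image_pair`: list with matrices `x_dl`, `y_gt`
#'   and the originating `field`.
#' @export
render_pair <- function(field, psf_sigma_px = 1.6, background_level = 200,
                        noise_model = c("poisson", "none"), rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(field, "emitter_field"))
  if (psf_sigma_px <= 0) stop("psf_sigma_px must be positive")
  if (background_level < 0) stop("background_level must be nonnegative")
  ideal <- render_ideal_image(field, psf_sigma_px) + background_level
  if (noise_model == "poisson") {
    x_dl <- withr::with_seed(rng_seed, {
      matrix(rpois(length(ideal), lambda = ideal), nrow(ideal), ncol(ideal))
    })
    x_dl <- x_dl * 1.0
  } else {
    x_dl <- ideal
  }
  y_gt <- matrix(0, field$height_px, field$width_px)
  if (length(field$x_px) > 0L) {
    rows <- floor(field$y_px) + 1L
    cols <- floor(field$x_px) + 1L
    for (e in seq_along(rows)) {
      y_gt[rows[e], cols[e]] <- y_gt[rows[e], cols[e]] + field$photons[e]
    }
  }
  structure(list(x_dl = x_dl, y_gt = y_gt, field = field),
            class = "image_pair")
}

#' Export / import a ThunderSTORM-style emitter list
#'
#' Writes the ground-truth emitter list as CSV with the header columns
#' `"id","frame","x [nm]","y [nm]","intensity [photon]"` (the localization
#' table format of the ThunderSTORM ImageJ plug-in), and reads such a file
#' back into an `emitter_field`.
#'
#' @param field an `emitter_field`.
#' @param path CSV file path.
#' @param frame frame index written to the `frame` column.
#' @export
write_thunderstorm_csv <- function(field, path, frame = 1L) {
  nm <- field$pixel_size_um * 1000
  df <- data.frame(
    id = seq_along(field$x_px),
    frame = rep(frame, length(field$x_px)),
    x_nm = field$x_px * nm,
    y_nm = field$y_px * nm,
    intensity = field$photons,
    check.names = FALSE
  )
  names(df) <- c("id", "frame", "x [nm]", "y [nm]", "intensity [photon]")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_thunderstorm_csv
#' @param width_px,height_px,pixel_size_um grid parameters of the field the
#'   localizations belong to (the CSV stores nanometer coordinates only).
#' @export
read_thunderstorm_csv <- function(path, width_px, height_px, pixel_size_um) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("id", "frame", "x [nm]", "y [nm]", "intensity [photon]")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("malformed emitter CSV, missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  nm <- pixel_size_um * 1000
  emitter_field(width_px, height_px, pixel_size_um,
                x_px = df[["x [nm]"]] / nm, y_px = df[["y [nm]"]] / nm,
                photons = df[["intensity [photon]"]])
}
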