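#' Discretized Gaussian smoothing kernel
#'
#' Builds the small Gaussian kernel used inside the sparse-reconstruction
#' losses: the squared-error term compares Gaussian-blurred images so that a
#' prediction is rewarded for placing intensity within a kernel-width of the
#' true emitter pixel rather than exactly on it. The kernel is an isotropic
#' Gaussian sampled at integer offsets from the center and normalized to unit
#' sum.
#'
#' @param size odd kernel side length (default 3).
#' @param sigma Gaussian standard deviation in pixels (default 1).
#' @return An object of class `gaussian_kernel`: a list with `size`, `sigma`
#'   and the `size x size` `weights` matrix (nonnegative, sums to 1).
#' @export
#' @examples
#' k <- make_gaussian_kernel(3, 1)
#' sum(k$weights) # 1
make_gaussian_kernel <- function(size = 3L, sigma = 1) {
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) {
    stop("`size` must be an odd positive integer, got ", size)
  }
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("`sigma` must be positive")
  }
  r <- (size - 1L) / 2L
  off <- seq(-r, r)
  w <- outer(off, off, function(i, j) exp(-(i^2 + j^2) / (2 * sigma^2)))
  w <- w / sum(w)
  structure(list(size = size, sigma = sigma, weights = w),
            class = "gaussian_kernel")
}

# Blur a single H x W image with the kernel (zero-padded, same-size output).
blur2 <- function(img, kernel) {
  x <- array(img, dim = c(nrow(img), ncol(img), 1L))
  w <- matrix(as.numeric(kernel$weights), ncol = 1L)
  out <- conv2d_fwd(x, w, 0, kernel$size)
  matrix(out, nrow(img), ncol(img))
}
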