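#' @title Factorized reconstruction networks
#' @description Both networks map a 1-channel H x W diffraction-limited
#'   image to a 1-channel H x W reconstruction (magnification 1, no net
#'   up-sampling) and are split into a *body* ending at a 32-channel hint
#'   representation and a single-convolution reconstruction *head*, so that
#'   hint-layer features can be compared and trained across models.
#' @name models
NULL

relu <- function(z) {
  z[z < 0] <- 0
  z
}

init_conv <- function(k, cin, cout, act = c("relu", "linear")) {
  act <- match.arg(act)
  fan_in <- k * k * cin
  gain <- if (act == "relu") 2 else 1
  list(W = matrix(rnorm(fan_in * cout, sd = sqrt(gain / fan_in)),
                  nrow = fan_in, ncol = cout),
       b = numeric(cout), k = as.integer(k),
       cin = as.integer(cin), cout = as.integer(cout))
}

new_factorized_model <- function(name, arch, params, body_params, head_params,
                                 cfg, seed) {
  structure(list(name = name, arch = arch, params = params,
                 body_params = body_params, head_params = head_params,
                 cfg = cfg, body_frozen = FALSE, seed = as.integer(seed)),
            class = "factorized_model")
}

#' Build the SRCNN student network
#'
#' A three-layer network: a 9x9 convolution from the input image to 64
#' feature channels (ReLU), a 1x1 convolution down to the 32-channel hint
#' representation (ReLU) — the body — and a 5x5 reconstruction convolution
#' back to one channel — the head. All convolutions are zero-padded to
#' preserve H x W. Weights use seeded Kaiming fan-in initialization.
#'
#' @param rng_seed integer seed for the weight draw.
#' @param name model label carried through reports.
#' @return a `factorized_model`.
#' @export
build_srcnn <- function(rng_seed = 1L, name = "SRCNN") {
  params <- withr::with_seed(rng_seed, list(
    conv1 = init_conv(9, 1, 64, "relu"),
    conv2 = init_conv(1, 64, 32, "relu"),
    head = init_conv(5, 32, 1, "linear")
  ))
  new_factorized_model(name, "srcnn", params,
                       body_params = c("conv1", "conv2"),
                       head_params = "head", cfg = list(), seed = rng_seed)
}

#' Build the DRL-STORM-style teacher network
#'
#' An encoder–decoder: three encoder stages of 3x3 convolution + ReLU
#' followed by 2x2 max-pooling (default widths 32, 64, 128), a skip
#' connection carrying the 1x1-projected input to the encoder output (added
#' after an 8x average-pool so the grids match; `skip_mode = "concat"`
#' concatenates instead), then three decoder stages of 2x up-sampling
#' (nearest-neighbour by default, `"smooth"` adds a fixed tent smoothing)
#' and 3x3 convolution + ReLU (default widths 64, 32, 32). The body ends at
#' the final 32-channel decoder convolution (the hint layer); the head is a
#' single 3x3 convolution to one channel. Input H and W must be divisible
#' by 8.
#'
#' @param rng_seed integer seed for the weight draw.
#' @param widths encoder channel widths (3 stages).
#' @param dec_widths decoder channel widths (3 stages); the last must be 32
#'   so the hint layer matches the student's.
#' @param skip_mode `"add"` or `"concat"`.
#' @param upsample `"nearest"` or `"smooth"`.
#' @param name model label.
#' @return a `factorized_model`.
#' @export
build_drlstorm <- function(rng_seed = 1L, widths = c(32, 64, 128),
                           dec_widths = c(64, 32, 32),
                           skip_mode = c("add", "concat"),
                           upsample = c("nearest", "smooth"),
                           name = "DRL-STORM") {
  skip_mode <- match.arg(skip_mode)
  upsample <- match.arg(upsample)
  stopifnot(length(widths) == 3L, length(dec_widths) == 3L)
  if (dec_widths[3] != 32L) {
    stop("the last decoder width must be 32 (the shared hint-layer width)")
  }
  mid <- if (skip_mode == "concat") 2L * widths[3] else widths[3]
  params <- withr::with_seed(rng_seed, list(
    enc1 = init_conv(3, 1, widths[1], "relu"),
    enc2 = init_conv(3, widths[1], widths[2], "relu"),
    enc3 = init_conv(3, widths[2], widths[3], "relu"),
    skip = init_conv(1, 1, widths[3], "linear"),
    dec1 = init_conv(3, mid, dec_widths[1], "relu"),
    dec2 = init_conv(3, dec_widths[1], dec_widths[2], "relu"),
    dec3 = init_conv(3, dec_widths[2], dec_widths[3], "relu"),
    head = init_conv(3, 32, 1, "linear")
  ))
  new_factorized_model(name, "drlstorm", params,
                       body_params = c("enc1", "enc2", "enc3", "skip",
                                       "dec1", "dec2", "dec3"),
                       head_params = "head",
                       cfg = list(widths = widths, dec_widths = dec_widths,
                                  skip_mode = skip_mode, upsample = upsample),
                       seed = rng_seed)
}

#' Count trainable parameters
#'
#' @param model a `factorized_model`.
#' @param which `"all"`, `"body"` or `"head"`.
#' @return integer parameter count (weights + biases).
#' @export
param_count <- function(model, which = c("all", "body", "head")) {
  which <- match.arg(which)
  nms <- switch(which, all = names(model$params),
                body = model$body_params, head = model$head_params)
  sum(vapply(model$params[nms],
             function(p) length(p$W) + length(p$b), numeric(1)))
}

conv_apply <- function(x, p) conv2d_fwd(x, p$W, p$b, p$k)

tent_smooth <- function(x) {
  t3 <- outer(c(0.25, 0.5, 0.25), c(0.25, 0.5, 0.25))
  w <- matrix(as.numeric(t3), ncol = 1L)
  out <- x
  for (c in seq_len(dim(x)[3])) {
    sl <- array(x[, , c], dim = c(dim(x)[1], dim(x)[2], 1L))
    out[, , c] <- conv2d_fwd(sl, w, 0, 3L)
  }
  out
}

up2 <- function(x, mode) {
  u <- upsample2_fwd(x)
  if (mode == "smooth") u <- tent_smooth(u) else u
}

up2_bwd <- function(g, mode) {
  if (mode == "smooth") g <- tent_smooth(g)  # tent kernel is symmetric
  upsample2_bwd(g)
}

srcnn_forward_cache <- function(params, x) {
  x3 <- array(x, dim = c(nrow(x), ncol(x), 1L))
  z1 <- conv_apply(x3, params$conv1); a1 <- relu(z1)
  z2 <- conv_apply(a1, params$conv2); a2 <- relu(z2)
  o <- conv_apply(a2, params$head)
  list(out = matrix(o, nrow(x), ncol(x)), hint = a2,
       cache = list(x3 = x3, z1 = z1, a1 = a1, z2 = z2, a2 = a2))
}

srcnn_backward <- function(params, cache, dout = NULL, dhint = NULL) {
  grads <- list()
  if (!is.null(dout)) {
    d3 <- array(dout, dim = c(nrow(dout), ncol(dout), 1L))
    bh <- conv2d_bwd(cache$a2, params$head$W, d3, params$head$k, TRUE)
    grads$head <- list(W = bh$dW, b = bh$db)
    da2 <- bh$dX
    if (!is.null(dhint)) da2 <- da2 + dhint
  } else {
    da2 <- dhint
  }
  dz2 <- da2 * (cache$z2 > 0)
  b2 <- conv2d_bwd(cache$a1, params$conv2$W, dz2, params$conv2$k, TRUE)
  grads$conv2 <- list(W = b2$dW, b = b2$db)
  dz1 <- b2$dX * (cache$z1 > 0)
  b1 <- conv2d_bwd(cache$x3, params$conv1$W, dz1, params$conv1$k, FALSE)
  grads$conv1 <- list(W = b1$dW, b = b1$db)
  grads
}

drlstorm_forward_cache <- function(params, x, cfg) {
  H <- nrow(x); W <- ncol(x)
  if (H %% 8L != 0L || W %% 8L != 0L) {
    stop("input dimensions must be divisible by 8 (got ", H, "x", W,
         "); pad the image, e.g. with pad_to_multiple()")
  }
  x3 <- array(x, dim = c(H, W, 1L))
  z1 <- conv_apply(x3, params$enc1); e1 <- relu(z1)
  m1 <- maxpool2_fwd(e1)
  z2 <- conv_apply(m1$out, params$enc2); e2 <- relu(z2)
  m2 <- maxpool2_fwd(e2)
  z3 <- conv_apply(m2$out, params$enc3); e3 <- relu(z3)
  m3 <- maxpool2_fwd(e3)
  skp <- avgpool_fwd(conv_apply(x3, params$skip), 8L)
  h <- if (cfg$skip_mode == "add") m3$out + skp else {
    ar <- array(0, dim = c(dim(m3$out)[1], dim(m3$out)[2],
                           dim(m3$out)[3] + dim(skp)[3]))
    ar[, , seq_len(dim(m3$out)[3])] <- m3$out
    ar[, , dim(m3$out)[3] + seq_len(dim(skp)[3])] <- skp
    ar
  }
  u1 <- up2(h, cfg$upsample)
  w1 <- conv_apply(u1, params$dec1); d1 <- relu(w1)
  u2 <- up2(d1, cfg$upsample)
  w2 <- conv_apply(u2, params$dec2); d2 <- relu(w2)
  u3 <- up2(d2, cfg$upsample)
  w3 <- conv_apply(u3, params$dec3); d3 <- relu(w3)
  o <- conv_apply(d3, params$head)
  list(out = matrix(o, H, W), hint = d3,
       cache = list(x3 = x3, z1 = z1, e1 = e1, m1 = m1, z2 = z2, e2 = e2,
                    m2 = m2, z3 = z3, e3 = e3, m3 = m3, skp = skp, h = h,
                    u1 = u1, w1 = w1, d1 = d1, u2 = u2, w2 = w2, d2 = d2,
                    u3 = u3, w3 = w3, d3 = d3))
}

drlstorm_backward <- function(params, cache, cfg, dout = NULL, dhint = NULL) {
  grads <- list()
  if (!is.null(dout)) {
    dO <- array(dout, dim = c(nrow(dout), ncol(dout), 1L))
    bh <- conv2d_bwd(cache$d3, params$head$W, dO, params$head$k, TRUE)
    grads$head <- list(W = bh$dW, b = bh$db)
    dd3 <- bh$dX
    if (!is.null(dhint)) dd3 <- dd3 + dhint
  } else {
    dd3 <- dhint
  }
  dw3 <- dd3 * (cache$w3 > 0)
  b3 <- conv2d_bwd(cache$u3, params$dec3$W, dw3, params$dec3$k, TRUE)
  grads$dec3 <- list(W = b3$dW, b = b3$db)
  dd2 <- up2_bwd(b3$dX, cfg$upsample)
  dw2 <- dd2 * (cache$w2 > 0)
  b2 <- conv2d_bwd(cache$u2, params$dec2$W, dw2, params$dec2$k, TRUE)
  grads$dec2 <- list(W = b2$dW, b = b2$db)
  dd1 <- up2_bwd(b2$dX, cfg$upsample)
  dw1 <- dd1 * (cache$w1 > 0)
  b1 <- conv2d_bwd(cache$u1, params$dec1$W, dw1, params$dec1$k, TRUE)
  grads$dec1 <- list(W = b1$dW, b = b1$db)
  dh <- up2_bwd(b1$dX, cfg$upsample)
  nc3 <- dim(cache$m3$out)[3]
  if (cfg$skip_mode == "add") {
    dp3 <- dh
    dskp <- dh
  } else {
    dp3 <- dh[, , seq_len(nc3), drop = FALSE]
    dskp <- dh[, , nc3 + seq_len(dim(cache$skp)[3]), drop = FALSE]
  }
  # skip branch: average-pool then 1x1 conv back to the input
  dskin <- avgpool_bwd(dskp, 8L)
  bs <- conv2d_bwd(cache$x3, params$skip$W, dskin, params$skip$k, FALSE)
  grads$skip <- list(W = bs$dW, b = bs$db)
  # main encoder branch
  de3 <- maxpool2_bwd(dp3, cache$m3$argmax, nrow(cache$e3), ncol(cache$e3))
  dz3 <- de3 * (cache$z3 > 0)
  be3 <- conv2d_bwd(cache$m2$out, params$enc3$W, dz3, params$enc3$k, TRUE)
  grads$enc3 <- list(W = be3$dW, b = be3$db)
  de2 <- maxpool2_bwd(be3$dX, cache$m2$argmax, nrow(cache$e2), ncol(cache$e2))
  dz2 <- de2 * (cache$z2 > 0)
  be2 <- conv2d_bwd(cache$m1$out, params$enc2$W, dz2, params$enc2$k, TRUE)
  grads$enc2 <- list(W = be2$dW, b = be2$db)
  de1 <- maxpool2_bwd(be2$dX, cache$m1$argmax, nrow(cache$e1), ncol(cache$e1))
  dz1 <- de1 * (cache$z1 > 0)
  be1 <- conv2d_bwd(cache$x3, params$enc1$W, dz1, params$enc1$k, FALSE)
  grads$enc1 <- list(W = be1$dW, b = be1$db)
  grads
}

model_forward_cache <- function(model, x) {
  switch(model$arch,
         srcnn = srcnn_forward_cache(model$params, x),
         drlstorm = drlstorm_forward_cache(model$params, x, model$cfg),
         stop("unknown architecture: ", model$arch))
}

model_backward <- function(model, cache, dout = NULL, dhint = NULL) {
  switch(model$arch,
         srcnn = srcnn_backward(model$params, cache, dout, dhint),
         drlstorm = drlstorm_backward(model$params, cache, model$cfg,
                                      dout, dhint))
}

#' Run a model
#'
#' `model_forward()` runs the full network (head following body) on a single
#' H x W image and returns the H x W reconstruction; [forward_hint()]
#' returns the body output only — the 32-channel hint representation.
#'
#' @param model a `factorized_model`.
#' @param x an H x W numeric matrix (normalized diffraction-limited patch).
#' @return `model_forward()`: an H x W matrix; `forward_hint()`: an
#'   H x W x 32 array.
#' @export
model_forward <- function(model, x) {
  model_forward_cache(model, x)$out
}

#' @rdname model_forward
#' @export
forward_hint <- function(model, x) {
  model_forward_cache(model, x)$hint
}

#' Freeze a model's body
#'
#' Marks the body (everything up to and including the hint layer) as
#' non-trainable; subsequent training updates only the head. Idempotent.
#'
#' @param model a `factorized_model`.
#' @return the model with `body_frozen = TRUE`.
#' @export
freeze_body <- function(model) {
  model$body_frozen <- TRUE
  model
}

# stable fingerprint of a set of parameter tensors, used by freezing tests
weights_digest <- function(model, which = c("all", "body", "head")) {
  which <- match.arg(which)
  nms <- switch(which, all = names(model$params),
                body = model$body_params, head = model$head_params)
  vals <- unlist(lapply(model$params[nms], function(p) c(p$W, p$b)))
  paste(format(sum(vals), digits = 17), format(sum(vals^2), digits = 17),
        length(vals))
}

#' Pad an image to a multiple of a grid size
#'
#' Reflectively pads the bottom/right edges so both dimensions become
#' multiples of `m` (the teacher needs multiples of 8); returns the padded
#' matrix and the original size for later cropping.
#'
#' @param x numeric matrix.
#' @param m required multiple.
#' @return list with `padded`, `orig_dim`.
#' @export
pad_to_multiple <- function(x, m = 8L) {
  H <- nrow(x); W <- ncol(x)
  ph <- (m - H %% m) %% m
  pw <- (m - W %% m) %% m
  if (ph > 0L) x <- rbind(x, x[H:(H - ph + 1L), , drop = FALSE])
  if (pw > 0L) x <- cbind(x, x[, W:(W - pw + 1L), drop = FALSE])
  list(padded = x, orig_dim = c(H, W))
}
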