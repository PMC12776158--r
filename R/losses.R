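#' @title Sparse-reconstruction and distillation losses
#' @description The losses used throughout the pipeline. Image batches are
#'   lists of equally-sized H x W matrices (a single matrix is treated as a
#'   batch of one); feature batches are lists of H x W x C arrays.
#' @name losses
NULL

as_image_batch <- function(x, what = "batch") {
  if (is.matrix(x)) x <- list(x)
  if (!is.list(x) || length(x) == 0L) {
    stop(what, " must be a nonempty list of matrices")
  }
  d <- dim(x[[1]])
  for (m in x) {
    if (!is.matrix(m) || !identical(dim(m), d)) {
      stop("all images in ", what, " must be matrices of identical shape")
    }
  }
  x
}

check_same_shape <- function(a, b, what = "batches") {
  if (length(a) != length(b) || !identical(dim(a[[1]]), dim(b[[1]]))) {
    stop("shape mismatch between ", what)
  }
}

# per-sample L1L2: (lam/2) * ||(pred - truth) blurred||_2^2 + ||pred||_1
l1l2_sample <- function(pred, truth, lam, kernel) {
  d <- blur2(pred, kernel) - blur2(truth, kernel)
  (lam / 2) * sum(d^2) + sum(abs(pred))
}

# gradient of l1l2_sample w.r.t. pred (subgradient sign(0) = 0 for the L1 term)
l1l2_grad_sample <- function(pred, truth, lam, kernel) {
  d <- blur2(pred, kernel) - blur2(truth, kernel)
  lam * blur2(d, kernel) + sign(pred)
}

#' L1L2 sparse reconstruction loss
#'
#' Mean over the batch of
#' \deqn{\frac{\lambda}{2}\,\lVert \hat{x}_i \otimes g - x_i \otimes g
#'   \rVert_2^2 + \lVert \hat{x}_i \rVert_1,}
#' where \eqn{g} is a small Gaussian kernel (see
#' [make_gaussian_kernel()]): squared error between Gaussian-blurred
#' prediction and ground truth, plus an L1 sparsity penalty on the raw
#' prediction weighted through \eqn{\lambda}. The blur gives the squared term
#' a one-kernel-width tolerance for localization error; the L1 term drives
#' the background to exact zeros. Convolution is zero-padded with same-size
#' output.
#'
#' @param pred_batch,truth_batch lists of equally-shaped matrices (or single
#'   matrices) of predictions and ground truths.
#' @param lam sparsity weight \eqn{\lambda > 0}.
#' @param kernel a `gaussian_kernel`.
#' @return nonnegative scalar loss.
#' @export
l1l2_loss <- function(pred_batch, truth_batch, lam, kernel = make_gaussian_kernel()) {
  pred_batch <- as_image_batch(pred_batch, "pred_batch")
  truth_batch <- as_image_batch(truth_batch, "truth_batch")
  check_same_shape(pred_batch, truth_batch)
  stopifnot(lam > 0)
  mean(mapply(l1l2_sample, pred_batch, truth_batch,
              MoreArgs = list(lam = lam, kernel = kernel)))
}

#' Per-sample teacher error vector
#'
#' Evaluates the L1L2 loss of a frozen, trained teacher on every training
#' sample individually. The resulting vector feeds the attention
#' normalization of the imitation loss (see [compute_eta_phi()]): its range
#' calibrates how much a teacher-informed term should be trusted. Both the
#' squared term and the L1 term are taken on the teacher's own predictions
#' (the teacher error predates any student).
#'
#' @param teacher_pred_batch,truth_batch matched lists over the training set.
#' @inheritParams l1l2_loss
#' @return numeric vector, one L1L2 value per sample.
#' @export
teacher_error_vector <- function(teacher_pred_batch, truth_batch, lam,
                                 kernel = make_gaussian_kernel()) {
  teacher_pred_batch <- as_image_batch(teacher_pred_batch, "teacher_pred_batch")
  truth_batch <- as_image_batch(truth_batch, "truth_batch")
  check_same_shape(teacher_pred_batch, truth_batch)
  vapply(seq_along(teacher_pred_batch), function(i) {
    l1l2_sample(teacher_pred_batch[[i]], truth_batch[[i]], lam, kernel)
  }, numeric(1))
}

#' Attention normalization constants from the teacher error vector
#'
#' Computes \eqn{\eta = \max(e_T) - \min(e_T)} (the spread of the teacher's
#' per-sample training errors) and \eqn{\Phi = \mathrm{mean}(e_T)/\eta}, the
#' scalar that scales the teacher-informed term of the imitation loss.
#'
#' @param e_T numeric vector of per-sample teacher L1L2 losses (length >= 2).
#' @return list with elements `eta` and `phi`.
#' @export
#' @examples
#' compute_eta_phi(c(2, 4, 6)) # eta 4, phi 1
compute_eta_phi <- function(e_T) {
  if (length(e_T) < 2L) stop("e_T must have at least 2 entries")
  eta <- max(e_T) - min(e_T)
  if (eta <= 0) {
    stop("degenerate normalization: e_T is constant (eta = 0)")
  }
  list(eta = eta, phi = mean(e_T) / eta)
}

#' Attentive-imitation loss context
#'
#' Bundles everything the imitation loss needs: the sparsity weight
#' \eqn{\lambda}, the attention weight \eqn{\alpha}, the blur kernel, the
#' teacher error vector and its derived constants \eqn{\eta} and \eqn{\Phi}.
#'
#' @param lam sparsity weight (> 0).
#' @param alpha attention weight in \[0, 1\]; 1 = pure ground-truth loss,
#'   small values shift attention to the teacher.
#' @param e_T teacher error vector (see [teacher_error_vector()]).
#' @param kernel a `gaussian_kernel`.
#' @param mode `"as_printed"` (teacher-vs-truth squared term in the
#'   imitation component) or `"imitation"` (student-vs-teacher squared
#'   term).
#' @return object of class `ail_context`.
#' @export
ail_context <- function(lam, alpha, e_T, kernel = make_gaussian_kernel(),
                        mode = c("as_printed", "imitation")) {
  mode <- match.arg(mode)
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("`alpha` must lie in [0, 1]")
  }
  stopifnot(lam > 0)
  ep <- compute_eta_phi(e_T)
  structure(list(lam = lam, alpha = alpha, kernel = kernel, e_T = e_T,
                 eta = ep$eta, phi = ep$phi, mode = mode),
            class = "ail_context")
}

ail_sample_terms <- function(student, teacher, truth, ctx) {
  lam <- ctx$lam
  k <- ctx$kernel
  own <- l1l2_sample(student, truth, lam, k)
  l1_student <- sum(abs(student))
  if (ctx$mode == "as_printed") {
    d <- blur2(teacher, k) - blur2(truth, k)
  } else {
    d <- blur2(student, k) - blur2(teacher, k)
  }
  imit <- (lam / 2) * sum(d^2) + l1_student
  c(own = own, imit = imit)
}

#' Attentive Imitation Loss (AIL)
#'
#' A regression distillation loss blending ground-truth fidelity with a
#' teacher-informed term. For each sample the loss is
#' \deqn{\alpha\, L_{1L2}(\hat{x}_i, x_i) + (1-\alpha)\,\Phi\,
#'   \left[\tfrac{\lambda}{2}\lVert \bar{x}_i \otimes g - x_i \otimes g
#'   \rVert^2 + \lVert \hat{x}_i \rVert_1\right]}
#' in the default `"as_printed"` mode (\eqn{\bar{x}} the teacher prediction);
#' `"imitation"` mode replaces the second squared term with
#' \eqn{\lVert \hat{x}_i \otimes g - \bar{x}_i \otimes g\rVert^2} so the
#' student is pulled directly toward the teacher. \eqn{\Phi} scales the
#' teacher term by the teacher's mean training error relative to its spread
#' (see [compute_eta_phi()]).
#'
#' @param student_pred_batch,teacher_pred_batch,truth_batch matched lists of
#'   equally-shaped matrices.
#' @param ctx an [ail_context()].
#' @return nonnegative scalar loss.
#' @export
ail_loss <- function(student_pred_batch, teacher_pred_batch, truth_batch, ctx) {
  stopifnot(inherits(ctx, "ail_context"))
  student_pred_batch <- as_image_batch(student_pred_batch, "student_pred_batch")
  teacher_pred_batch <- as_image_batch(teacher_pred_batch, "teacher_pred_batch")
  truth_batch <- as_image_batch(truth_batch, "truth_batch")
  check_same_shape(student_pred_batch, truth_batch)
  check_same_shape(student_pred_batch, teacher_pred_batch)
  a <- ctx$alpha
  vals <- vapply(seq_along(student_pred_batch), function(i) {
    tm <- ail_sample_terms(student_pred_batch[[i]], teacher_pred_batch[[i]],
                           truth_batch[[i]], ctx)
    a * tm[["own"]] + (1 - a) * ctx$phi * tm[["imit"]]
  }, numeric(1))
  mean(vals)
}

# gradient of the per-sample AIL w.r.t. the student prediction
ail_grad_sample <- function(student, teacher, truth, ctx) {
  a <- ctx$alpha
  g_own <- l1l2_grad_sample(student, truth, ctx$lam, ctx$kernel)
  s <- sign(student)
  if (ctx$mode == "as_printed") {
    # teacher squared term is constant w.r.t. the student; only its L1 flows
    g_imit <- s
  } else {
    d <- blur2(student, ctx$kernel) - blur2(teacher, ctx$kernel)
    g_imit <- ctx$lam * blur2(d, ctx$kernel) + s
  }
  a * g_own + (1 - a) * ctx$phi * g_imit
}

#' Hint-learning loss (feature MSE)
#'
#' Mean squared error between the student's and the teacher's hint-layer
#' feature maps (32-channel penultimate representations). The default
#' `"mean"` reduction averages over every element so the value is independent
#' of patch size and batch size; `"sum"` accumulates instead.
#'
#' @param student_features,teacher_features lists of H x W x C arrays (or a
#'   single array each), identically shaped; C must match between the two.
#' @param reduction `"mean"` (default) or `"sum"`.
#' @return nonnegative scalar.
#' @export
hint_loss <- function(student_features, teacher_features,
                      reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (is.array(student_features) && !is.list(student_features)) {
    student_features <- list(student_features)
  }
  if (is.array(teacher_features) && !is.list(teacher_features)) {
    teacher_features <- list(teacher_features)
  }
  if (length(student_features) != length(teacher_features)) {
    stop("feature batches differ in length")
  }
  ds <- dim(student_features[[1]])
  dt <- dim(teacher_features[[1]])
  if (length(ds) != 3L || length(dt) != 3L) {
    stop("features must be H x W x C arrays")
  }
  if (ds[3] != dt[3]) {
    stop("channel-count mismatch: student has ", ds[3], ", teacher has ",
         dt[3], " (hint layers are expected to share 32 channels)")
  }
  if (!identical(ds, dt)) stop("feature shapes differ")
  tot <- 0
  n <- 0
  for (i in seq_along(student_features)) {
    d <- student_features[[i]] - teacher_features[[i]]
    tot <- tot + sum(d^2)
    n <- n + length(d)
  }
  if (reduction == "mean") tot / n else tot
}
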