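#' Training configuration
#'
#' Defaults follow the study protocol: 50 epochs, batch size 5, Adam at
#' learning rate 1e-4, and a plateau scheduler that multiplies the learning
#' rate by 0.1 when the monitored loss has not improved by more than
#' `threshold` for `patience_epochs` consecutive epochs.
#'
#' @param epochs number of passes over the training split (>= 0).
#' @param batch_size samples per optimizer step.
#' @param learning_rate initial Adam learning rate.
#' @param scheduler list with `factor` (in (0,1)), `patience_epochs`,
#'   `threshold` (minimum absolute improvement that counts) and `monitor`
#'   (`"val"` or `"train"`).
#' @param rng_seed integer seed governing shuffling (and nothing else).
#' @param lam sparsity weight for the L1L2 loss.
#' @param kernel Gaussian kernel used inside the losses.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 50L, batch_size = 5L, learning_rate = 1e-4,
                         scheduler = list(factor = 0.1, patience_epochs = 5L,
                                          threshold = 1e-4, monitor = "val"),
                         rng_seed = 1L, lam = 100,
                         kernel = make_gaussian_kernel()) {
  stopifnot(epochs >= 0L, batch_size >= 1L, learning_rate >= 0)
  sched <- modifyList(list(factor = 0.1, patience_epochs = 5L,
                           threshold = 1e-4, monitor = "val"), scheduler)
  stopifnot(sched$factor > 0, sched$factor < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, scheduler = sched,
                 rng_seed = as.integer(rng_seed), lam = lam, kernel = kernel),
            class = "train_config")
}

adam_init <- function(params, nms) {
  st <- list(t = 0L, m = list(), v = list())
  for (nm in nms) {
    st$m[[nm]] <- list(W = params[[nm]]$W * 0, b = params[[nm]]$b * 0)
    st$v[[nm]] <- list(W = params[[nm]]$W * 0, b = params[[nm]]$b * 0)
  }
  st
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(st$m)) {
    for (part in c("W", "b")) {
      g <- grads[[nm]][[part]]
      st$m[[nm]][[part]] <- beta1 * st$m[[nm]][[part]] + (1 - beta1) * g
      st$v[[nm]][[part]] <- beta2 * st$v[[nm]][[part]] + (1 - beta2) * g^2
      mhat <- st$m[[nm]][[part]] / bc1
      vhat <- st$v[[nm]][[part]] / bc2
      params[[nm]][[part]] <- params[[nm]][[part]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = st)
}

zero_like_grads <- function(params, nms) {
  g <- list()
  for (nm in nms) g[[nm]] <- list(W = params[[nm]]$W * 0,
                                  b = params[[nm]]$b * 0)
  g
}

accumulate_grads <- function(acc, g, nms) {
  for (nm in nms) {
    if (is.null(g[[nm]])) next
    acc[[nm]]$W <- acc[[nm]]$W + g[[nm]]$W
    acc[[nm]]$b <- acc[[nm]]$b + as.numeric(g[[nm]]$b)
  }
  acc
}

scale_grads <- function(g, s) {
  lapply(g, function(p) list(W = p$W * s, b = p$b * s))
}

# Generic seeded training loop.
#
# step_fn(model, idx) -> list(loss = mean batch loss, grads = named grads,
#                             summed over the batch, only for trainable nms)
# eval_fn(model, idx) -> per-sample mean loss on the given indices
run_training <- function(model, train_idx, val_idx, cfg, trainable_nms,
                         step_fn, eval_fn) {
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), lr = numeric(0))
  if (cfg$epochs == 0L) {
    return(list(model = model, history = history))
  }
  st <- adam_init(model$params, trainable_nms)
  lr <- cfg$learning_rate
  best <- Inf
  stall <- 0L
  sched <- cfg$scheduler
  withr::with_seed(cfg$rng_seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_loss <- 0
      for (b in batches) {
        sb <- step_fn(model, b)
        ep_loss <- ep_loss + sb$loss * length(b)
        upd <- adam_step(model$params, scale_grads(sb$grads, 1 / length(b)),
                         st, lr)
        model$params <- upd$params
        st <- upd$state
      }
      train_loss <- ep_loss / length(train_idx)
      val_loss <- if (length(val_idx) > 0L) eval_fn(model, val_idx) else NA_real_
      history <- rbind(history, data.frame(epoch = ep,
                                           train_loss = train_loss,
                                           val_loss = val_loss, lr = lr))
      watched <- if (sched$monitor == "train" || length(val_idx) == 0L) {
        train_loss
      } else {
        val_loss
      }
      if (watched < best - sched$threshold) {
        best <- watched
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= sched$patience_epochs) {
          lr <- lr * sched$factor
          stall <- 0L
        }
      }
    }
  })
  list(model = model, history = history)
}

check_dataset_ready <- function(dataset, need_val = TRUE) {
  stopifnot(inherits(dataset, "patch_dataset"))
  if (is.na(dataset$norm_mean)) {
    stop("dataset must be normalized first (see normalize_dataset())")
  }
  if (sum(dataset$split == "train") == 0L) stop("empty train split")
  if (need_val && sum(dataset$split == "val") == 0L) stop("empty val split")
}

#' Baseline training on the L1L2 loss
#'
#' Optimizes the full model with Adam on shuffled mini-batches of the train
#' split, computing the validation loss every epoch and applying the
#' plateau learning-rate scheduler. Deterministic given the config seed.
#'
#' @param model a `factorized_model`.
#' @param dataset a normalized `patch_dataset`.
#' @param cfg a [train_config()].
#' @return list with the trained `model` and a `history` data frame
#'   (epoch, train_loss, val_loss, lr).
#' @export
train_baseline <- function(model, dataset, cfg = train_config()) {
  check_dataset_ready(dataset)
  nms <- names(model$params)
  step_fn <- function(m, idx) {
    acc <- zero_like_grads(m$params, nms)
    loss <- 0
    for (i in idx) {
      fc <- model_forward_cache(m, dataset$x[[i]])
      loss <- loss + l1l2_sample(fc$out, dataset$y[[i]], cfg$lam, cfg$kernel)
      dout <- l1l2_grad_sample(fc$out, dataset$y[[i]], cfg$lam, cfg$kernel)
      acc <- accumulate_grads(acc, model_backward(m, fc$cache, dout = dout),
                              nms)
    }
    list(loss = loss / length(idx), grads = acc)
  }
  eval_fn <- function(m, idx) {
    mean(vapply(idx, function(i) {
      l1l2_sample(model_forward(m, dataset$x[[i]]), dataset$y[[i]],
                  cfg$lam, cfg$kernel)
    }, numeric(1)))
  }
  run_training(model, which(dataset$split == "train"),
               which(dataset$split == "val"), cfg, nms, step_fn, eval_fn)
}

#' Student training with the Attentive Imitation Loss
#'
#' Optimizes the student on [ail_loss()] with the frozen teacher's
#' predictions computed on the fly (or cached once when `cache_teacher` is
#' set, identical results since the teacher never changes). At `alpha = 1`
#' the loss and every update reduce exactly to [train_baseline()].
#'
#' @param student,frozen_teacher `factorized_model`s; the teacher is only
#'   ever run in inference.
#' @param dataset a normalized `patch_dataset`.
#' @param alpha attention weight in \[0, 1\].
#' @param cfg a [train_config()].
#' @param ctx an [ail_context()] built from the teacher's error vector; its
#'   `alpha` is overridden by `alpha`.
#' @param cache_teacher precompute teacher predictions once (default TRUE).
#' @return list with trained `student` (as `model`) and `history`.
#' @export
train_with_ail <- function(student, frozen_teacher, dataset, alpha,
                           cfg = train_config(), ctx,
                           cache_teacher = TRUE) {
  check_dataset_ready(dataset)
  if (missing(ctx) || !inherits(ctx, "ail_context")) {
    stop("an ail_context (teacher error vector, eta, phi) is required")
  }
  ctx$alpha <- alpha
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]")
  tpred <- new.env(parent = emptyenv())
  teacher_pred <- function(i) {
    key <- as.character(i)
    if (cache_teacher && !is.null(tpred[[key]])) return(tpred[[key]])
    p <- model_forward(frozen_teacher, dataset$x[[i]])
    if (cache_teacher) tpred[[key]] <- p
    p
  }
  nms <- names(student$params)
  step_fn <- function(m, idx) {
    acc <- zero_like_grads(m$params, nms)
    loss <- 0
    for (i in idx) {
      fc <- model_forward_cache(m, dataset$x[[i]])
      tp <- teacher_pred(i)
      tm <- ail_sample_terms(fc$out, tp, dataset$y[[i]], ctx)
      loss <- loss + ctx$alpha * tm[["own"]] +
        (1 - ctx$alpha) * ctx$phi * tm[["imit"]]
      dout <- ail_grad_sample(fc$out, tp, dataset$y[[i]], ctx)
      acc <- accumulate_grads(acc, model_backward(m, fc$cache, dout = dout),
                              nms)
    }
    list(loss = loss / length(idx), grads = acc)
  }
  eval_fn <- function(m, idx) {
    mean(vapply(idx, function(i) {
      tm <- ail_sample_terms(model_forward(m, dataset$x[[i]]),
                             teacher_pred(i), dataset$y[[i]], ctx)
      ctx$alpha * tm[["own"]] + (1 - ctx$alpha) * ctx$phi * tm[["imit"]]
    }, numeric(1)))
  }
  run_training(student, which(dataset$split == "train"),
               which(dataset$split == "val"), cfg, nms, step_fn, eval_fn)
}

#' Hint learning: train the student body toward the teacher's features
#'
#' Optimizes only the student's body so that its hint-layer output matches
#' the frozen teacher's 32-channel hint representation under [hint_loss()];
#' the student head is untouched. Teacher features are computed once per
#' patch and cached (the teacher is frozen).
#'
#' @inheritParams train_with_ail
#' @param reduction hint-loss reduction, `"mean"` or `"sum"`.
#' @return list with the body-trained `model` and `history`.
#' @export
train_hint <- function(student, frozen_teacher, dataset,
                       cfg = train_config(), reduction = "mean") {
  check_dataset_ready(dataset)
  tfeat <- new.env(parent = emptyenv())
  teacher_feat <- function(i) {
    key <- as.character(i)
    if (is.null(tfeat[[key]])) {
      tfeat[[key]] <- forward_hint(frozen_teacher, dataset$x[[i]])
    }
    tfeat[[key]]
  }
  nms <- student$body_params
  step_fn <- function(m, idx) {
    acc <- zero_like_grads(m$params, nms)
    loss <- 0
    for (i in idx) {
      fc <- model_forward_cache(m, dataset$x[[i]])
      tf <- teacher_feat(i)
      if (!identical(dim(fc$hint), dim(tf))) {
        stop("hint-shape mismatch between student (",
             paste(dim(fc$hint), collapse = "x"), ") and teacher (",
             paste(dim(tf), collapse = "x"), ")")
      }
      d <- fc$hint - tf
      n <- length(d)
      if (reduction == "mean") {
        loss <- loss + sum(d^2) / n
        dhint <- 2 * d / n
      } else {
        loss <- loss + sum(d^2)
        dhint <- 2 * d
      }
      acc <- accumulate_grads(acc, model_backward(m, fc$cache, dhint = dhint),
                              nms)
    }
    list(loss = loss / length(idx), grads = acc)
  }
  eval_fn <- function(m, idx) {
    mean(vapply(idx, function(i) {
      hint_loss(forward_hint(m, dataset$x[[i]]), teacher_feat(i),
                reduction = reduction)
    }, numeric(1)))
  }
  run_training(student, which(dataset$split == "train"),
               which(dataset$split == "val"), cfg, nms, step_fn, eval_fn)
}

#' Head fine-tuning after hint learning
#'
#' With the student body frozen (see [freeze_body()]), optimizes only the
#' reconstruction head on the Attentive Imitation Loss. The body is
#' bit-identical before and after.
#'
#' @inheritParams train_with_ail
#' @param student_with_frozen_body a `factorized_model` whose body was
#'   frozen via [freeze_body()].
#' @return list with trained `model` and `history`.
#' @export
train_head_after_hint <- function(student_with_frozen_body, frozen_teacher,
                                  dataset, alpha, cfg = train_config(), ctx,
                                  cache_teacher = TRUE) {
  if (!isTRUE(student_with_frozen_body$body_frozen)) {
    stop("the student body must be frozen first (freeze_body())")
  }
  check_dataset_ready(dataset)
  ctx$alpha <- alpha
  tpred <- new.env(parent = emptyenv())
  teacher_pred <- function(i) {
    key <- as.character(i)
    if (cache_teacher && !is.null(tpred[[key]])) return(tpred[[key]])
    p <- model_forward(frozen_teacher, dataset$x[[i]])
    if (cache_teacher) tpred[[key]] <- p
    p
  }
  nms <- student_with_frozen_body$head_params
  step_fn <- function(m, idx) {
    acc <- zero_like_grads(m$params, nms)
    loss <- 0
    for (i in idx) {
      fc <- model_forward_cache(m, dataset$x[[i]])
      tp <- teacher_pred(i)
      tm <- ail_sample_terms(fc$out, tp, dataset$y[[i]], ctx)
      loss <- loss + ctx$alpha * tm[["own"]] +
        (1 - ctx$alpha) * ctx$phi * tm[["imit"]]
      dout <- ail_grad_sample(fc$out, tp, dataset$y[[i]], ctx)
      g <- model_backward(m, fc$cache, dout = dout)
      acc <- accumulate_grads(acc, g[nms], nms)
    }
    list(loss = loss / length(idx), grads = acc)
  }
  eval_fn <- function(m, idx) {
    mean(vapply(idx, function(i) {
      tm <- ail_sample_terms(model_forward(m, dataset$x[[i]]),
                             teacher_pred(i), dataset$y[[i]], ctx)
      ctx$alpha * tm[["own"]] + (1 - ctx$alpha) * ctx$phi * tm[["imit"]]
    }, numeric(1)))
  }
  run_training(student_with_frozen_body,
               which(dataset$split == "train"), which(dataset$split == "val"),
               cfg, nms, step_fn, eval_fn)
}
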