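#' Generate a study dataset with the protocol presets
#'
#' Reproduces the synthetic-data protocol end to end: emitter fields at a
#' fixed density on a 0.1 um/px grid, pixel-integrated Gaussian PSF
#' rendering with Poisson shot noise over a uniform background of 200
#' counts, random square patches with identical X/Y offsets, a categorical
#' 80:10:10 split, ground-truth spikes expressed in units of the nominal
#' photon count, and dataset-wide z-scoring of the inputs.
#'
#' The `"full"` preset matches the study protocol (five 1000 x 1000 frames,
#' 200 patches of 200 x 200 each, density 13); `"desk"` is the scaled-down
#' configuration used throughout the tests and the acceptance analyses
#' (three 192 x 192 frames, 60 patches of 32 x 32 each) — small enough to
#' train on a single CPU while keeping the dense-emitter regime (about 130
#' overlapping emitters per patch).
#'
#' @param scale `"desk"` or `"full"`.
#' @param density_per_um2 emitter density (13 dense, 5 sparse).
#' @param rng_seed integer master seed (field, noise, patching each get a
#'   derived seed).
#' @param background_level uniform background mean counts.
#' @param psf_sigma_px Gaussian PSF sd in pixels.
#' @param photons nominal photons per emitter; also the Y amplitude unit.
#' @param normalize z-score the inputs (default TRUE).
#' @return a normalized `patch_dataset`.
#' @export
make_study_dataset <- function(scale = c("desk", "full"),
                               density_per_um2 = 13, rng_seed = 1L,
                               background_level = 200, psf_sigma_px = 1.6,
                               photons = 1000, normalize = TRUE) {
  scale <- match.arg(scale)
  p <- if (scale == "full") {
    list(n_images = 5L, size = 1000L, patch = 200L, per_image = 200L)
  } else {
    list(n_images = 3L, size = 192L, patch = 32L, per_image = 60L)
  }
  pairs <- lapply(seq_len(p$n_images), function(i) {
    fld <- simulate_emitter_field(p$size, p$size, pixel_size_um = 0.1,
                                  density_per_um2 = density_per_um2,
                                  photon_model = photon_model_fixed(photons),
                                  rng_seed = rng_seed + 1000L * i)
    render_pair(fld, psf_sigma_px = psf_sigma_px,
                background_level = background_level,
                noise_model = "poisson", rng_seed = rng_seed + 1000L * i + 1L)
  })
  ds <- build_patch_dataset(pairs, patch_size = p$patch,
                            patches_per_image = p$per_image,
                            split_probs = c(train = 0.8, val = 0.1,
                                            test = 0.1),
                            rng_seed = rng_seed + 7L, y_scale = 1 / photons)
  ds$meta$generation <- list(scale = scale, density_per_um2 = density_per_um2,
                             background_level = background_level,
                             psf_sigma_px = psf_sigma_px,
                             pixel_size_um = 0.1, photons = photons,
                             rng_seed = rng_seed)
  if (normalize) ds <- normalize_dataset(ds)
  ds
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a diffable JSON manifest (`<prefix>.json`: name,
#' architecture, config, seed, tensor shapes) next to a raw little-endian
#' double weights blob (`<prefix>.bin`).
#'
#' @param model a `factorized_model`.
#' @param prefix file path prefix (no extension).
#' @export
save_model <- function(model, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  shapes <- lapply(model$params, function(p) {
    list(k = p$k, cin = p$cin, cout = p$cout)
  })
  manifest <- list(name = model$name, arch = model$arch, cfg = model$cfg,
                   seed = model$seed, body_params = model$body_params,
                   head_params = model$head_params,
                   body_frozen = model$body_frozen, shapes = shapes)
  jsonlite::write_json(manifest, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(prefix, ".bin"), "wb")
  for (nm in names(model$params)) {
    writeBin(c(as.numeric(model$params[[nm]]$W),
               as.numeric(model$params[[nm]]$b)), con, size = 8,
             endian = "little")
  }
  close(con)
  invisible(prefix)
}

#' @rdname save_model
#' @export
load_model <- function(prefix) {
  mf <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  cfg <- as.list(mf$cfg)
  params <- list()
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  for (nm in names(mf$shapes)) {
    sh <- mf$shapes[[nm]]
    nW <- sh$k * sh$k * sh$cin * sh$cout
    W <- matrix(readBin(con, numeric(), nW, size = 8, endian = "little"),
                nrow = sh$k * sh$k * sh$cin, ncol = sh$cout)
    b <- readBin(con, numeric(), sh$cout, size = 8, endian = "little")
    params[[nm]] <- list(W = W, b = b, k = as.integer(sh$k),
                         cin = as.integer(sh$cin), cout = as.integer(sh$cout))
  }
  m <- new_factorized_model(mf$name, mf$arch, params,
                            body_params = mf$body_params,
                            head_params = mf$head_params, cfg = cfg,
                            seed = mf$seed)
  m$body_frozen <- isTRUE(mf$body_frozen)
  m
}

#' Reconstruct a super-resolved image from a frame stack
#'
#' Applies the model frame by frame (inputs are normalized with the
#' training-set statistics; frames are reflectively padded to the model's
#' grid constraint and cropped back) and aggregates per-frame outputs into
#' a single reconstruction — the standard sum rendering of localization
#' microscopy, with a mean option.
#'
#' @param model a `factorized_model`.
#' @param stack a multi-page TIFF path, a list of matrices, or an
#'   H x W x n array of raw frames.
#' @param norm_mean,norm_std normalization statistics of the training
#'   dataset (see [normalize_dataset()]).
#' @param aggregate `"sum"` (default) or `"mean"`.
#' @return an H x W reconstruction matrix.
#' @export
reconstruct_stack <- function(model, stack, norm_mean, norm_std,
                              aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  if (is.character(stack)) {
    if (!file.exists(stack)) stop("cannot read TIFF: ", stack)
    # 8/16-bit pages hold raw camera counts (read as integers); 32-bit
    # pages are floating point and must be read verbatim
    info <- tiff::readTIFF(stack, payload = FALSE)
    as_is <- info$bits.per.sample[1] < 32L
    stack <- tiff::readTIFF(stack, all = TRUE, as.is = as_is)
    if (!is.list(stack)) stack <- list(stack)
    stack <- lapply(stack, function(f) {
      if (length(dim(f)) == 3L) f <- f[, , 1]  # first channel
      matrix(as.numeric(f), nrow(f), ncol(f))
    })
  }
  if (is.array(stack) && length(dim(stack)) == 3L) {
    stack <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  }
  stopifnot(is.list(stack), length(stack) >= 1L)
  needs_pad <- !is.function(model) && model$arch == "drlstorm"
  fwd <- if (is.function(model)) model else function(x) model_forward(model, x)
  out <- NULL
  for (f in stack) {
    x <- (f - norm_mean) / norm_std
    if (needs_pad) {
      pd <- pad_to_multiple(x, 8L)
      y <- fwd(pd$padded)[seq_len(pd$orig_dim[1]), seq_len(pd$orig_dim[2]),
                          drop = FALSE]
    } else {
      y <- fwd(x)
    }
    out <- if (is.null(out)) y else out + y
  }
  if (aggregate == "mean") out / length(stack) else out
}

stage_keys <- list(
  common = c("stage", "out_dir", "seed"),
  simulate = c("scale", "density_per_um2", "background_level",
               "psf_sigma_px", "photons"),
  train = c("dataset", "model", "epochs", "batch_size", "learning_rate",
            "lambda"),
  distill = c("dataset", "teacher", "alpha", "epochs", "batch_size",
              "learning_rate", "lambda", "ail_mode"),
  hint = c("dataset", "teacher", "epochs", "batch_size", "learning_rate",
           "hint_reduction"),
  evaluate = c("dataset", "model_checkpoint", "split"),
  embed = c("dataset", "model_checkpoints", "split", "method",
            "n_neighbors", "min_dist"),
  `sweep-lambda` = c("dataset", "model", "lambda_values", "epochs",
                     "batch_size", "learning_rate"),
  `sweep-alpha` = c("dataset", "teacher", "alpha_values", "epochs",
                    "batch_size", "learning_rate", "lambda"),
  reconstruct = c("model_checkpoint", "tiff", "norm_mean", "norm_std",
                  "aggregate")
)

build_train_cfg <- function(config, defaults = train_config()) {
  cfg <- defaults
  if (!is.null(config$epochs)) cfg$epochs <- as.integer(config$epochs)
  if (!is.null(config$batch_size)) cfg$batch_size <- as.integer(config$batch_size)
  if (!is.null(config$learning_rate)) cfg$learning_rate <- config$learning_rate
  if (!is.null(config$lambda)) cfg$lam <- config$lambda
  cfg$rng_seed <- as.integer(config$seed %||% 1L)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute one pipeline stage from a configuration
#'
#' A serializable-config front end over the package's functions: each stage
#' reads/writes artifacts under `config$out_dir` together with a config
#' snapshot (`config.json`), so any run can be replayed. Stages:
#' `simulate` (dataset bundle + sidecar), `train` (baseline model +
#' history), `distill` (AIL student), `hint` (hint-learned body), `evaluate`
#' (metrics CSV/JSON), `embed` (2-D embedding CSV), `sweep-lambda`,
#' `sweep-alpha` (metric tables), `reconstruct` (summed reconstruction
#' CSV). Configs may come from [yaml::read_yaml()]; unknown keys are
#' rejected by name.
#'
#' @param config named list with at least `stage` and `out_dir`.
#' @return the output directory, invisibly; stage artifacts on disk.
#' @export
run_stage <- function(config) {
  stage <- config$stage
  if (is.null(stage) || !stage %in% names(stage_keys)[-1]) {
    stop("unknown stage: ", if (is.null(stage)) "<missing>" else stage)
  }
  allowed <- c(stage_keys$common, stage_keys[[stage]])
  bad <- setdiff(names(config), allowed)
  if (length(bad) > 0L) {
    stop("unknown config key(s) for stage '", stage, "': ",
         paste(bad, collapse = ", "))
  }
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  snapshot <- config
  snapshot$package_version <- as.character(utils::packageVersion("stormdistill"))
  jsonlite::write_json(snapshot, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  if (stage == "simulate") {
    ds <- make_study_dataset(scale = config$scale %||% "desk",
                             density_per_um2 = config$density_per_um2 %||% 13,
                             background_level = config$background_level %||% 200,
                             psf_sigma_px = config$psf_sigma_px %||% 1.6,
                             photons = config$photons %||% 1000,
                             rng_seed = seed)
    write_dataset(ds, file.path(out_dir, "dataset"))
  } else if (stage == "train") {
    ds <- read_dataset(config$dataset)
    cfg <- build_train_cfg(config)
    model <- switch(config$model %||% "srcnn",
                    srcnn = build_srcnn(seed),
                    drlstorm = build_drlstorm(seed),
                    stop("unknown model: ", config$model))
    fit <- train_baseline(model, ds, cfg)
    save_model(fit$model, file.path(out_dir, "model"))
    utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
  } else if (stage == "distill") {
    ds <- read_dataset(config$dataset)
    cfg <- build_train_cfg(config)
    teacher <- load_model(config$teacher)
    tr <- dataset_split(ds, "train")
    tpred <- lapply(tr$x, function(x) model_forward(teacher, x))
    eT <- teacher_error_vector(tpred, tr$y, cfg$lam, cfg$kernel)
    ctx <- ail_context(cfg$lam, config$alpha %||% 0.6, eT, cfg$kernel,
                       mode = config$ail_mode %||% "as_printed")
    fit <- train_with_ail(build_srcnn(seed), teacher, ds,
                          alpha = config$alpha %||% 0.6, cfg = cfg, ctx = ctx)
    save_model(fit$model, file.path(out_dir, "model"))
    utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(sample = tr$index, e_T = eT),
                     file.path(out_dir, "teacher_errors.csv"),
                     row.names = FALSE)
  } else if (stage == "hint") {
    ds <- read_dataset(config$dataset)
    cfg <- build_train_cfg(config)
    teacher <- load_model(config$teacher)
    fit <- train_hint(build_srcnn(seed), teacher, ds, cfg,
                      reduction = config$hint_reduction %||% "mean")
    save_model(fit$model, file.path(out_dir, "model"))
    utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
  } else if (stage == "evaluate") {
    ds <- read_dataset(config$dataset)
    model <- load_model(config$model_checkpoint)
    rep <- evaluate(model, ds, split = config$split %||% "test")
    utils::write.csv(data.frame(patch = rep$patch_index, nmse = rep$nmse,
                                ssim = rep$ssim),
                     file.path(out_dir, "metrics.csv"), row.names = FALSE)
    jsonlite::write_json(rep$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (stage == "embed") {
    ds <- read_dataset(config$dataset)
    sp <- dataset_split(ds, config$split %||% "test")
    sets <- lapply(config$model_checkpoints, function(pfx) {
      extract_features(load_model(pfx), sp$x, ids = sp$index)
    })
    emb <- embed_models(sets, method = config$method %||% "umap",
                        n_neighbors = config$n_neighbors %||% 15L,
                        min_dist = config$min_dist %||% 0.1, seed = seed)
    utils::write.csv(emb, file.path(out_dir, "embedding.csv"),
                     row.names = FALSE)
  } else if (stage == "sweep-lambda") {
    ds <- read_dataset(config$dataset)
    cfg <- build_train_cfg(config)
    builder <- switch(config$model %||% "srcnn",
                      srcnn = build_srcnn, drlstorm = build_drlstorm)
    tab <- sweep_lambda(builder, ds,
                        lambda_values = unlist(config$lambda_values) %||%
                          c(10, 50, 100, 200, 400, 800), cfg = cfg)
    utils::write.csv(tab, file.path(out_dir, "sweep_lambda.csv"),
                     row.names = FALSE)
  } else if (stage == "sweep-alpha") {
    ds <- read_dataset(config$dataset)
    cfg <- build_train_cfg(config)
    teacher <- load_model(config$teacher)
    tr <- dataset_split(ds, "train")
    tpred <- lapply(tr$x, function(x) model_forward(teacher, x))
    eT <- teacher_error_vector(tpred, tr$y, cfg$lam, cfg$kernel)
    ctx <- ail_context(cfg$lam, 0.5, eT, cfg$kernel)
    tab <- sweep_alpha(build_srcnn, teacher, ds,
                       alpha_values = unlist(config$alpha_values) %||%
                         seq(0.1, 0.8, by = 0.1), cfg = cfg, ctx = ctx)
    utils::write.csv(tab, file.path(out_dir, "sweep_alpha.csv"),
                     row.names = FALSE)
  } else if (stage == "reconstruct") {
    model <- load_model(config$model_checkpoint)
    rec <- reconstruct_stack(model, config$tiff, config$norm_mean,
                             config$norm_std,
                             aggregate = config$aggregate %||% "sum")
    utils::write.csv(rec, file.path(out_dir, "reconstruction.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}
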