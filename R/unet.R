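#' U-net configuration
#'
#' Size-configurable 3D U-net for patch-wise dose-rate regression.  The
#' contracting path is `depth` resolution levels of 3x3x3 convolution +
#' batch normalization + ReLU, joined by 2x2x2 max pooling, with the
#' feature-map count starting at `base_features` and doubling per level;
#' the expanding path uses stride-2 transposed convolutions and skip
#' concatenation with the feature count halving, followed by a final
#' 1x1x1 linear convolution to one output channel.  Batch normalization
#' is applied in the contracting path only.
#'
#' Patch dimensions must be divisible by `2^(depth - 1)` on every axis.
#'
#' @param in_channels input channels (2: PET and CT).
#' @param base_features feature maps in the first level (reference
#'   configuration uses 14; desk-scale tests use fewer).
#' @param depth number of resolution levels (>= 1).
#' @param batch_norm logical.
#' @param seed integer seed for weight initialization.
#' @return A `unet_config` list.
#' @export
unet_config <- function(in_channels = 2, base_features = 14, depth = 4,
                        batch_norm = TRUE, seed = 1L) {
  stopifnot(in_channels >= 1, base_features >= 1, depth >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 base_features = as.integer(base_features),
                 depth = as.integer(depth),
                 batch_norm = isTRUE(batch_norm),
                 seed = as.integer(seed)),
            class = "unet_config")
}

.unet_features <- function(config)
  config$base_features * 2L^(seq_len(config$depth) - 1L)

#' Build a U-net model
#'
#' Initializes all parameters (He initialization, seeded) and reports the
#' total trainable parameter count, which is a pure function of the
#' configuration.
#'
#' @param config a [unet_config()].
#' @return A `unet_model`: `config`, `params` (named list of arrays),
#'   `bn_stats` (running mean/var per BN layer), `n_params`, and `scaling`
#'   (filled in by [train_unet()]).
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  feats <- .unet_features(config)
  d <- config$depth
  params <- list()
  rng <- seeded_rng(config$seed)
  he <- function(dims, fan_in) array(rng(prod(dims)) * sqrt(2 / fan_in),
                                     dims)
  cin <- config$in_channels
  for (l in seq_len(d)) {
    f <- feats[l]
    params[[paste0("enc", l, "_w")]] <- he(c(3, 3, 3, cin, f), 27 * cin)
    params[[paste0("enc", l, "_b")]] <- numeric(f)
    if (config$batch_norm) {
      params[[paste0("enc", l, "_g")]] <- rep(1, f)
      params[[paste0("enc", l, "_be")]] <- numeric(f)
    }
    cin <- f
  }
  if (d > 1) for (l in (d - 1):1) {
    fup <- feats[l + 1]; f <- feats[l]
    params[[paste0("up", l, "_w")]] <- he(c(2, 2, 2, fup, f), 8 * fup)
    params[[paste0("up", l, "_b")]] <- numeric(f)
    params[[paste0("dec", l, "_w")]] <- he(c(3, 3, 3, 2 * f, f), 27 * 2 * f)
    params[[paste0("dec", l, "_b")]] <- numeric(f)
  }
  params[["out_w"]] <- he(c(1, 1, 1, feats[1], 1), feats[1])
  params[["out_b"]] <- numeric(1)
  bn_stats <- list()
  if (config$batch_norm) for (l in seq_len(d))
    bn_stats[[paste0("enc", l)]] <- list(mean = numeric(feats[l]),
                                         var = rep(1, feats[l]), n = 0)
  structure(list(config = config, params = params, bn_stats = bn_stats,
                 n_params = sum(vapply(params, length, numeric(1))),
                 scaling = NULL),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> depth %d, base %d, %s parameters%s\n",
              x$config$depth, x$config$base_features,
              format(x$n_params, big.mark = ","),
              if (is.null(x$scaling)) " (untrained)" else " (trained)"))
  invisible(x)
}

# deterministic standard-normal stream independent of the global RNG
seeded_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  function(n) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    x <- rnorm(n)
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    x
  }
}

.check_patch_dims <- function(config, pd) {
  div <- 2L^(config$depth - 1L)
  if (any(pd %% div != 0L))
    stop(sprintf("patch dims (%s) must be divisible by %d at depth %d",
                 paste(pd, collapse = "x"), div, config$depth))
}

# ---- forward / backward -------------------------------------------------

.bn_forward <- function(x, gamma, beta, stats, training, eps = 1e-5,
                        momentum = 0.1) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 3, 5, 4)), ncol = d[4])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2, mu)^2)
    stats$mean <- if (stats$n == 0) mu else
      (1 - momentum) * stats$mean + momentum * mu
    stats$var <- if (stats$n == 0) v else
      (1 - momentum) * stats$var + momentum * v
    stats$n <- stats$n + 1
  } else {
    mu <- stats$mean; v <- stats$var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, ivar, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  out <- aperm(array(y, c(d[1], d[2], d[3], d[5], d[4])), c(1, 2, 3, 5, 4))
  list(out = out, cache = list(xhat = xhat, ivar = ivar, gamma = gamma,
                               dims = d),
       stats = stats)
}

.bn_backward <- function(gout, cache) {
  d <- cache$dims
  gm <- matrix(aperm(gout, c(1, 2, 3, 5, 4)), ncol = d[4])
  n <- nrow(gm)
  dgamma <- colSums(gm * cache$xhat)
  dbeta <- colSums(gm)
  dxhat <- sweep(gm, 2, cache$gamma, `*`)
  dx <- sweep(dxhat - matrix(colMeans(dxhat), n, d[4], byrow = TRUE) -
                sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`),
              2, cache$ivar, `*`)
  gin <- aperm(array(dx, c(d[1], d[2], d[3], d[5], d[4])), c(1, 2, 3, 5, 4))
  list(gin = gin, dgamma = dgamma, dbeta = dbeta)
}

.conv_f <- function(x, w, b) {
  din <- as.integer(dim(x))
  out <- .conv3d_fwd(as.numeric(x), din, as.numeric(w), as.integer(dim(w)),
                     as.numeric(b))
  array(out, c(din[1:3], dim(w)[5], din[5]))
}

.unet_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  d <- cfg$depth
  pd <- as.integer(dim(x)[1:3])
  .check_patch_dims(cfg, pd)
  cache <- list(); skips <- list()
  h <- x
  for (l in seq_len(d)) {
    w <- model$params[[paste0("enc", l, "_w")]]
    pre <- .conv_f(h, w, model$params[[paste0("enc", l, "_b")]])
    cache[[paste0("enc", l, "_in")]] <- h
    if (cfg$batch_norm) {
      bn <- .bn_forward(pre, model$params[[paste0("enc", l, "_g")]],
                        model$params[[paste0("enc", l, "_be")]],
                        model$bn_stats[[paste0("enc", l)]], training)
      model$bn_stats[[paste0("enc", l)]] <- bn$stats
      cache[[paste0("enc", l, "_bn")]] <- bn$cache
      act_in <- bn$out
    } else act_in <- pre
    h <- pmax(act_in, 0)
    cache[[paste0("enc", l, "_relu")]] <- act_in > 0
    skips[[l]] <- h
    if (l < d) {
      mp <- .maxpool3d_fwd(as.numeric(h), as.integer(dim(h)))
      cache[[paste0("pool", l, "_arg")]] <- mp$argmax
      cache[[paste0("pool", l, "_din")]] <- as.integer(dim(h))
      h <- array(mp$out, c(dim(h)[1:3] %/% 2L, dim(h)[4:5]))
    }
  }
  if (d > 1) for (l in (d - 1):1) {
    wup <- model$params[[paste0("up", l, "_w")]]
    cache[[paste0("up", l, "_in")]] <- h
    up <- .deconv3d_fwd(as.numeric(h), as.integer(dim(h)),
                        as.numeric(wup),
                        as.numeric(model$params[[paste0("up", l, "_b")]]),
                        dim(wup)[5])
    up <- array(up, c(dim(h)[1:3] * 2L, dim(wup)[5], dim(h)[5]))
    cache[[paste0("up", l, "_relu")]] <- up > 0
    up <- pmax(up, 0)
    f <- dim(up)[4]
    cat5 <- array(0, c(dim(up)[1:3], 2L * f, dim(up)[5]))
    cat5[, , , seq_len(f), ] <- skips[[l]]
    cat5[, , , f + seq_len(f), ] <- up
    cache[[paste0("dec", l, "_in")]] <- cat5
    pre <- .conv_f(cat5, model$params[[paste0("dec", l, "_w")]],
                   model$params[[paste0("dec", l, "_b")]])
    cache[[paste0("dec", l, "_relu")]] <- pre > 0
    h <- pmax(pre, 0)
  }
  cache[["out_in"]] <- h
  y <- .conv_f(h, model$params[["out_w"]], model$params[["out_b"]])
  list(y = y, cache = cache, skips_dims = lapply(skips, dim),
       model = model)
}

.unet_backward <- function(model, fwd, gy) {
  cfg <- model$config
  d <- cfg$depth
  cache <- fwd$cache
  grads <- list()
  bw <- .conv3d_bwd(as.numeric(cache[["out_in"]]),
                    as.integer(dim(cache[["out_in"]])),
                    as.numeric(model$params[["out_w"]]),
                    as.integer(dim(model$params[["out_w"]])),
                    as.numeric(gy))
  grads[["out_w"]] <- array(bw$gw, dim(model$params[["out_w"]]))
  grads[["out_b"]] <- bw$gb
  gh <- array(bw$gin, dim(cache[["out_in"]]))
  gskip <- vector("list", d)
  if (d > 1) for (l in seq_len(d - 1)) {
    gh <- gh * cache[[paste0("dec", l, "_relu")]]
    cin <- cache[[paste0("dec", l, "_in")]]
    bw <- .conv3d_bwd(as.numeric(cin), as.integer(dim(cin)),
                      as.numeric(model$params[[paste0("dec", l, "_w")]]),
                      as.integer(dim(model$params[[paste0("dec", l,
                                                          "_w")]])),
                      as.numeric(gh))
    grads[[paste0("dec", l, "_w")]] <-
      array(bw$gw, dim(model$params[[paste0("dec", l, "_w")]]))
    grads[[paste0("dec", l, "_b")]] <- bw$gb
    gcat <- array(bw$gin, dim(cin))
    f <- dim(cin)[4] / 2L
    gskip[[l]] <- gcat[, , , seq_len(f), , drop = FALSE]
    gup <- gcat[, , , f + seq_len(f), , drop = FALSE]
    gup <- gup * cache[[paste0("up", l, "_relu")]]
    uin <- cache[[paste0("up", l, "_in")]]
    bw <- .deconv3d_bwd(as.numeric(uin), as.integer(dim(uin)),
                        as.numeric(model$params[[paste0("up", l, "_w")]]),
                        f, as.numeric(gup))
    grads[[paste0("up", l, "_w")]] <-
      array(bw$gw, dim(model$params[[paste0("up", l, "_w")]]))
    grads[[paste0("up", l, "_b")]] <- bw$gb
    gh <- array(bw$gin, dim(uin))
  }
  # contracting path, deepest level first
  for (l in rev(seq_len(d))) {
    if (l < d) {
      din <- cache[[paste0("pool", l, "_din")]]
      gh <- array(.maxpool3d_bwd(as.numeric(gh),
                                 cache[[paste0("pool", l, "_arg")]],
                                 din), din)
    }
    if (!is.null(gskip[[l]])) gh <- gh + gskip[[l]]
    gh <- gh * cache[[paste0("enc", l, "_relu")]]
    if (cfg$batch_norm) {
      bb <- .bn_backward(gh, cache[[paste0("enc", l, "_bn")]])
      grads[[paste0("enc", l, "_g")]] <- bb$dgamma
      grads[[paste0("enc", l, "_be")]] <- bb$dbeta
      gh <- bb$gin
    }
    cin <- cache[[paste0("enc", l, "_in")]]
    bw <- .conv3d_bwd(as.numeric(cin), as.integer(dim(cin)),
                      as.numeric(model$params[[paste0("enc", l, "_w")]]),
                      as.integer(dim(model$params[[paste0("enc", l,
                                                          "_w")]])),
                      as.numeric(gh))
    grads[[paste0("enc", l, "_w")]] <-
      array(bw$gw, dim(model$params[[paste0("enc", l, "_w")]]))
    grads[[paste0("enc", l, "_b")]] <- bw$gb
    gh <- array(bw$gin, dim(cin))
  }
  grads
}

# ---- training -----------------------------------------------------------

#' Training configuration
#'
#' @param lr ADAM learning rate.
#' @param beta1,beta2,eps ADAM moment parameters.
#' @param batch_size mini-batch size (reference configuration 150;
#'   desk-scale profile 16).
#' @param epochs training epochs (reference configuration 7).
#' @param seed integer seed for shuffling.
#' @param folds cross-validation folds (default 5).
#' @return A `train_config` list.  The loss is the L1 norm (mean absolute
#'   error) on scaled targets; the optimizer is ADAM.
#' @export
train_config <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, batch_size = 16, epochs = 7,
                         seed = 1L, folds = 5L) {
  stopifnot(batch_size >= 1, epochs >= 1, lr > 0)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 folds = as.integer(folds)),
            class = "train_config")
}

.stack_input <- function(pet, ct, pet_scale, ct_scale = 1000) {
  pd <- dim(pet)[1:3]; np <- dim(pet)[4]
  x <- array(0, c(pd, 2L, np))
  x[, , , 1L, ] <- pet / pet_scale
  x[, , , 2L, ] <- ct / ct_scale
  x
}

#' Train the dose-prediction U-net
#'
#' Minimizes the L1 norm between predicted and ground-truth dose-rate
#' patches with ADAM, on globally scaled inputs and targets: PET divided
#' by the training set's 99.9th percentile, CT mapped HU/1000, targets
#' divided by their 99.9th percentile.  The scaling constants are stored
#' with the model and reapplied at inference.  Shuffling is seeded; the
#' per-epoch mean loss history is returned.
#'
#' @param model a [build_unet()] model.
#' @param patches a `patch_set` (or plain list) with 4D arrays `pet`,
#'   `ct`, `dose`.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch loss.
#' @return The trained `unet_model` with `loss_history` and `scaling`.
#' @export
train_unet <- function(model, patches, cfg = train_config(),
                       verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"), inherits(cfg, "train_config"))
  np <- dim(patches$pet)[4]
  if (is.null(np) || np < 1) stop("empty patch set")
  pet_scale <- as.numeric(quantile(patches$pet, 0.999))
  if (pet_scale <= 0) pet_scale <- max(patches$pet, 1e-12)
  dose_scale <- as.numeric(quantile(patches$dose, 0.999))
  if (dose_scale <= 0) dose_scale <- max(patches$dose, 1e-12)
  x_all <- .stack_input(patches$pet, patches$ct, pet_scale)
  y_all <- patches$dose / dose_scale

  # ADAM state
  mstate <- lapply(model$params, function(p) array(0, dim(p) %||%
                                                     length(p)))
  vstate <- mstate
  step <- 0L
  losses <- numeric(0)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample_int_seeded(np, np, cfg$seed + ep)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, np, by = cfg$batch_size)) {
      sel <- ord[start:min(start + cfg$batch_size - 1, np)]
      xb <- x_all[, , , , sel, drop = FALSE]
      yb <- y_all[, , , sel, drop = FALSE]
      fwd <- .unet_forward(model, xb, training = TRUE)
      model <- fwd$model  # updated BN running stats
      pred <- fwd$y[, , , 1L, ]
      dim(pred) <- dim(yb)
      resid <- pred - yb
      loss <- mean(abs(resid))
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d (|resid| max %.3g)",
                     ep, max(abs(resid))))
      gy <- array(sign(resid) / length(resid),
                  c(dim(yb)[1:3], 1L, dim(yb)[4]))
      grads <- .unet_backward(model, fwd, gy)
      step <- step + 1L
      for (nm in names(model$params)) {
        g <- grads[[nm]]
        mstate[[nm]] <- cfg$beta1 * mstate[[nm]] + (1 - cfg$beta1) * g
        vstate[[nm]] <- cfg$beta2 * vstate[[nm]] + (1 - cfg$beta2) * g^2
        mhat <- mstate[[nm]] / (1 - cfg$beta1^step)
        vhat <- vstate[[nm]] / (1 - cfg$beta2^step)
        model$params[[nm]] <- model$params[[nm]] -
          cfg$lr * mhat / (sqrt(vhat) + cfg$eps)
      }
      ep_loss <- ep_loss + loss; nb <- nb + 1
    }
    losses <- c(losses, ep_loss / nb)
    if (verbose)
      message(sprintf("epoch %d/%d  L1 loss %.5f", ep, cfg$epochs,
                      losses[ep]))
  }
  model$scaling <- list(pet_scale = pet_scale, ct_scale = 1000,
                        dose_scale = dose_scale)
  model$loss_history <- losses
  model$train_config <- cfg
  model
}

#' Predict a dose-rate volume with a trained U-net
#'
#' Runs patch-wise inference over the volume at the given stride and
#' reassembles overlapping predictions by uniform averaging, then
#' un-scales the output back to Gy/s.  Negative predictions are clipped
#' to zero (dose rates are non-negative).
#'
#' @param model trained `unet_model` (scaling constants required).
#' @param pet `voxvol` activity volume (`"Bq/mL"` or `"Bq"`).
#' @param ct `voxvol` CT volume (`"HU"`) on the same grid.
#' @param patch_dims integer triple (divisible per the model depth).
#' @param stride integer triple; defaults to half the patch dims.
#' @param batch_size inference mini-batch size.
#' @return A `voxvol` in Gy/s.
#' @export
predict_dose_rate <- function(model, pet, ct,
                              patch_dims = c(48, 48, 24),
                              stride = NULL, batch_size = 16) {
  if (is.null(model$scaling))
    stop("model has no scaling constants; train it first")
  check_same_grid(pet, ct)
  pd <- as.integer(patch_dims)
  .check_patch_dims(model$config, pd)
  if (is.null(stride)) stride <- pmax(pd %/% 2L, 1L)
  idx <- enumerate_patches(dim(pet), pd, stride, mask = NULL,
                           min_fraction = 0)
  # flush patches at the far boundary so the whole volume is covered
  flush <- expand.grid(x0 = unique(c(idx$x0, dim(pet)[1] - pd[1])),
                       y0 = unique(c(idx$y0, dim(pet)[2] - pd[2])),
                       z0 = unique(c(idx$z0, dim(pet)[3] - pd[3])))
  idx <- unique(rbind(idx[, 1:3], flush))
  ps <- extract_patches(list(pet = pet, ct = ct), idx, patch_dims = pd)
  x_all <- .stack_input(ps$pet, ps$ct, model$scaling$pet_scale,
                        model$scaling$ct_scale)
  np <- nrow(idx)
  pred <- array(0, c(pd, np))
  for (start in seq(1, np, by = batch_size)) {
    sel <- start:min(start + batch_size - 1, np)
    fwd <- .unet_forward(model, x_all[, , , , sel, drop = FALSE],
                         training = FALSE)
    pred[, , , sel] <- fwd$y[, , , 1L, ]
  }
  out <- assemble_prediction(idx, pred, dim(pet),
                             attr(pet, "voxel_size"), units = "Gy/s")
  vals <- pmax(unclass(out) * model$scaling$dose_scale, 0)
  dim(vals) <- dim(out)
  v <- new_like(pet, vals, units = "Gy/s")
  attr(v, "coverage") <- attr(out, "coverage")
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' k-fold cross-validation over phantom datasets
#'
#' Splits the datasets into `k` equal test folds (seeded, persisted in
#' the output), trains a fresh model on the complement of each fold and
#' evaluates mean voxel-level percentage error on the held-out datasets.
#' With 10 datasets and `k = 5` this is the 8-train / 2-test design;
#' with `k` equal to the dataset count it degenerates to leave-one-out.
#'
#' @param datasets list of datasets; each is a list with `voxvol`s `pet`,
#'   `ct`, `dose` (ground-truth dose rate) and optionally `mask`.
#' @param k number of folds; must divide the dataset count.
#' @param unet_cfg a [unet_config()].
#' @param train_cfg a [train_config()].
#' @param patch_dims,offsets patch geometry for training extraction.
#' @param patches_per_image per-image patch cap (seeded subsampling).
#' @return List with `folds` (assignment), `metrics` (per-dataset
#'   data.frame of held-out voxel errors) and `pooled` (mean +/- sd).
#' @export
crossvalidate_unet <- function(datasets, k = 5,
                               unet_cfg = unet_config(),
                               train_cfg = train_config(),
                               patch_dims = c(16, 16, 8),
                               offsets = c(8, 8, 4),
                               patches_per_image = 500) {
  n <- length(datasets)
  if (k > n) stop("k exceeds dataset count")
  if (n %% k != 0) stop("dataset count must divide into k equal folds")
  per <- n %/% k
  ord <- sample_int_seeded(n, n, train_cfg$seed)
  folds <- split(ord, rep(seq_len(k), each = per))
  rows <- list()
  for (fi in seq_len(k)) {
    test_ids <- folds[[fi]]
    train_ids <- setdiff(seq_len(n), test_ids)
    tr <- .collect_patches(datasets[train_ids], patch_dims, offsets,
                           patches_per_image, train_cfg$seed + fi)
    model <- build_unet(unet_cfg)
    model <- train_unet(model, tr, train_cfg)
    for (ti in test_ids) {
      ds <- datasets[[ti]]
      pred <- predict_dose_rate(model, ds$pet, ds$ct, patch_dims)
      msk <- ds$mask %||% new_like(ds$pet,
                                   array(1, dim(ds$pet)), units = "mask")
      err <- voxel_percent_diff(pred, ds$dose, msk)
      rows[[length(rows) + 1L]] <-
        data.frame(fold = fi, dataset = ti, mean_pct = err$mean,
                   sd_pct = err$sd, n_voxels = err$n)
    }
  }
  metrics <- do.call(rbind, rows)
  list(folds = folds, metrics = metrics,
       pooled = c(mean = mean(metrics$mean_pct),
                  sd = sd(metrics$mean_pct)))
}

#' Collect training patches from several datasets
#'
#' Enumerates body-masked patch positions in each dataset (exclusion
#' below 1/8 body fraction), caps them per image with seeded uniform
#' subsampling, extracts aligned PET/CT/dose stacks and concatenates
#' them across datasets.
#'
#' @param datasets list of datasets as in [crossvalidate_unet()].
#' @param patch_dims,offsets patch geometry.
#' @param patches_per_image per-image cap.
#' @param seed integer seed for the subsampling.
#' @return List with 4D arrays `pet`, `ct`, `dose`.
#' @export
collect_training_patches <- function(datasets, patch_dims = c(16, 16, 8),
                                     offsets = c(3, 3, 2),
                                     patches_per_image = 170,
                                     seed = 100) {
  .collect_patches(datasets, patch_dims, offsets, patches_per_image, seed)
}

.collect_patches <- function(datasets, patch_dims, offsets, cap, seed) {
  acc <- list(pet = NULL, ct = NULL, dose = NULL)
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    msk <- ds$mask %||% NULL
    idx <- enumerate_patches(dim(ds$pet), patch_dims, offsets, mask = msk)
    idx <- cap_patches(idx, cap, seed + i)
    ps <- extract_patches(list(pet = ds$pet, ct = ds$ct, dose = ds$dose),
                          idx, patch_dims)
    acc$pet <- if (is.null(acc$pet)) ps$pet else
      abind4(acc$pet, ps$pet)
    acc$ct <- if (is.null(acc$ct)) ps$ct else abind4(acc$ct, ps$ct)
    acc$dose <- if (is.null(acc$dose)) ps$dose else
      abind4(acc$dose, ps$dose)
  }
  acc
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[1:3] == db[1:3]))
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}
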