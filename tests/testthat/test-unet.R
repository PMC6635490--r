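# tiny deterministic patch set: target is a fixed linear blur of the
# inputs, cheap for the network to approximate
toy_patches <- function(np = 24, pd = c(8, 8, 4), seed = 31) {
  set.seed(seed)
  pet <- array(runif(prod(pd) * np), c(pd, np))
  ct <- array(rep(c(-500, 0), length.out = prod(pd) * np), c(pd, np))
  dose <- pet * 2e-7 + 1e-8
  list(pet = pet, ct = ct, dose = dose)
}

test_that("feature widths double down the contracting path and params are reproducible", {
  cfg <- unet_config(base_features = 14, depth = 4, seed = 2)
  expect_equal(voxdose:::.unet_features(cfg), c(14, 28, 56, 112))
  m1 <- build_unet(cfg); m2 <- build_unet(cfg)
  expect_equal(m1$n_params, m2$n_params)
  expect_identical(m1$params, m2$params)
  # minimal network parameter count checked against hand arithmetic:
  # conv 3x3x3 (2 -> 1) = 54 + 1 bias, BN gamma/beta = 2,
  # final 1x1x1 conv (1 -> 1) = 1 + 1 bias
  mini <- build_unet(unet_config(in_channels = 2, base_features = 1,
                                 depth = 1))
  expect_equal(mini$n_params, 54 + 1 + 2 + 1 + 1)
  # without batch norm the affine pair disappears
  mini2 <- build_unet(unet_config(2, 1, 1, batch_norm = FALSE))
  expect_equal(mini2$n_params, 54 + 1 + 1 + 1)
})

test_that("output patch dims equal input patch dims across random valid configs", {
  set.seed(77)
  for (trial in 1:5) {
    depth <- sample(1:3, 1)
    base <- sample(1:4, 1)
    mult <- 2^(depth - 1)
    pd <- mult * sample(1:2, 3, replace = TRUE) * 2
    cfg <- unet_config(2, base, depth, seed = trial)
    m <- build_unet(cfg)
    x <- array(rnorm(prod(pd) * 2 * 2), c(pd, 2, 2))
    y <- voxdose:::.unet_forward(m, x, training = TRUE)$y
    expect_equal(dim(y), c(pd, 1, 2))
  }
  # indivisible patch dims are a config error
  m4 <- build_unet(unet_config(2, 2, 3))
  x_bad <- array(0, c(6, 6, 6, 2, 1))
  expect_error(voxdose:::.unet_forward(m4, x_bad), "divisible")
})

test_that("analytic gradients match numeric gradients", {
  cfg <- unet_config(2, 2, 2, batch_norm = TRUE, seed = 7)
  m <- build_unet(cfg)
  # nudge biases off zero so no pre-activation sits exactly on the ReLU
  # kink (where the subgradient and the central difference differ)
  for (nm in grep("_b$|_be$", names(m$params), value = TRUE))
    m$params[[nm]] <- m$params[[nm]] + 0.05
  set.seed(42)
  x <- array(rnorm(4 * 4 * 4 * 2 * 3), c(4, 4, 4, 2, 3))
  y <- array(rnorm(4 * 4 * 4 * 3), c(4, 4, 4, 3))
  lossfun <- function(model) {
    fwd <- voxdose:::.unet_forward(model, x, training = TRUE)
    pred <- fwd$y[, , , 1, ]; dim(pred) <- dim(y)
    0.5 * mean((pred - y)^2)
  }
  fwd <- voxdose:::.unet_forward(m, x, training = TRUE)
  pred <- fwd$y[, , , 1, ]; dim(pred) <- dim(y)
  gy <- array((pred - y) / length(y), c(4, 4, 4, 1, 3))
  grads <- voxdose:::.unet_backward(m, fwd, gy)
  eps <- 1e-5
  set.seed(8)
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      m2 <- m; m2$params[[nm]][i] <- p[i] + eps
      m3 <- m; m3$params[[nm]][i] <- p[i] - eps
      num <- (lossfun(m2) - lossfun(m3)) / (2 * eps)
      expect_lt(abs(num - grads[[nm]][i]) /
                  max(abs(num) + abs(grads[[nm]][i]), 1e-6), 5e-3,
                label = sprintf("gradient of %s[%d]", nm, i))
    }
  }
})

test_that("training drives the loss down and memorizes a constant mapping", {
  tp <- toy_patches()
  cfg <- train_config(batch_size = 8, epochs = 6, seed = 3)
  m <- build_unet(unet_config(2, 4, 2, seed = 9))
  m <- train_unet(m, tp, cfg)
  expect_lt(tail(m$loss_history, 1), m$loss_history[1])
  # identical input -> identical target pairs: loss collapses toward zero
  one <- list(pet = array(rep(tp$pet[, , , 1], 16), c(8, 8, 4, 16)),
              ct = array(rep(tp$ct[, , , 1], 16), c(8, 8, 4, 16)),
              dose = array(rep(tp$dose[, , , 1], 16), c(8, 8, 4, 16)))
  mm <- build_unet(unet_config(2, 4, 2, seed = 9))
  mm <- train_unet(mm, one, train_config(lr = 5e-3, batch_size = 16,
                                         epochs = 60, seed = 3))
  expect_lt(tail(mm$loss_history, 1), 0.1 * mm$loss_history[1])
})

test_that("training is seed-deterministic and invariant to target rescaling", {
  tp <- toy_patches()
  cfg <- train_config(batch_size = 8, epochs = 3, seed = 12)
  m1 <- train_unet(build_unet(unet_config(2, 2, 2, seed = 4)), tp, cfg)
  m2 <- train_unet(build_unet(unet_config(2, 2, 2, seed = 4)), tp, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params, m2$params)
  # scaling all targets by alpha rescales the stored constant, leaving
  # the normalized optimization identical and predictions scaled
  tp_scaled <- tp; tp_scaled$dose <- tp$dose * 3.5
  m3 <- train_unet(build_unet(unet_config(2, 2, 2, seed = 4)), tp_scaled,
                   cfg)
  expect_equal(m3$loss_history, m1$loss_history, tolerance = 1e-12)
  expect_equal(m3$scaling$dose_scale, m1$scaling$dose_scale * 3.5)
  expect_error(train_unet(build_unet(unet_config(2, 2, 2)),
                          list(pet = array(0, c(8, 8, 4, 0)),
                               ct = array(0, c(8, 8, 4, 0)),
                               dose = array(0, c(8, 8, 4, 0))),
                          cfg),
               "empty")
})

test_that("prediction reassembles to the volume grid and requires scaling constants", {
  tp <- toy_patches(np = 32)
  m <- train_unet(build_unet(unet_config(2, 4, 2, seed = 9)), tp,
                  train_config(batch_size = 8, epochs = 4, seed = 3))
  dims <- c(16, 16, 8)
  pet <- voxvol(array(runif(prod(dims)), dims), c(2.67, 2.67, 5), "Bq/mL")
  ct <- voxvol(array(0, dims), c(2.67, 2.67, 5), "HU")
  pred <- predict_dose_rate(m, pet, ct, patch_dims = c(8, 8, 4))
  expect_equal(dim(pred), dims)
  expect_true(all(unclass(pred) >= 0))
  expect_true(all(attr(pred, "coverage") >= 1))
  um <- build_unet(unet_config(2, 4, 2, seed = 9))
  expect_error(predict_dose_rate(um, pet, ct, c(8, 8, 4)),
               "scaling")
})

test_that("cross-validation folds partition the datasets exactly once", {
  ker <- small_kernel()
  datasets <- lapply(1:5, function(s)
    demo_dataset(demo_phantom_spec("torso", c(16, 16, 8), seed = s), ker,
                 truth = "kernel"))
  cv <- crossvalidate_unet(datasets, k = 5,
                           unet_cfg = unet_config(2, 2, 2, seed = 1),
                           train_cfg = train_config(batch_size = 8,
                                                    epochs = 1, seed = 2),
                           patch_dims = c(8, 8, 4), offsets = c(4, 4, 2),
                           patches_per_image = 20)
  tested <- sort(unname(unlist(cv$folds)))
  expect_equal(tested, 1:5)                 # leave-one-out partition
  expect_equal(nrow(cv$metrics), 5L)
  expect_equal(sort(cv$metrics$dataset), 1:5)
  expect_true(all(is.finite(cv$metrics$mean_pct)))
  expect_error(crossvalidate_unet(datasets, k = 7), "exceeds")
  expect_error(crossvalidate_unet(datasets[1:4], k = 3), "equal folds")
})
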