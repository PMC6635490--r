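test_that("kernel convolution equals the brute-force double sum on small grids", {
  set.seed(21)
  for (trial in 1:4) {
    dv <- sample(5:16, 3, replace = TRUE)
    dk <- c(5, 5, 3)
    vol <- array(runif(prod(dv)), dv)
    ker <- array(runif(prod(dk)) * 1e-3, dk)
    oracle <- brute_convolve3(vol, ker)
    kernel <- structure(list(values = voxvol(ker, c(2.67, 2.67, 5),
                                             "Gy/MBq.s"),
                             n_histories = 1, capture_fraction = 1,
                             scheme = decay_scheme()),
                        class = "vsv_kernel")
    at <- voxvol(vol, c(2.67, 2.67, 5), "MBq.s")
    direct <- convolve_vsv(at, kernel, method = "direct")
    ffted <- convolve_vsv(at, kernel, method = "fft")
    expect_lt(max(abs(unclass(direct) - oracle)) / max(oracle), 1e-10)
    expect_lt(max(abs(unclass(ffted) - oracle)) / max(oracle), 1e-10)
  }
})

test_that("a unit point source reproduces the kernel and convolution is linear", {
  ker <- small_kernel()
  dims <- c(25, 25, 15)
  at <- array(0, dims); at[13, 13, 8] <- 1
  at <- voxvol(at, c(2.67, 2.67, 5), "MBq.s")
  d <- convolve_vsv(at, ker)
  kd <- dim(ker$values)
  sub <- unclass(d)[13 + (-(kd[1] %/% 2)):(kd[1] %/% 2),
                    13 + (-(kd[2] %/% 2)):(kd[2] %/% 2),
                    8 + (-(kd[3] %/% 2)):(kd[3] %/% 2)]
  expect_equal(sub, unclass(ker$values), tolerance = 1e-10,
               ignore_attr = TRUE)
  # linearity at alpha = 3.5
  a2 <- new_like(at, unclass(at) * 3.5, units = "MBq.s")
  expect_equal(unclass(convolve_vsv(a2, ker)), unclass(d) * 3.5,
               tolerance = 1e-12)
})

test_that("kernel has centred maximum, reflection symmetry and matched voxel size", {
  ker <- small_kernel()
  v <- unclass(ker$values)
  kd <- dim(v); ctr <- (kd + 1) %/% 2
  expect_equal(arrayInd(which.max(v), kd)[1, ], ctr, ignore_attr = TRUE)
  expect_equal(attr(ker$values, "voxel_size"), c(2.67, 2.67, 5))
  expect_true(all(v >= 0))
  # reflection symmetry within Monte Carlo noise on the bright core
  core <- ctr[1] + (-3:3)
  a <- v[core, ctr[2], ctr[3]]
  expect_lt(max(abs(a - rev(a)) / pmax(a, rev(a))), 0.2)
  # energy bookkeeping: kernel mass-weighted sum ~ deposited energy kept
  # inside the kernel volume (Gy/MBq.s * g over kernel = J per 1e6 decays)
  vox_g <- voxel_volume_ml(ker$values) * 1.0
  e_kernel_j <- sum(v * vox_g * 1e-3) / 1e6        # J per decay
  sc <- ker$scheme
  e_emitted_j <- emitted_energy_per_decay(sc) * 1.602176634e-13
  frac <- e_kernel_j / e_emitted_j
  # positron energy alone is 44% of the budget; photons mostly escape the
  # small kernel volume, so the captured fraction sits between the local
  # deposit and the full budget
  expect_gt(frac, 0.44)
  expect_lt(frac, 1.0)
})

test_that("a kernel too small for the photon dose range warns", {
  expect_warning(generate_vsv_kernel(kernel_dims = c(5, 5, 3),
                                     n_histories = 5e4, seed = 2,
                                     margin_voxels = c(6, 6, 4)),
                 "enlarge kernel_dims")
})

test_that("voxel-size mismatch is a hard error and negative activity rejected", {
  ker <- small_kernel()
  at <- voxvol(array(1, c(8, 8, 8)), c(3, 3, 3), "MBq.s")
  expect_error(convolve_vsv(at, ker), "voxel size")
  at2 <- voxvol(array(-1, c(25, 25, 11)), c(2.67, 2.67, 5), "MBq.s")
  expect_error(convolve_vsv(at2, ker), "negative")
  at3 <- voxvol(array(1, c(25, 25, 11)), c(2.67, 2.67, 5), "Bq")
  expect_error(convolve_vsv(at3, ker), "MBq.s")
})

test_that("dose rate from a shifted source shifts identically (translation equivariance)", {
  ker <- small_kernel()
  dims <- c(30, 30, 16)
  a1 <- array(0, dims); a1[14, 14, 8] <- 5e5
  a2 <- array(0, dims); a2[16, 15, 9] <- 5e5
  r1 <- vsv_dose_rate(voxvol(a1, c(2.67, 2.67, 5), "Bq"), ker)
  r2 <- vsv_dose_rate(voxvol(a2, c(2.67, 2.67, 5), "Bq"), ker)
  # interior region well away from the boundary
  expect_equal(unclass(r2)[9:23, 10:23, 6:12],
               unclass(r1)[7:21, 9:22, 5:11], tolerance = 1e-12)
})

test_that("enlarging the kernel never decreases total convolved dose", {
  set.seed(9)
  vol <- array(runif(10 * 10 * 8), c(10, 10, 8))
  at <- voxvol(vol, c(2.67, 2.67, 5), "MBq.s")
  ker_big <- small_kernel()
  shrink <- function(k, by) {
    kd <- dim(k$values)
    idx <- lapply(1:3, function(a) (1 + by[a]):(kd[a] - by[a]))
    structure(list(values = voxvol(unclass(k$values)[idx[[1]], idx[[2]],
                                                     idx[[3]]],
                                   attr(k$values, "voxel_size"),
                                   "Gy/MBq.s"),
                   n_histories = k$n_histories, capture_fraction = NA,
                   scheme = k$scheme), class = "vsv_kernel")
  }
  ker_small <- shrink(ker_big, c(4, 4, 2))
  d_small <- sum(convolve_vsv(at, ker_small, method = "direct"))
  d_big <- sum(convolve_vsv(at, ker_big, method = "direct"))
  expect_gte(d_big, d_small)
})

test_that("density-corrected surrogate boosts lung dose relative to the water kernel", {
  ker <- small_kernel()
  sp <- demo_phantom_spec("torso", c(24, 24, 12), seed = 2)
  ph <- make_phantom(sp)
  water <- vsv_dose_rate(ph$activity, ker)
  corr <- density_corrected_dose_rate(ph$activity, ph$density, ker)
  lung <- unclass(ph$labels) %in% c(2, 6)
  soft <- unclass(ph$labels) == 3
  expect_equal(unclass(corr)[soft], unclass(water)[soft] / 1.0)
  expect_equal(unclass(corr)[lung], unclass(water)[lung] / 0.26)
})
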