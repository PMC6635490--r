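#' Generate a voxel S-value kernel
#'
#' Computes the voxel S-value (VSV) kernel for a nuclide in water: the
#' dose (Gy) delivered to voxel j per unit time-integrated activity
#' (MBq s) in the central source voxel, on a grid with the same voxel
#' size as the target images.  The kernel is produced by running the
#' Monte Carlo engine with a single-voxel source at the centre of a
#' uniform water volume of the kernel extent plus a margin, then cropping
#' to the kernel dimensions.
#'
#' The default kernel dimensions (49 x 49 x 25) are the odd-sized
#' analogue of the 48 x 48 x 24 patch geometry used by the network: a
#' convolution kernel needs a central voxel, and that extent is large
#' enough to cover the dose range of Ga-68 at PET voxel sizes.
#'
#' @param voxel_size mm triple; must equal the target image voxel size.
#' @param kernel_dims odd integer triple.
#' @param n_histories Monte Carlo histories for the kernel run.
#' @param seed integer seed.
#' @param scheme a [decay_scheme()].
#' @param margin_voxels extra water voxels around the kernel extent so
#'   backscatter into the kernel volume is not lost.
#' @param capture_warn_frac warn when the kernel captures less than this
#'   fraction of the non-escaping deposited energy.
#' @return A `vsv_kernel`: `values` (`voxvol`, Gy per MBq s),
#'   `n_histories`, `capture_fraction`, `scheme`.
#' @export
generate_vsv_kernel <- function(voxel_size = c(2.67, 2.67, 5),
                                kernel_dims = c(49, 49, 25),
                                n_histories = 2e6, seed = 1,
                                scheme = decay_scheme(),
                                margin_voxels = c(6, 6, 4),
                                capture_warn_frac = 0.95) {
  kernel_dims <- as.integer(kernel_dims)
  if (any(kernel_dims %% 2L == 0L))
    stop("kernel_dims must be odd in each axis")
  dims <- kernel_dims + 2L * as.integer(margin_voxels)
  centre <- (dims + 1L) %/% 2L
  act <- array(0, dims)
  act[centre[1], centre[2], centre[3]] <- 1      # 1 Bq source voxel
  act <- voxvol(act, voxel_size, "Bq")
  den <- voxvol(array(1.0, dims), voxel_size, "g/cm3")
  dm <- simulate_dose(act, den, scheme, n_histories = n_histories,
                      seed = seed, represented_time_s = 1)
  half <- kernel_dims %/% 2L
  ix <- lapply(1:3, function(a) (centre[a] - half[a]):(centre[a] + half[a]))
  per_decay <- unclass(dm$per_decay)[ix[[1]], ix[[2]], ix[[3]]]
  # energy captured inside the kernel volume vs all deposited energy
  vox_ml <- voxel_volume_ml(act)
  dep_all <- sum(unclass(dm$per_decay) * 1.0 * vox_ml * 1e-3)  # J/decay
  dep_ker <- sum(per_decay * 1.0 * vox_ml * 1e-3)
  capture <- if (dep_all > 0) dep_ker / dep_all else 0
  if (capture < capture_warn_frac)
    warning(sprintf(
      "kernel captures only %.1f%% of non-escaping energy; enlarge kernel_dims",
      100 * capture))
  values <- per_decay * 1e6                      # Gy/decay -> Gy per MBq.s
  structure(list(
    values = voxvol(values, voxel_size, "Gy/MBq.s"),
    n_histories = n_histories,
    capture_fraction = capture,
    scheme = scheme),
    class = "vsv_kernel")
}

#' @export
print.vsv_kernel <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<vsv_kernel> %dx%dx%d, %.3g histories, capture %.2f%%, centre %.3g Gy/MBq.s\n",
    d[1], d[2], d[3], x$n_histories, 100 * x$capture_fraction,
    x$values[(d[1] + 1) / 2, (d[2] + 1) / 2, (d[3] + 1) / 2]))
  invisible(x)
}

# 3D linear convolution of `vol` with centred odd kernel `ker`, zero
# padding, computed in the Fourier domain.
.fft_convolve3 <- function(vol, ker) {
  dv <- dim(vol); dk <- dim(ker)
  dp <- dv + dk - 1L
  pv <- array(0, dp); pv[seq_len(dv[1]), seq_len(dv[2]), seq_len(dv[3])] <- vol
  pk <- array(0, dp); pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- ker
  full <- Re(fft(fft(pv) * fft(pk), inverse = TRUE)) / prod(dp)
  c0 <- (dk + 1L) %/% 2L                          # centre (1-based)
  full[c0[1]:(c0[1] + dv[1] - 1L),
       c0[2]:(c0[2] + dv[2] - 1L),
       c0[3]:(c0[3] + dv[3] - 1L)]
}

#' Convolve time-integrated activity with a VSV kernel
#'
#' Computes the absorbed-dose map `D_j = sum_i A_i * VSV(j <- i)`: the
#' discrete 3D convolution of a time-integrated activity map (MBq s per
#' voxel) with the voxel S-value kernel, with zero padding outside the
#' volume (no activity outside the imaged body).  The convolution is done
#' in the Fourier domain above a size threshold and by direct summation
#' below; both routes agree to floating tolerance.
#'
#' @param a_tilde `voxvol` of time-integrated activity, units `"MBq.s"`.
#' @param kernel a `vsv_kernel` with the same voxel size (no silent
#'   resampling; a mismatch is an error).
#' @param method `"auto"`, `"fft"` or `"direct"`.
#' @return A `voxvol` in Gy.
#' @export
convolve_vsv <- function(a_tilde, kernel, method = c("auto", "fft",
                                                     "direct")) {
  method <- match.arg(method)
  stopifnot(inherits(kernel, "vsv_kernel"))
  if (attr(a_tilde, "units") != "MBq.s")
    stop("`a_tilde` must have units 'MBq.s'")
  vsk <- attr(kernel$values, "voxel_size")
  vsa <- attr(a_tilde, "voxel_size")
  if (max(abs(vsk - vsa)) > 1e-6)
    stop(sprintf("kernel voxel size (%s mm) does not match map (%s mm)",
                 paste(signif(vsk, 6), collapse = "x"),
                 paste(signif(vsa, 6), collapse = "x")))
  if (any(as.numeric(a_tilde) < 0)) stop("negative time-integrated activity")
  vol <- unclass(a_tilde); ker <- unclass(kernel$values)
  use_fft <- method == "fft" ||
    (method == "auto" && prod(dim(vol)) * prod(dim(ker)) > 1e7)
  out <- if (use_fft) {
    .fft_convolve3(vol, ker)
  } else {
    array(.conv3d_direct(as.numeric(vol), dim(vol), as.numeric(ker),
                         dim(ker)), dim(vol))
  }
  out[out < 0] <- 0   # clip FFT round-off
  new_like(a_tilde, out, units = "Gy")
}

#' VSV dose-rate map for an activity frame
#'
#' Per-frame reading of the kernel convolution: an activity frame in
#' Bq/mL (or Bq per voxel) contributes `A` MBq of instantaneous activity
#' per voxel, i.e. `A` MBq s of time-integrated activity per second, so
#' the convolution directly yields Gy/s.
#'
#' @param activity_frame `voxvol`, `"Bq/mL"` or `"Bq"`.
#' @param kernel a `vsv_kernel`.
#' @param method passed to [convolve_vsv()].
#' @return A `voxvol` in Gy/s.
#' @export
vsv_dose_rate <- function(activity_frame, kernel, method = "auto") {
  if (attr(activity_frame, "units") == "Bq/mL")
    activity_frame <- concentration_to_activity(activity_frame)
  stopifnot(attr(activity_frame, "units") == "Bq")
  a_mbqs <- new_like(activity_frame, unclass(activity_frame) * 1e-6,
                     units = "MBq.s")
  d <- convolve_vsv(a_mbqs, kernel, method = method)
  new_like(d, unclass(d), units = "Gy/s")
}

#' Density-corrected kernel dose-rate surrogate
#'
#' Fast deterministic ground-truth surrogate for training experiments:
#' the water-kernel dose rate divided by the local relative mass density.
#' This applies the first-order heterogeneity correction that the plain
#' water kernel lacks (deposited energy per unit mass scales inversely
#' with local density, which is why a water kernel underestimates lung
#' dose), giving a noise-free target that a network seeing the CT volume
#' can learn but that the uncorrected VSV baseline cannot match.
#'
#' @param activity_frame `voxvol`, `"Bq/mL"` or `"Bq"`.
#' @param density `voxvol`, `"g/cm3"`.
#' @param kernel a `vsv_kernel`.
#' @param min_density densities are clamped below this value (g/cm3)
#'   before division, keeping air voxels finite.
#' @return A `voxvol` in Gy/s.
#' @export
density_corrected_dose_rate <- function(activity_frame, density, kernel,
                                        min_density = 0.05) {
  check_same_grid(activity_frame, density)
  water <- vsv_dose_rate(activity_frame, kernel)
  rho <- pmax(unclass(density), min_density)
  new_like(water, unclass(water) / rho, units = "Gy/s")
}
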