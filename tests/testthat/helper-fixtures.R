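# Shared fixtures, built once per test run.  The kernel is the expensive
# one; a small 17x17x9 kernel at the PET voxel size is enough for every
# desk-scale check here.

fixture_env <- new.env()

small_kernel <- function() {
  if (is.null(fixture_env$kernel))
    fixture_env$kernel <- generate_vsv_kernel(
      kernel_dims = c(17, 17, 9), n_histories = 1e6, seed = 11,
      margin_voxels = c(4, 4, 3))
  fixture_env$kernel
}

# uniform water volume pair (activity + density) on a small grid
water_pair <- function(dims = c(16, 16, 12), activity = 1000,
                       voxel_size = c(2.67, 2.67, 5)) {
  list(activity = voxvol(array(activity, dims), voxel_size, "Bq/mL"),
       density = voxvol(array(1, dims), voxel_size, "g/cm3"))
}

# brute-force triple-loop convolution oracle: out[j] = sum_i in[i] k[j-i+c]
brute_convolve3 <- function(vol, ker) {
  dv <- dim(vol); dk <- dim(ker)
  ctr <- (dk + 1L) %/% 2L
  out <- array(0, dv)
  for (sx in seq_len(dv[1])) for (sy in seq_len(dv[2]))
    for (sz in seq_len(dv[3])) {
      a <- vol[sx, sy, sz]
      if (a == 0) next
      for (kx in seq_len(dk[1])) for (ky in seq_len(dk[2]))
        for (kz in seq_len(dk[3])) {
          jx <- sx + kx - ctr[1]; jy <- sy + ky - ctr[2]
          jz <- sz + kz - ctr[3]
          if (jx >= 1 && jx <= dv[1] && jy >= 1 && jy <= dv[2] &&
              jz >= 1 && jz <= dv[3])
            out[jx, jy, jz] <- out[jx, jy, jz] + a * ker[kx, ky, kz]
        }
    }
  out
}

# brute-force patch-position enumeration oracle
brute_enumerate <- function(volume_dims, patch_dims, offsets) {
  out <- NULL
  for (z0 in seq.int(0, volume_dims[3] - patch_dims[3], by = offsets[3]))
    for (y0 in seq.int(0, volume_dims[2] - patch_dims[2], by = offsets[2]))
      for (x0 in seq.int(0, volume_dims[1] - patch_dims[1],
                         by = offsets[1]))
        out <- rbind(out, c(x0, y0, z0))
  out
}
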