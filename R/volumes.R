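#' @useDynLib voxdose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx fft quantile median sd rnorm runif setNames
#' @importFrom utils read.csv write.csv packageVersion tail
NULL

#' Voxel volume container
#'
#' A `voxvol` is a plain 3D numeric array carrying the metadata every
#' multi-volume operation in the package needs: the voxel size in mm, a
#' mandatory units tag, and free-form provenance.  All dose, activity,
#' density and label volumes in the package are `voxvol` objects, so grid
#' compatibility can be checked uniformly before any two volumes are
#' combined.
#'
#' @param data 3D numeric array.
#' @param voxel_size numeric length-3, voxel edge lengths in mm (x, y, z).
#' @param units units tag, one of `"Bq/mL"`, `"Bq"`, `"HU"`, `"g/cm3"`,
#'   `"Gy"`, `"Gy/s"`, `"Gy/MBq.s"`, `"MBq.s"`, `"label"`, `"mask"`,
#'   `"fraction"`, `"arb"`.
#' @param time_min optional acquisition time stamp in minutes.
#' @param provenance optional named list recording how the volume was made.
#' @return A `voxvol` object (numeric array with attributes).
#' @examples
#' v <- voxvol(array(0, c(8, 8, 4)), c(2.67, 2.67, 5), "Bq/mL")
#' voxel_volume_ml(v)
#' @export
voxvol <- function(data, voxel_size, units, time_min = NULL,
                   provenance = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive numbers (mm)")
  units <- match.arg(units, c("Bq/mL", "Bq", "HU", "g/cm3", "Gy", "Gy/s",
                              "Gy/MBq.s", "MBq.s", "label", "mask",
                              "fraction", "arb"))
  structure(data,
            voxel_size = voxel_size,
            units = units,
            time_min = time_min,
            provenance = provenance,
            class = c("voxvol", "array"))
}

#' @export
print.voxvol <- function(x, ...) {
  d <- dim(x)
  vs <- attr(x, "voxel_size")
  cat(sprintf("<voxvol> %d x %d x %d voxels of %.4g x %.4g x %.4g mm [%s]\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3], attr(x, "units")))
  rng <- range(x)
  cat(sprintf("  range [%.4g, %.4g]", rng[1], rng[2]))
  if (!is.null(attr(x, "time_min")))
    cat(sprintf("  t = %g min", attr(x, "time_min")))
  cat("\n")
  invisible(x)
}

#' @rdname voxvol
#' @param x object to test.
#' @export
is_voxvol <- function(x) inherits(x, "voxvol")

#' Voxel volume in millilitres
#'
#' @param x a `voxvol`, or a numeric length-3 voxel size in mm.
#' @return Volume of one voxel in mL (= cm^3).
#' @export
voxel_volume_ml <- function(x) {
  vs <- if (is_voxvol(x)) attr(x, "voxel_size") else as.numeric(x)
  prod(vs) / 1000  # mm^3 -> cm^3
}

#' Check that volumes share one grid
#'
#' Stops with an error naming both grids unless all supplied volumes have
#' identical dimensions and voxel sizes (voxel size compared to 1e-6 mm).
#'
#' @param ... two or more `voxvol` objects.
#' @return Invisibly `TRUE`.
#' @export
check_same_grid <- function(...) {
  vols <- list(...)
  if (length(vols) < 2L) return(invisible(TRUE))
  ref <- vols[[1L]]
  fmt <- function(v) sprintf("%sx%sx%s @ %s mm", dim(v)[1], dim(v)[2],
                             dim(v)[3],
                             paste(signif(attr(v, "voxel_size"), 6),
                                   collapse = "x"))
  for (v in vols[-1L]) {
    if (!identical(dim(v), dim(ref)) ||
        max(abs(attr(v, "voxel_size") - attr(ref, "voxel_size"))) > 1e-6)
      stop(sprintf("grid mismatch: [%s] vs [%s]", fmt(ref), fmt(v)))
  }
  invisible(TRUE)
}

new_like <- function(template, data, units = attr(template, "units")) {
  voxvol(data, attr(template, "voxel_size"), units,
         time_min = attr(template, "time_min"))
}

#' Read / write volumes as NIfTI
#'
#' Volumes are exchanged as NIfTI (`.nii` / `.nii.gz`) with the voxel size
#' encoded in the header and the units tag plus provenance in a JSON
#' sidecar (`<file>.json`).  Writing always emits the sidecar; reading
#' without a sidecar requires an explicit `units` argument, so no unit-less
#' dose or activity volume can enter downstream computation.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param units units tag; overrides/replaces the sidecar value.
#' @return `read_volume` returns a `voxvol`; `write_volume` returns `path`
#'   invisibly.
#' @export
read_volume <- function(path, units = NULL) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  if (is.null(units)) units <- meta$units
  if (is.null(units))
    stop("no units recorded for ", path,
         ": missing sidecar and no `units` given")
  arr <- array(as.numeric(img), dim = dim(img))
  voxvol(arr, vs, units,
         time_min = meta$time_min,
         provenance = meta$provenance)
}

#' @rdname read_volume
#' @param vol a `voxvol` to write.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_voxvol(vol))
  img <- RNifti::asNifti(array(as.numeric(vol), dim = dim(vol)))
  RNifti::pixdim(img) <- attr(vol, "voxel_size")
  RNifti::writeNifti(img, path, datatype = "float")
  meta <- list(units = attr(vol, "units"))
  if (!is.null(attr(vol, "time_min"))) meta$time_min <- attr(vol, "time_min")
  if (!is.null(attr(vol, "provenance")))
    meta$provenance <- attr(vol, "provenance")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Resample a volume onto a reference grid
#'
#' Matches a CT-like volume to the PET grid: trilinear interpolation for
#' continuous data, nearest neighbour for label/mask volumes.  Grids are
#' assumed co-registered at a shared corner origin.
#'
#' @param vol `voxvol` to resample.
#' @param ref `voxvol` defining the target grid.
#' @param method `"trilinear"` or `"nearest"`; defaults to `"nearest"` for
#'   label/mask units, `"trilinear"` otherwise.
#' @return A `voxvol` on `ref`'s grid with `vol`'s units.
#' @export
resample_to <- function(vol, ref, method = NULL) {
  if (is.null(method))
    method <- if (attr(vol, "units") %in% c("label", "mask"))
      "nearest" else "trilinear"
  method <- match.arg(method, c("trilinear", "nearest"))
  dv <- dim(vol); dr <- dim(ref)
  vsv <- attr(vol, "voxel_size"); vsr <- attr(ref, "voxel_size")
  # physical centre of target voxel k (0-based): (k + 0.5) * vsr
  out <- array(0, dr)
  idx <- lapply(1:3, function(a) ((seq_len(dr[a]) - 0.5) * vsr[a]) /
                  vsv[a] + 0.5)  # continuous 1-based source coordinate
  if (method == "nearest") {
    ix <- pmin(pmax(round(idx[[1]]), 1L), dv[1])
    iy <- pmin(pmax(round(idx[[2]]), 1L), dv[2])
    iz <- pmin(pmax(round(idx[[3]]), 1L), dv[3])
    out <- vol[ix, iy, iz, drop = FALSE]
    dim(out) <- dr
  } else {
    out <- trilinear_resample(as.numeric(vol), dim(vol),
                              idx[[1]], idx[[2]], idx[[3]])
    dim(out) <- dr
  }
  voxvol(out, vsr, attr(vol, "units"), time_min = attr(vol, "time_min"))
}
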