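#' Organ specification for synthetic phantoms
#'
#' Describes one organ as a geometric primitive filled with a single
#' material and a uniform initial activity concentration.  Voxels whose
#' centres fall inside the primitive are assigned wholly to the organ;
#' when organs overlap, the last-listed organ wins.
#'
#' @param label positive integer label id (unique within a phantom).
#' @param name organ name.
#' @param shape `"ellipsoid"` or `"cuboid"`.
#' @param center numeric length-3, centre in voxel units (1-based,
#'   fractional allowed).
#' @param semi_axes numeric length-3, semi-axes (ellipsoid) or half-widths
#'   (cuboid) in voxel units per axis.
#' @param material material tag from [material_table()].
#' @param activity initial activity concentration in Bq/mL (>= 0).
#' @param half_time_min effective clearance half-time in minutes
#'   (`Inf` for no clearance).
#' @return An `organ_spec` list.
#' @export
organ_spec <- function(label, name, shape, center, semi_axes, material,
                       activity = 0, half_time_min = Inf) {
  shape <- match.arg(shape, c("ellipsoid", "cuboid"))
  material <- match.arg(material, material_table()$material)
  stopifnot(length(center) == 3L, length(semi_axes) == 3L,
            all(semi_axes > 0), label >= 1, activity >= 0)
  if (!is.infinite(half_time_min) && half_time_min <= 0)
    stop("`half_time_min` must be positive")
  structure(list(label = as.integer(label), name = name, shape = shape,
                 center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 material = material, activity = activity,
                 half_time_min = half_time_min),
            class = "organ_spec")
}

#' Phantom specification
#'
#' Defines a synthetic co-registered PET/CT-like phantom: grid geometry, a
#' list of organs ([organ_spec()]) and a background material.  The default
#' grid is a desk-scale 64 x 64 x 32 volume at the 2.67 x 2.67 x 5 mm
#' voxel size typical of whole-body PET reconstructions, which preserves
#' the patch-geometry feasibility of full-size grids.
#'
#' @param grid_dims integer length-3, voxel counts per axis.
#' @param voxel_size numeric length-3 voxel size in mm.
#' @param organs list of [organ_spec()] objects.
#' @param background material tag for voxels covered by no organ.
#' @param background_activity activity concentration of the background
#'   compartment in Bq/mL (decays with the physical half-life).
#' @param seed integer seed recorded with the phantom (generation itself is
#'   deterministic; the seed feeds downstream stochastic stages).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_dims = c(64, 64, 32),
                         voxel_size = c(2.67, 2.67, 5),
                         organs = list(),
                         background = "air",
                         background_activity = 0,
                         seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 1),
            length(voxel_size) == 3L, all(voxel_size > 0),
            background_activity >= 0)
  background <- match.arg(background, material_table()$material)
  labels <- vapply(organs, function(o) o$label, integer(1))
  if (anyDuplicated(labels)) stop("duplicate organ labels")
  for (o in organs) {
    if (!inherits(o, "organ_spec")) stop("organs must be organ_spec objects")
    lo <- o$center - o$semi_axes; hi <- o$center + o$semi_axes
    if (any(lo < 0.5) || any(hi > grid_dims + 0.5))
      stop(sprintf("organ '%s' extends outside the grid", o$name))
  }
  structure(list(grid_dims = grid_dims, voxel_size = as.numeric(voxel_size),
                 organs = organs, background = background,
                 background_activity = background_activity,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic phantom
#'
#' Rasterizes a [phantom_spec()] into four co-registered volumes: activity
#' concentration (Bq/mL), CT number (HU), mass density (g/cm3) and integer
#' organ labels.  A voxel belongs to an organ when its centre lies inside
#' the primitive; overlapping organs resolve to the last listed.  CT
#' values are the material table's nominal HU and densities come from
#' [hu_to_density()], so the CT and density volumes are exactly
#' consistent.  Generation is deterministic: the same spec always yields
#' bit-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom` list with elements `activity`, `ct`, `density`,
#'   `labels` (all `voxvol`) and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_dims
  mt <- material_table()
  hu_of <- setNames(mt$hu, mt$material)

  lab <- array(0L, d)
  act <- array(0, d)
  ct  <- array(hu_of[[spec$background]], d)

  cx <- seq_len(d[1]); cy <- seq_len(d[2]); cz <- seq_len(d[3])
  for (o in spec$organs) {
    if (o$shape == "ellipsoid") {
      ux <- ((cx - o$center[1]) / o$semi_axes[1])^2
      uy <- ((cy - o$center[2]) / o$semi_axes[2])^2
      uz <- ((cz - o$center[3]) / o$semi_axes[3])^2
      inside <- outer(outer(ux, uy, `+`), uz, `+`) <= 1
    } else {
      ux <- abs(cx - o$center[1]) <= o$semi_axes[1]
      uy <- abs(cy - o$center[2]) <= o$semi_axes[2]
      uz <- abs(cz - o$center[3]) <= o$semi_axes[3]
      inside <- outer(outer(ux, uy, `&`), uz, `&`)
    }
    if (!any(inside))
      stop(sprintf("organ '%s' covers zero voxels", o$name))
    lab[inside] <- o$label
    act[inside] <- o$activity
    ct[inside]  <- hu_of[[o$material]]
  }
  if (spec$background_activity > 0) act[lab == 0L] <- spec$background_activity

  vs <- spec$voxel_size
  prov <- list(stage = "phantom", seed = spec$seed)
  list(activity = voxvol(act, vs, "Bq/mL", time_min = 0, provenance = prov),
       ct       = voxvol(ct, vs, "HU", provenance = prov),
       density  = voxvol(hu_to_density(ct), vs, "g/cm3", provenance = prov),
       labels   = voxvol(lab + 0, vs, "label", provenance = prov),
       spec     = spec)
}

#' Physical half-life of Ga-68 in minutes
#' @export
GA68_HALF_LIFE_MIN <- 67.71

#' Generate a dynamic activity series
#'
#' Applies per-organ mono-exponential clearance to a phantom's initial
#' activity volume: frame at time t scales each organ's concentration by
#' 2^(-t / T_eff) using that organ's effective half-time, while the
#' background compartment decays with the physical half-life of the
#' nuclide.  The default schedule is the eight-frame dynamic acquisition
#' at 1, 4, 7, 10, 15, 30, 46 and 62 min post-injection.
#'
#' @param phantom result of [make_phantom()].
#' @param time_points_min strictly increasing times in minutes.
#' @param physical_half_life_min background (physical) half-life; defaults
#'   to Ga-68.
#' @return A `dynamic_series` list with `time_points_min` and `frames`
#'   (list of activity `voxvol`s, one per time point).
#' @export
make_dynamic_series <- function(phantom,
                                time_points_min = c(1, 4, 7, 10, 15, 30,
                                                    46, 62),
                                physical_half_life_min =
                                  GA68_HALF_LIFE_MIN) {
  t <- as.numeric(time_points_min)
  if (length(t) < 1L || any(diff(t) <= 0))
    stop("time points must be strictly increasing")
  spec <- phantom$spec
  for (o in spec$organs)
    if (!is.infinite(o$half_time_min) && o$half_time_min <= 0)
      stop("non-positive organ half-time")
  lab <- phantom$labels
  act0 <- phantom$activity
  frames <- lapply(t, function(tt) {
    f <- array(0, dim(act0))
    bg <- lab == 0L
    f[bg] <- act0[bg] * 2^(-tt / physical_half_life_min)
    for (o in spec$organs) {
      m <- lab == o$label
      f[m] <- act0[m] * 2^(-tt / o$half_time_min)
    }
    voxvol(f, attr(act0, "voxel_size"), "Bq/mL", time_min = tt)
  })
  structure(list(time_points_min = t, frames = frames),
            class = "dynamic_series")
}

#' Convert an activity-concentration volume to per-voxel activity
#'
#' PET-style volumes store concentration (Bq/mL); simulation and kernel
#' convolution need activity per voxel.  Multiplies by the voxel volume.
#'
#' @param act a `voxvol` with units `"Bq/mL"`.
#' @return A `voxvol` with units `"Bq"`.
#' @export
concentration_to_activity <- function(act) {
  stopifnot(attr(act, "units") == "Bq/mL")
  new_like(act, unclass(act) * voxel_volume_ml(act), units = "Bq")
}
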