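#' Desk-scale study phantoms
#'
#' Preset synthetic phantoms emulating the study conditions the package
#' is exercised under: heterogeneous organ activity, lung/bone/air
#' density contrast and per-organ clearance.  All presets use the
#' 2.67 x 2.67 x 5 mm PET voxel size on desk-scale grids.
#'
#' * `"water_sphere"` — uniform water across the whole grid with an
#'   active soft-tissue ellipsoid: the homogeneous-medium case where
#'   kernel convolution and Monte Carlo must agree.
#' * `"torso"` — soft-tissue body ellipsoid containing a low-density
#'   lung, a high-uptake liver-like organ, a heart-like organ and a bone
#'   block, in air.  Organ centres and activities are jittered by the
#'   seed so different seeds give structurally similar but distinct
#'   subjects.
#'
#' @param kind `"water_sphere"` or `"torso"`.
#' @param grid_dims integer triple (default 32 x 32 x 16).
#' @param seed integer; controls the jitter of organ geometry/uptake.
#' @return A [phantom_spec()].
#' @export
demo_phantom_spec <- function(kind = c("torso", "water_sphere"),
                              grid_dims = c(32, 32, 16), seed = 1L) {
  kind <- match.arg(kind)
  g <- as.numeric(grid_dims)
  ctr <- (g + 1) / 2
  if (kind == "water_sphere") {
    organs <- list(
      organ_spec(1L, "source", "ellipsoid", ctr, g * 0.28,
                 material = "soft", activity = 5000,
                 half_time_min = 50))
    return(phantom_spec(grid_dims, organs = organs, background = "soft",
                        background_activity = 200, seed = seed))
  }
  # thorax-like torso: two large lungs (a realistic chest is mostly
  # lung by volume), a heart between them, a liver-like high-uptake
  # organ below the right lung and a spine block.  Seeded jitter on
  # centres (+/- 4.5% of the grid per axis, so organs stay inside the
  # body on any grid size) and uptake (+/- 20%).
  u <- sample_int_seeded(3000, 16, seed) / 3000   # reproducible uniforms
  jg <- mean(g)
  j <- function(i) (u[i] - 0.5) * 0.09 * jg
  s <- function(i) 0.8 + 0.4 * u[i]
  body_ax <- g * c(0.44, 0.44, 0.47)
  organs <- list(
    organ_spec(1L, "body", "ellipsoid", ctr, body_ax,
               material = "soft", activity = 400 * s(1),
               half_time_min = 60),
    organ_spec(2L, "lung", "ellipsoid",
               ctr + c(-g[1] * 0.2 + j(1), j(2), g[3] * 0.1 + j(3)),
               g * c(0.18, 0.26, 0.3), material = "lung",
               activity = 500 * s(2), half_time_min = 45),
    organ_spec(6L, "lung_r", "ellipsoid",
               ctr + c(g[1] * 0.2 + j(11), j(12), g[3] * 0.12 + j(13)),
               g * c(0.17, 0.25, 0.28), material = "lung",
               activity = 500 * s(6), half_time_min = 45),
    organ_spec(3L, "liver", "ellipsoid",
               ctr + c(g[1] * 0.16 + j(4), j(5), -g[3] * 0.22 + j(6)),
               g * c(0.18, 0.22, 0.16), material = "soft",
               activity = 2500 * s(3), half_time_min = 55),
    organ_spec(4L, "heart", "ellipsoid",
               ctr + c(j(7), -g[2] * 0.14 + j(8), g[3] * 0.08 + j(9)),
               g * c(0.11, 0.11, 0.13), material = "soft",
               activity = 1500 * s(4), half_time_min = 40),
    organ_spec(5L, "bone", "cuboid",
               ctr + c(j(10), g[2] * 0.32, 0),
               g * c(0.07, 0.06, 0.3), material = "bone",
               activity = 150 * s(5), half_time_min = 70))
  phantom_spec(grid_dims, organs = organs, background = "air",
               background_activity = 0, seed = seed)
}

#' Build a complete synthetic dataset for network experiments
#'
#' Generates a phantom, its body mask and a ground-truth dose-rate map
#' for the initial activity frame.  Ground truth is either the Monte
#' Carlo engine (`truth = "mc"`) or the fast density-corrected kernel
#' surrogate (`truth = "kernel"`, noise free; see
#' [density_corrected_dose_rate()]).
#'
#' @param spec a [phantom_spec()].
#' @param kernel a `vsv_kernel` (required for `truth = "kernel"` and for
#'   the VSV baseline).
#' @param truth `"kernel"` or `"mc"`.
#' @param n_histories histories for `truth = "mc"`.
#' @param seed integer seed for the MC run.
#' @return List with `voxvol`s `pet` (Bq/mL), `ct` (HU), `density`,
#'   `labels`, `mask`, `dose` (ground-truth Gy/s) and the `phantom`.
#' @export
demo_dataset <- function(spec, kernel = NULL,
                         truth = c("kernel", "mc"),
                         n_histories = 2e6, seed = spec$seed) {
  truth <- match.arg(truth)
  ph <- make_phantom(spec)
  mask <- make_body_mask(ph$ct)
  dose <- if (truth == "kernel") {
    if (is.null(kernel)) stop("kernel truth requires a vsv_kernel")
    density_corrected_dose_rate(ph$activity, ph$density, kernel)
  } else {
    mc_dose_rate(ph$activity, ph$density, n_histories = n_histories,
                 seed = seed)
  }
  list(pet = ph$activity, ct = ph$ct, density = ph$density,
       labels = ph$labels, mask = mask, dose = dose, phantom = ph)
}
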