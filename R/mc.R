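MEV_TO_J <- 1.602176634e-13

#' Radionuclide decay scheme
#'
#' Emission data consumed by the Monte Carlo engine.  The default is
#' Ga-68: positron branching ratio 0.889 with mean positron kinetic
#' energy 0.836 MeV, the 1.077 MeV nuclear gamma at 3.2% yield, and a
#' physical half-life of 67.71 min (values from the NNDC / Table of
#' Isotopes evaluation for Ga-68; all overridable).
#'
#' @param positron_yield positrons per decay, in \[0, 1\].
#' @param positron_mean_energy mean positron kinetic energy, MeV.
#' @param annihilation_photon_energy MeV, 0.511 per annihilation photon.
#' @param gamma_lines data.frame with columns `energy_mev`, `yield`.
#' @param physical_half_life_min minutes.
#' @return A `decay_scheme` list.
#' @export
decay_scheme <- function(positron_yield = 0.889,
                         positron_mean_energy = 0.836,
                         annihilation_photon_energy = 0.51099895,
                         gamma_lines = data.frame(energy_mev = 1.077,
                                                  yield = 0.032),
                         physical_half_life_min = GA68_HALF_LIFE_MIN) {
  stopifnot(positron_yield >= 0, positron_yield <= 1,
            positron_mean_energy > 0, annihilation_photon_energy > 0,
            physical_half_life_min > 0,
            all(gamma_lines$yield >= 0), all(gamma_lines$yield <= 1),
            all(gamma_lines$energy_mev > 0))
  structure(list(positron_yield = positron_yield,
                 positron_mean_energy = positron_mean_energy,
                 annihilation_photon_energy = annihilation_photon_energy,
                 gamma_lines = gamma_lines,
                 physical_half_life_min = physical_half_life_min),
            class = "decay_scheme")
}

#' Mean energy emitted per decay
#'
#' Analytic emitted-energy budget of a [decay_scheme()]: positron kinetic
#' energy plus both annihilation photons (weighted by the positron yield)
#' plus all gamma lines weighted by their yields.  Used to check energy
#' conservation of the transport engine.
#'
#' @param scheme a [decay_scheme()].
#' @return Energy in MeV per decay.
#' @export
emitted_energy_per_decay <- function(scheme) {
  scheme$positron_yield *
    (scheme$positron_mean_energy + 2 * scheme$annihilation_photon_energy) +
    sum(scheme$gamma_lines$energy_mev * scheme$gamma_lines$yield)
}

#' Simulate voxel dose deposition
#'
#' Runs the simplified voxel Monte Carlo engine: decays are sampled from
#' the activity distribution (per-voxel multinomial, uniform position
#' within the voxel), positron kinetic energy is deposited locally in the
#' source voxel, and the annihilation photons plus gamma lines are
#' transported by Woodcock tracking through the density volume with
#' density-scaled water cross-sections (Klein-Nishina Compton +
#' tabulated photoelectric, 10 keV cutoff).  Histories are split into
#' `n_batches` independent batches for uncertainty estimation.
#'
#' The tally is normalized per simulated decay and scaled to the number
#' of decays the map represents: `sum(activity) * represented_time_s`.
#' With `represented_time_s = 1` the returned values are numerically the
#' dose rate in Gy/s at the frame's activity.
#'
#' @param activity `voxvol` of per-voxel activity (`"Bq"`) or activity
#'   concentration (`"Bq/mL"`, converted internally).
#' @param density `voxvol` of mass density (`"g/cm3"`) on the same grid.
#' @param scheme a [decay_scheme()].
#' @param n_histories number of simulated decays (> 0).
#' @param seed integer seed; fixed seed gives bit-identical tallies.
#' @param represented_time_s duration the decays represent, seconds.
#' @param n_batches number of statistical batches (default 10).
#' @param cutoff_mev photon tracking cutoff (local deposition below).
#' @return A `dose_map` list: `dose` (`voxvol`, Gy), `rel_uncertainty`
#'   (`voxvol`, fractional standard error of the mean, 0 where dose is 0),
#'   `per_decay` (`voxvol`, Gy per decay), `n_histories`, `n_decays`,
#'   `energy` (emitted / deposited / escaped, MeV per simulated history).
#' @export
simulate_dose <- function(activity, density, scheme = decay_scheme(),
                          n_histories, seed,
                          represented_time_s = 1,
                          n_batches = 10, cutoff_mev = 0.010) {
  stopifnot(inherits(scheme, "decay_scheme"), n_histories > 0,
            represented_time_s > 0, n_batches >= 1)
  check_same_grid(activity, density)
  if (attr(activity, "units") == "Bq/mL")
    activity <- concentration_to_activity(activity)
  stopifnot(attr(activity, "units") == "Bq",
            attr(density, "units") == "g/cm3")
  atot <- sum(activity)
  if (atot <= 0) {
    warning("total activity is zero; returning zero dose map")
    z <- new_like(density, array(0, dim(density)), units = "Gy")
    return(structure(list(dose = z, rel_uncertainty = z, per_decay = z,
                          n_histories = n_histories, n_decays = 0,
                          energy = c(emitted = 0, deposited = 0,
                                     escaped = 0)),
                     class = "dose_map"))
  }
  res <- .mc_run(as.numeric(activity), dim(activity),
                 attr(activity, "voxel_size"), as.numeric(density),
                 scheme$positron_yield, scheme$positron_mean_energy,
                 scheme$annihilation_photon_energy,
                 as.numeric(scheme$gamma_lines$energy_mev),
                 as.numeric(scheme$gamma_lines$yield),
                 n_histories, as.integer(n_batches), cutoff_mev,
                 as.integer(seed))
  vox_ml <- voxel_volume_ml(activity)
  mass_kg <- as.numeric(density) * vox_ml * 1e-3   # g -> kg
  edep <- rowSums(res$edep_mev)                     # MeV over all batches
  per_decay <- ifelse(mass_kg > 0, edep * MEV_TO_J / mass_kg, 0) /
    res$n_histories
  dim(per_decay) <- dim(density)

  # batch statistics: relative standard error of the per-voxel mean
  nb <- ncol(res$edep_mev)
  if (nb >= 2) {
    bm <- res$edep_mev / (res$n_histories / nb)     # per-decay, per batch
    mu <- rowMeans(bm)
    sdb <- sqrt(pmax(rowSums((bm - mu)^2) / (nb - 1), 0))
    se <- sdb / sqrt(nb)
    rel <- ifelse(mu > 0, se / mu, 0)
  } else {
    rel <- rep(0, length(edep))
  }
  dim(rel) <- dim(density)

  n_decays <- atot * represented_time_s
  dose <- per_decay * n_decays
  structure(list(
    dose = new_like(density, dose, units = "Gy"),
    rel_uncertainty = new_like(density, rel, units = "fraction"),
    per_decay = new_like(density, per_decay, units = "Gy"),
    n_histories = res$n_histories,
    n_decays = n_decays,
    energy = c(emitted = sum(res$emitted_mev) / res$n_histories,
               deposited = sum(res$edep_mev) / res$n_histories,
               escaped = sum(res$escaped_mev) / res$n_histories)),
    class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map> %.3g histories, %.4g decays represented\n",
              x$n_histories, x$n_decays))
  cat(sprintf("  energy/decay: emitted %.4g, deposited %.4g, escaped %.4g MeV\n",
              x$energy["emitted"], x$energy["deposited"],
              x$energy["escaped"]))
  invisible(x)
}

#' Convert a dose map to a dose-rate map
#'
#' Divides the dose by the represented duration; the relative uncertainty
#' map is carried through unchanged.
#'
#' @param dose_map result of [simulate_dose()].
#' @param represented_duration_s duration in seconds (> 0).
#' @return A `voxvol` in Gy/s with the uncertainty map attached as
#'   attribute `rel_uncertainty`.
#' @export
dose_to_rate <- function(dose_map, represented_duration_s) {
  stopifnot(represented_duration_s > 0)
  r <- new_like(dose_map$dose,
                unclass(dose_map$dose) / represented_duration_s,
                units = "Gy/s")
  attr(r, "rel_uncertainty") <- dose_map$rel_uncertainty
  r
}

#' Monte Carlo dose-rate map for an activity frame
#'
#' Convenience wrapper: simulates the frame's activity distribution and
#' returns the instantaneous dose-rate map in Gy/s (per-decay dose scaled
#' by the frame's total activity in Bq).
#'
#' @inheritParams simulate_dose
#' @return A `voxvol` in Gy/s (attributes as [dose_to_rate()]).
#' @export
mc_dose_rate <- function(activity, density, scheme = decay_scheme(),
                         n_histories, seed, n_batches = 10) {
  dm <- simulate_dose(activity, density, scheme, n_histories, seed,
                      represented_time_s = 1, n_batches = n_batches)
  dose_to_rate(dm, 1)
}

#' Per-voxel uncertainty from independent batches
#'
#' Batch-statistics uncertainty estimate: relative standard error of the
#' per-voxel mean over independent dose batches, with summary quantiles
#' over voxels receiving dose.
#'
#' @param batches list of >= 2 `voxvol` dose maps from independent runs.
#' @return List with `rel_se` (`voxvol`) and `summary` (quantiles over
#'   voxels with non-zero mean dose).
#' @export
estimate_uncertainty <- function(batches) {
  stopifnot(length(batches) >= 2L)
  do.call(check_same_grid, batches)
  m <- sapply(batches, as.numeric)
  mu <- rowMeans(m)
  se <- apply(m, 1, sd) / sqrt(ncol(m))
  rel <- ifelse(mu > 0, se / mu, 0)
  dim(rel) <- dim(batches[[1L]])
  list(rel_se = new_like(batches[[1L]], rel, units = "fraction"),
       summary = quantile(rel[mu > 0], c(0.05, 0.25, 0.5, 0.75, 0.95)))
}

#' Water mass attenuation coefficients used by the engine
#'
#' Exposes the engine's internal water cross-sections (Klein-Nishina
#' Compton, tabulated photoelectric) for inspection.
#'
#' @param energies_mev photon energies in MeV.
#' @return data.frame with columns `energy_mev`, `compton`,
#'   `photoelectric` (cm^2/g).
#' @export
water_mass_attenuation <- function(energies_mev) {
  .water_mass_attenuation(as.numeric(energies_mev))
}
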