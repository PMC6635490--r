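#' Material table
#'
#' Closed five-class material table used by the synthetic phantoms.  Each
#' material carries a nominal CT number (HU) and mass density (g/cm3).
#' The densities follow the usual stylized tissue values (lung inflated
#' ~0.26 g/cm3, adipose 0.95, water-equivalent soft tissue 1.00, compact
#' bone ~1.80); the soft-tissue class is pinned to HU 0 / 1.000 g/cm3 so
#' that water defines the HU scale exactly.
#'
#' @return A data.frame with columns `material`, `hu`, `density`.
#' @examples
#' material_table()
#' @export
material_table <- function() {
  data.frame(
    material = c("air", "lung", "adipose", "soft", "bone"),
    hu       = c(-1000, -740,   -98,        0,     1300),
    density  = c(0.00121, 0.26,  0.95,      1.00,  1.80),
    stringsAsFactors = FALSE
  )
}

# Piecewise-linear HU -> density breakpoints: the material table's nominal
# points.  Monotone non-decreasing by construction; HU 0 maps to exactly
# 1.000 g/cm3 (water).  Values above the last breakpoint extrapolate along
# the last segment's slope; values below -1000 clamp to air.
.hu_breakpoints <- function() {
  mt <- material_table()
  list(hu = mt$hu, density = mt$density)
}

#' Convert CT numbers to mass density
#'
#' Piecewise-linear, monotone non-decreasing mapping from Hounsfield units
#' to mass density in g/cm3, in the spirit of the stoichiometric
#' (Schneider-type) CT calibrations used to import CT volumes into Monte
#' Carlo dose engines.  The breakpoints are the nominal (HU, density)
#' pairs of [material_table()]; HU below -1000 are clamped to air.
#'
#' @param hu numeric vector or array of CT numbers (finite).
#' @return Densities in g/cm3, same shape as `hu`.
#' @examples
#' hu_to_density(c(-1200, -1000, -740, 0, 1300))
#' @export
hu_to_density <- function(hu) {
  if (any(!is.finite(hu))) stop("`hu` must be finite")
  bp <- .hu_breakpoints()
  hu_cl <- pmax(hu, bp$hu[1L])
  out <- approx(bp$hu, bp$density, xout = pmin(hu_cl, max(bp$hu)),
                method = "linear", ties = "ordered")$y
  # linear extrapolation above the last breakpoint
  n <- length(bp$hu)
  slope <- (bp$density[n] - bp$density[n - 1L]) /
    (bp$hu[n] - bp$hu[n - 1L])
  hi <- hu_cl > bp$hu[n]
  if (any(hi)) out[hi] <- bp$density[n] + (hu_cl[hi] - bp$hu[n]) * slope
  if (is.array(hu)) dim(out) <- dim(hu)
  out
}
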