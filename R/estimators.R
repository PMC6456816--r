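# The four estimators. Internal unit discipline: mm everywhere; totals
# are converted to display units (m for length) only in stereoTotals().

#' Cavalieri volume estimator
#'
#' `V = t * a(p) * sum(P)`: slab thickness times the area per grid point
#' times the total number of points hitting the reference space over all
#' systematic sections.
#'
#' @param sumP total point count over sections (non-negative integer).
#' @param ap area per grid point (mm^2).
#' @param t slab thickness (mm).
#' @return volume (mm^3).
#' @export
#' @examples
#' cavalieriVolume(22, ap = 0.59, t = 1) # 12.98
cavalieriVolume <- function(sumP, ap, t) {
  stopIfNot(sumP >= 0, "point count must be non-negative")
  stopIfNot(ap > 0 && t > 0, "a(p) and t must be positive")
  t * ap * sumP
}

#' Capillary length density
#'
#' `Lv = 2 * sum(Q) / sum(A)`: on isotropic uniform random sections the
#' expected number of profiles per unit frame area is half the length
#' density. Pooling across sections is ratio-of-sums (sum the counts, sum
#' the frame areas, divide once), the formula-literal reading of the
#' summed counts.
#'
#' @param sumQ total capillary profile count.
#' @param sumA total counting-frame area (mm^2).
#' @return length density (mm / mm^3 = mm^-2).
#' @export
lengthDensity <- function(sumQ, sumA) {
  stopIfNot(sumQ >= 0, "profile count must be non-negative")
  stopIfNot(sumA > 0, "total frame area must be positive")
  2 * sumQ / sumA
}

#' Capillary volume density
#'
#' `Vv = sum(P_cap) / sum(P_ref)`: the fraction of test points hitting
#' the capillary phase among those hitting the reference space.
#'
#' @param sumPcap points hitting capillary profiles.
#' @param sumPref points hitting the reference space.
#' @return volume fraction (dimensionless, in `[0, 1]`).
#' @export
volumeDensity <- function(sumPcap, sumPref) {
  stopIfNot(sumPcap >= 0, "capillary point count must be non-negative")
  stopIfNot(sumPref > 0, "reference point count must be positive")
  stopIfNot(sumPcap <= sumPref,
            "capillary points cannot exceed reference points")
  sumPcap / sumPref
}

#' Capillary surface density
#'
#' `Sv = 2 * sum(I) / sum(L)`: on isotropic test lines the expected
#' number of boundary intersections per unit line length is half the
#' surface density.
#'
#' @param sumI intersections between test lines and capillary boundaries.
#' @param sumL total test-line length (mm).
#' @return surface density (mm^2 / mm^3 = mm^-1).
#' @export
surfaceDensity <- function(sumI, sumL) {
  stopIfNot(sumI >= 0, "intersection count must be non-negative")
  stopIfNot(sumL > 0, "total line length must be positive")
  2 * sumI / sumL
}

#' Densities to absolute totals
#'
#' Multiplies each density by the reference (white-matter) volume,
#' converting length to metres for display: `L = Lv * Vwm / 1000` (m),
#' `V = Vv * Vwm` (mm^3), `S = Sv * Vwm` (mm^2). Reporting absolute
#' totals rather than densities avoids the reference-space trap when the
#' reference volume itself differs between groups.
#'
#' @param Lv length density (mm^-2).
#' @param Vv volume fraction.
#' @param Sv surface density (mm^-1).
#' @param Vwm reference volume (mm^3).
#' @return named list `L_m`, `Vcap_mm3`, `Scap_mm2`, `Vwm_mm3`.
#' @export
#' @examples
#' stereoTotals(Lv = 966.6, Vv = 6.92e-3, Sv = 8.30, Vwm = 12.87)
stereoTotals <- function(Lv, Vv, Sv, Vwm) {
  stopIfNot(Vwm > 0, "reference volume must be positive")
  stopIfNot(Lv >= 0 && Vv >= 0 && Vv <= 1 && Sv >= 0,
            "densities out of range")
  list(L_m = Lv * Vwm / 1000,
       Vcap_mm3 = Vv * Vwm,
       Scap_mm2 = Sv * Vwm,
       Vwm_mm3 = Vwm)
}
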