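#' @import methods
NULL

#' White-matter reference region
#'
#' An axis-aligned box, or a union of disjoint axis-aligned boxes, standing
#' in for the dissected white matter. The closed-form volume and the exact
#' point-membership test are what make every downstream estimator testable
#' against analytic truth.
#'
#' @slot boxes numeric matrix with one row per box and columns
#'   `xmin, xmax, ymin, ymax, zmin, zmax` (mm).
#' @export
setClass("WMRegion", representation(boxes = "matrix"))

setValidity("WMRegion", function(object) {
  b <- object@boxes
  if (!is.numeric(b) || ncol(b) != 6) {
    return("boxes must be a numeric matrix with 6 columns")
  }
  if (nrow(b) < 1) return("region needs at least one box")
  if (any(!is.finite(b))) return("box coordinates must be finite")
  lo <- b[, c(1, 3, 5), drop = FALSE]
  hi <- b[, c(2, 4, 6), drop = FALSE]
  if (any(hi <= lo)) return("every box dimension must be positive")
  # interiors must be pairwise disjoint so the union volume is additive
  n <- nrow(b)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        overl <- all(b[i, c(2, 4, 6)] > b[j, c(1, 3, 5)] &
                     b[j, c(2, 4, 6)] > b[i, c(1, 3, 5)])
        if (overl) return("box interiors overlap; union volume undefined")
      }
    }
  }
  TRUE
})

#' Capillary network phantom
#'
#' A set of finite cylinders (capillary segments) inside a [WMRegion-class],
#' carrying the exact per-cylinder ground-truth totals: total axis length,
#' total volume `sum(pi r^2 l)` and total lateral surface `sum(2 pi r l)`.
#' Vessels at or above 10 micrometre diameter are stored too (to exercise
#' the capillary filter) but excluded from the capillary truth sums.
#'
#' @slot cylinders numeric matrix, one row per cylinder, columns
#'   `ax, ay, az, bx, by, bz, r` (mm): the two axis endpoints and the radius.
#' @slot region the enclosing [WMRegion-class].
#' @slot truth named list with `L_mm`, `Vcap_mm3`, `Scap_mm2`, `Vwm_mm3`
#'   (capillary-only sums; `Vwm_mm3` is the region volume).
#' @slot meta list of generation settings (orientation mode, seed, ...).
#' @export
setClass("CapillaryNetwork",
  representation(cylinders = "matrix", region = "WMRegion",
                 truth = "list", meta = "list"))

setValidity("CapillaryNetwork", function(object) {
  cyl <- object@cylinders
  if (ncol(cyl) != 7) return("cylinders must have 7 columns (a, b, r)")
  if (nrow(cyl) > 0) {
    len <- sqrt(rowSums((cyl[, 4:6, drop = FALSE] -
                         cyl[, 1:3, drop = FALSE])^2))
    if (any(len <= 0)) return("every cylinder must have positive length")
    if (any(cyl[, 7] <= 0)) return("every cylinder radius must be positive")
    mid <- (cyl[, 1:3, drop = FALSE] + cyl[, 4:6, drop = FALSE]) / 2
    if (!all(containsPoints(object@region, mid))) {
      return("every cylinder midpoint must lie inside the region")
    }
  }
  tr <- object@truth
  need <- c("L_mm", "Vcap_mm3", "Scap_mm2", "Vwm_mm3")
  if (!all(need %in% names(tr))) {
    return(paste("truth must contain", paste(need, collapse = ", ")))
  }
  cap <- cyl[, 7] < 5e-3 # diameter < 10 um
  len <- if (nrow(cyl)) sqrt(rowSums((cyl[, 4:6, drop = FALSE] -
                                      cyl[, 1:3, drop = FALSE])^2)) else 0
  Lc <- sum(len[cap])
  if (abs(tr$L_mm - Lc) > 1e-8 * max(1, Lc)) {
    return("truth$L_mm does not match the cylinder sums")
  }
  TRUE
})

#' Simulated two-group cohort
#'
#' Per-animal ground-truth stereological targets plus a Morris-water-maze
#' escape-latency table, as produced by [generateCohort()]. The networks
#' themselves are materialised lazily (each animal row carries the child
#' seed and calibration needed to regenerate its phantom bit-identically).
#'
#' @slot animals data.frame, one row per animal: id, group, latent factor,
#'   ground-truth totals, radius calibration and child seed.
#' @slot latency tidy data.frame `animal, group, day, trial, latency_s`.
#' @slot config the fully-resolved generating configuration.
#' @export
setClass("StereoCohort",
  representation(animals = "data.frame", latency = "data.frame",
                 config = "list"))

setValidity("StereoCohort", function(object) {
  a <- object@animals
  if (nrow(a) < 4) return("cohort needs at least 2 animals per group")
  if (min(table(a$group)) < 2) return("each group needs n >= 2")
  lat <- object@latency
  if (nrow(lat) && (any(lat$latency_s < 0) || any(lat$latency_s > 60))) {
    return("escape latencies must lie in [0, 60] s")
  }
  TRUE
})
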