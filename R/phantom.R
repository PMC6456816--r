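#' Published calibration targets
#'
#' Group-level reference values for 10-month-old wild-type and Tg2576 mice
#' (white-matter volume; total capillary length, volume, surface area;
#' structure-behaviour correlations) to which the synthetic phantoms are
#' calibrated, together with the probe constants used with them
#' (`a(p) = 0.59` mm^2 point area, `t = 1` mm slab thickness, 10 um
#' capillary diameter cutoff). Values are mean and SD per group; the
#' correlation table pairs final-day escape latency with each capillary
#' total (n = 7 per group).
#'
#' @return a named list with elements `wild_type`, `tg2576`, `table1`,
#'   `ap_mm2`, `t_mm`, `capillaryCutoffUm`, `n`.
#' @export
#' @examples
#' defaultCalibration()$wild_type$L_m
defaultCalibration <- function() {
  list(
    wild_type = list(
      Vwm_mm3 = 12.87, Vwm_sd = 0.44,
      L_m = 12.44, L_sd = 2.64,
      Vcap_mm3 = 0.0891, Vcap_sd = 0.0145,
      Scap_mm2 = 106.81, Scap_sd = 20.17),
    tg2576 = list(
      Vwm_mm3 = 12.33, Vwm_sd = 1.01,
      L_m = 6.90, L_sd = 0.82,
      Vcap_mm3 = 0.0648, Vcap_sd = 0.0167,
      Scap_mm2 = 61.77, Scap_sd = 13.80),
    table1 = data.frame(
      group = rep(c("wild_type", "tg2576"), each = 3),
      measure = rep(c("length", "volume", "surface"), 2),
      r = c(-0.935, -0.978, -0.957, -0.944, -0.817, -0.916),
      p = c(0.002, 0.000, 0.001, 0.001, 0.025, 0.004)),
    ap_mm2 = 0.59, t_mm = 1, capillaryCutoffUm = 10, n = 7)
}

#' Calibrate a radius distribution from capillary totals
#'
#' For a cylinder population, total volume and surface relate to total
#' length through the radius moments: `V = pi E[r^2] L` and
#' `S = 2 pi E[r] L`. Given targets (L, V, S) this solves for the mean and
#' coefficient of variation of a lognormal radius distribution that
#' reproduces all three totals in expectation.
#'
#' @param L_mm total capillary length (mm).
#' @param Vcap_mm3 total capillary volume (mm^3).
#' @param Scap_mm2 total capillary surface area (mm^2).
#' @return list with `meanUm` (mean radius, micrometres) and `cv`.
#' @export
#' @examples
#' calibrateRadius(12440, 0.0891, 106.81) # ~1.37 um, cv ~0.47
calibrateRadius <- function(L_mm, Vcap_mm3, Scap_mm2) {
  stopIfNot(L_mm > 0 && Vcap_mm3 > 0 && Scap_mm2 > 0,
            "totals must all be positive")
  Er <- Scap_mm2 / (2 * pi * L_mm)       # mm
  Er2 <- Vcap_mm3 / (pi * L_mm)          # mm^2
  ratio <- Er2 / Er^2
  cv <- sqrt(max(ratio - 1, 0))
  list(meanUm = Er * 1000, cv = cv)
}

# Moments of a lognormal truncated above at R.
.truncLognormalMoment <- function(mu, sig, R, k) {
  exp(k * mu + k^2 * sig^2 / 2) *
    stats::pnorm((log(R) - mu - k * sig^2) / sig) /
    stats::pnorm((log(R) - mu) / sig)
}

# Lognormal parameters such that, after truncation at rmax, the realised
# mean and CV match the requested ones (fixed-point iteration on the
# first two moments). Without this the upper truncation at the capillary
# cutoff would shave several percent off E[r^2] for wide distributions.
.truncLognormalParams <- function(meanUm, cv, rmaxUm) {
  targetRatio <- 1 + cv^2
  sdlog <- sqrt(log(targetRatio))
  meanlog <- log(meanUm) - sdlog^2 / 2
  for (i in 1:60) {
    m1 <- .truncLognormalMoment(meanlog, sdlog, rmaxUm, 1)
    ratio <- .truncLognormalMoment(meanlog, sdlog, rmaxUm, 2) / m1^2
    meanlog <- meanlog + log(meanUm / m1)
    sdlog <- sqrt(max(sdlog^2 + log(targetRatio / ratio), 1e-8))
  }
  m1 <- .truncLognormalMoment(meanlog, sdlog, rmaxUm, 1)
  ratio <- .truncLognormalMoment(meanlog, sdlog, rmaxUm, 2) / m1^2
  stopIfNot(abs(m1 / meanUm - 1) < 1e-4 &&
              abs(ratio / targetRatio - 1) < 1e-4,
            "radius calibration not attainable below the capillary cutoff")
  list(meanlog = meanlog, sdlog = sdlog)
}

#' Generate a capillary network phantom
#'
#' Fills a region with finite cylinders: midpoints uniform in the region,
#' axis directions either uniform on the sphere (isotropic) or all along a
#' fixed axis (to demonstrate anisotropy bias), radii lognormal (truncated
#' below the 10 um capillary diameter cutoff). Segments have fixed length
#' `segmentLength` except the last, which is trimmed so the realised
#' capillary total length equals `targetLength` exactly. Optional large
#' vessels (diameter >= 10 um) exercise the capillary filter; they are
#' excluded from the truth sums.
#'
#' @param region a [WMRegion-class].
#' @param targetLength total capillary length to place (mm).
#' @param radiusMeanUm mean capillary radius (micrometres); must give a
#'   diameter below 10 um.
#' @param radiusCV coefficient of variation of the radius (0 = fixed).
#' @param orientation `"isotropic"` or `"fixed"`.
#' @param axis unit axis used when `orientation = "fixed"`.
#' @param segmentLength segment length (mm); default 0.05 mm keeps segments
#'   short relative to any realistic region.
#' @param largeVesselCount number of non-capillary decoy vessels.
#' @param largeVesselDiameterUm their diameter (>= 10 um).
#' @param seed integer seed.
#' @return a [CapillaryNetwork-class].
#' @export
#' @examples
#' net <- generateNetwork(boxRegion(c(1, 1, 1)), targetLength = 100, seed = 1)
#' networkTruth(net)$L_mm # exactly 100
generateNetwork <- function(region, targetLength,
                            radiusMeanUm = 1.367, radiusCV = 0.47,
                            orientation = c("isotropic", "fixed"),
                            axis = c(0, 0, 1),
                            segmentLength = 0.05,
                            largeVesselCount = 0,
                            largeVesselDiameterUm = 14,
                            seed = 1) {
  orientation <- match.arg(orientation)
  stopIfNot(targetLength > 0, "targetLength must be positive")
  stopIfNot(segmentLength > 0, "segmentLength must be positive")
  stopIfNot(segmentLength <= targetLength,
            "targetLength unreachable: shorter than one segment")
  stopIfNot(radiusMeanUm > 0 && radiusMeanUm < 5,
            "capillary radius must lie in (0, 5) micrometres")
  stopIfNot(largeVesselDiameterUm >= 10,
            "large-vessel diameter must be >= 10 micrometres")

  nFull <- floor(targetLength / segmentLength + 1e-12)
  rem <- targetLength - nFull * segmentLength
  lens <- if (rem > 1e-9) c(rep(segmentLength, nFull), rem) else {
    rep(segmentLength, nFull)
  }
  n <- length(lens)

  withSeed(seed, {
    mids <- runifRegion(region, n)
    dirs <- if (orientation == "isotropic") runifSphere(n) else {
      u <- axis / sqrt(sum(axis^2))
      matrix(u, nrow = n, ncol = 3, byrow = TRUE)
    }
    radii <- if (radiusCV > 0) {
      rmaxUm <- 4.999 # keep diameters strictly below the 10 um cutoff
      par <- .truncLognormalParams(radiusMeanUm, radiusCV, rmaxUm)
      r <- stats::rlnorm(n, par$meanlog, par$sdlog)
      while (any(bad <- r >= rmaxUm)) {
        r[bad] <- stats::rlnorm(sum(bad), par$meanlog, par$sdlog)
      }
      r / 1000
    } else rep(radiusMeanUm / 1000, n)

    half <- dirs * (lens / 2)
    cyl <- cbind(mids - half, mids + half, radii)

    if (largeVesselCount > 0) {
      lmids <- runifRegion(region, largeVesselCount)
      ldirs <- if (orientation == "isotropic") {
        runifSphere(largeVesselCount)
      } else {
        u <- axis / sqrt(sum(axis^2))
        matrix(u, nrow = largeVesselCount, ncol = 3, byrow = TRUE)
      }
      lhalf <- ldirs * (segmentLength / 2)
      cyl <- rbind(cyl, cbind(lmids - lhalf, lmids + lhalf,
                              largeVesselDiameterUm / 2000))
    }
    colnames(cyl) <- c("ax", "ay", "az", "bx", "by", "bz", "r")

    cap <- cyl[, "r"] < 5e-3
    clen <- sqrt(rowSums((cyl[, 4:6, drop = FALSE] -
                          cyl[, 1:3, drop = FALSE])^2))
    truth <- list(
      L_mm = sum(clen[cap]),
      Vcap_mm3 = sum(pi * cyl[cap, "r"]^2 * clen[cap]),
      Scap_mm2 = sum(2 * pi * cyl[cap, "r"] * clen[cap]),
      Vwm_mm3 = regionVolume(region))

    new("CapillaryNetwork", cylinders = cyl, region = region, truth = truth,
        meta = list(orientation = orientation, axis = axis, seed = seed,
                    segmentLength = segmentLength,
                    targetLength = targetLength))
  })
}

#' @rdname generateNetwork
#' @param x a [CapillaryNetwork-class].
#' @export
setMethod("cylinders", "CapillaryNetwork", function(x) x@cylinders)

#' @rdname generateNetwork
#' @export
setMethod("networkTruth", "CapillaryNetwork", function(x) x@truth)

#' @rdname generateNetwork
#' @export
setMethod("nCylinders", "CapillaryNetwork", function(x) nrow(x@cylinders))

setMethod("show", "CapillaryNetwork", function(object) {
  tr <- object@truth
  cat(sprintf(paste0(
    "CapillaryNetwork: %d cylinders (%s) in %.3f mm^3\n",
    "  truth: L = %.2f mm, V = %.5f mm^3, S = %.3f mm^2\n"),
    nrow(object@cylinders), object@meta$orientation, tr$Vwm_mm3,
    tr$L_mm, tr$Vcap_mm3, tr$Scap_mm2))
  invisible(object)
})

#' Default cohort configuration
#'
#' Fully-resolved settings for [generateCohort()]: per-group means and
#' between-animal CVs for white-matter volume and the three capillary
#' totals (defaults are the published reference values from
#' [defaultCalibration()]), the escape-latency model, and the phantom
#' geometry. The latency model is linear in the standardized capillary
#' driver `z`: on day `d`, mean latency is `intercept[d] - slope * z`,
#' with day-decreasing intercepts (a learning curve), per-trial Gaussian
#' noise, and clamping to the 60 s trial cutoff.
#'
#' @param nPerGroup animals per group.
#' @param seed master seed.
#' @return a named configuration list.
#' @export
cohortConfig <- function(nPerGroup = 7, seed = 1) {
  cal <- defaultCalibration()
  grp <- function(g, intercepts) {
    list(Vwm_mm3 = g$Vwm_mm3, VwmCV = g$Vwm_sd / g$Vwm_mm3,
         L_m = g$L_m, LCV = g$L_sd / g$L_m,
         Vcap_mm3 = g$Vcap_mm3, VcapCV = g$Vcap_sd / g$Vcap_mm3,
         Scap_mm2 = g$Scap_mm2, ScapCV = g$Scap_sd / g$Scap_mm2,
         latencyIntercepts = intercepts)
  }
  list(
    nPerGroup = nPerGroup,
    seed = seed,
    groups = list(
      wild_type = grp(cal$wild_type, c(40, 32, 26, 21, 18, 15)),
      tg2576 = grp(cal$tg2576, c(56, 52, 49, 47, 45, 44))),
    latencySlope = 8,     # s per unit z; with 3 s day-mean noise -> |r| ~ 0.93
    trialNoiseSD = 6,     # s per trial; 4-trial mean SD = 3 s
    trialsPerDay = 4,
    days = 6,
    crossingsMean = 4,    # probe trial: same in both groups by design
    quadrantMean = 35, quadrantSD = 8,
    segmentLength = 0.05,
    regionDims = c(x_mm = 2.0, y_mm = 1.3)) # depth chosen per animal from Vwm
}

#' Generate a two-group cohort with behavioural data
#'
#' Draws per-animal ground-truth stereological targets and a Morris-water-
#' maze escape-latency series. A single standard-normal driver `z` per
#' animal scales the three capillary totals comonotonically (each with its
#' own configured CV, as mean-one lognormal factors) and lowers the
#' animal's escape latencies, producing the negative structure-behaviour
#' correlations; white-matter volume varies independently. Per-animal
#' radius calibrations and child seeds are stored so [animalNetwork()] can
#' materialise each phantom reproducibly.
#'
#' @param config configuration list from [cohortConfig()].
#' @param nPerGroup,seed convenience overrides of the config fields.
#' @return a [StereoCohort-class].
#' @export
#' @examples
#' coh <- generateCohort(nPerGroup = 3, seed = 7)
#' animals(coh)[, c("animal", "group", "L_true_m")]
generateCohort <- function(config = cohortConfig(), nPerGroup = NULL,
                           seed = NULL) {
  if (!is.null(nPerGroup)) config$nPerGroup <- nPerGroup
  if (!is.null(seed)) config$seed <- seed
  n <- config$nPerGroup
  stopIfNot(n >= 2, "need at least 2 animals per group (group SD undefined)")

  lnFactor <- function(cv, z) {
    if (cv <= 0) return(rep(1, length(z)))
    s <- sqrt(log(1 + cv^2))
    exp(s * z - s^2 / 2)
  }

  rows <- list(); lat <- list()
  for (gname in names(config$groups)) {
    g <- config$groups[[gname]]
    grows <- list()
    for (i in seq_len(n)) {
      id <- sprintf("%s_%02d", ifelse(gname == "wild_type", "wt", "tg"), i)
      aseed <- childSeed(config$seed, "animal", id)
      withSeed(childSeed(aseed, "truth"), {
        u <- stats::rnorm(1)   # shared structural driver for L, V, S
        uv <- stats::rnorm(1)  # independent driver for Vwm
        L_m <- g$L_m * lnFactor(g$LCV, u)
        Vcap <- g$Vcap_mm3 * lnFactor(g$VcapCV, u)
        Scap <- g$Scap_mm2 * lnFactor(g$ScapCV, u)
        Vwm <- g$Vwm_mm3 * lnFactor(g$VwmCV, uv)
        crossings <- stats::rpois(1, config$crossingsMean)
        quadrant <- min(100, max(0, stats::rnorm(1, config$quadrantMean,
                                                 config$quadrantSD)))
      })
      rcal <- calibrateRadius(L_m * 1000, Vcap, Scap)
      grows[[i]] <- data.frame(
        animal = id, group = gname, z = NA_real_,
        Vwm_mm3 = Vwm, L_true_m = L_m,
        Vcap_true_mm3 = Vcap, Scap_true_mm2 = Scap,
        radiusMeanUm = rcal$meanUm, radiusCV = rcal$cv,
        crossings = crossings, quadrantPct = quadrant,
        seed = aseed, stringsAsFactors = FALSE)
    }
    gdf <- do.call(rbind, grows)
    # latency driver: within-group standardized total capillary length,
    # so latency is linear in L_true (noise-free correlation exactly -1)
    sdL <- stats::sd(gdf$L_true_m)
    gdf$z <- if (sdL > 0) (gdf$L_true_m - mean(gdf$L_true_m)) / sdL else 0
    for (i in seq_len(n)) {
      id <- gdf$animal[i]
      withSeed(childSeed(gdf$seed[i], "latency"), {
        for (d in seq_len(config$days)) {
          mu <- g$latencyIntercepts[d] - config$latencySlope * gdf$z[i]
          tl <- pmin(60, pmax(0, mu + stats::rnorm(config$trialsPerDay,
                                                   0, config$trialNoiseSD)))
          lat[[length(lat) + 1]] <- data.frame(
            animal = id, group = gname, day = d,
            trial = seq_len(config$trialsPerDay), latency_s = tl,
            stringsAsFactors = FALSE)
        }
      })
    }
    rows[[gname]] <- gdf
  }
  new("StereoCohort",
      animals = do.call(rbind, c(rows, list(make.row.names = FALSE))),
      latency = do.call(rbind, c(lat, list(make.row.names = FALSE))),
      config = config)
}

#' @rdname generateCohort
#' @param x a [StereoCohort-class].
#' @export
setMethod("animals", "StereoCohort", function(x) x@animals)

#' @rdname generateCohort
#' @export
setMethod("latencies", "StereoCohort", function(x) x@latency)

setMethod("show", "StereoCohort", function(object) {
  tab <- table(object@animals$group)
  cat(sprintf("StereoCohort: %s\n",
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", ")))
  invisible(object)
})

#' Materialise one animal's phantom
#'
#' Rebuilds the white-matter region and capillary network for one cohort
#' animal from its stored calibration and child seed. The region is a box
#' with the configured x,y footprint and depth `Vwm / (x * y)` so its
#' analytic volume equals the animal's white-matter volume.
#'
#' @param cohort a [StereoCohort-class].
#' @param animal animal id (or integer row index).
#' @param orientation passed to [generateNetwork()].
#' @return a [CapillaryNetwork-class].
#' @export
animalNetwork <- function(cohort, animal, orientation = "isotropic") {
  a <- animals(cohort)
  row <- if (is.character(animal)) a[a$animal == animal, ] else {
    a[animal, , drop = FALSE]
  }
  stopIfNot(nrow(row) == 1, "animal not found in cohort")
  dims <- cohort@config$regionDims
  region <- boxRegion(c(dims[["x_mm"]], dims[["y_mm"]],
                        row$Vwm_mm3 / (dims[["x_mm"]] * dims[["y_mm"]])))
  generateNetwork(region, targetLength = row$L_true_m * 1000,
                  radiusMeanUm = row$radiusMeanUm, radiusCV = row$radiusCV,
                  orientation = orientation,
                  segmentLength = cohort@config$segmentLength,
                  seed = childSeed(row$seed, "network"))
}

#' Write a cohort to disk
#'
#' Writes the generating config plus per-animal truths to JSON and the
#' escape-latency series to a tidy CSV (`animal, group, day, trial,
#' latency_s`).
#'
#' @param cohort a [StereoCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jpath <- file.path(dir, "cohort.json")
  cpath <- file.path(dir, "latency.csv")
  jsonlite::write_json(
    list(config = cohort@config, animals = animals(cohort)),
    jpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(latencies(cohort), cpath, row.names = FALSE)
  invisible(c(jpath, cpath))
}
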