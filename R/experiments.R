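# Pre-packaged validation experiments. These are the package's own
# evidence that the estimators are unbiased under the calibrated study
# conditions; the acceptance script and the test suite both run them.

#' Cohort pinned at the group calibration targets
#'
#' A cohort whose per-animal ground truths equal the group means exactly
#' (all between-animal CVs set to zero): the configuration used for
#' estimator-recovery experiments, where cohort sampling wobble would
#' otherwise mask probe error.
#'
#' @param seed integer seed.
#' @param nPerGroup animals per group.
#' @return a [StereoCohort-class].
#' @export
recoveryCohort <- function(seed = 1, nPerGroup = 7) {
  cfg <- cohortConfig(nPerGroup = nPerGroup, seed = seed)
  for (g in names(cfg$groups)) {
    cfg$groups[[g]]$VwmCV <- 0
    cfg$groups[[g]]$LCV <- 0
    cfg$groups[[g]]$VcapCV <- 0
    cfg$groups[[g]]$ScapCV <- 0
  }
  generateCohort(cfg)
}

#' Cavalieri recovery experiment
#'
#' Replicated Cavalieri designs (systematic 1 mm slabs, fresh 0.59 mm^2
#' point grid per replicate) on a region whose analytic volume is the
#' wild-type calibration target; reports the mean estimate and its
#' relative error.
#'
#' @param seed integer seed.
#' @param reps number of replicate grid placements.
#' @param Vwm_mm3 target volume (mm^3).
#' @param t,ap Cavalieri design constants (mm, mm^2).
#' @return list with `meanVhat_mm3`, `relError`, `reps`, `Vtrue_mm3`.
#' @export
cavalieriExperiment <- function(seed = 1, reps = 500, Vwm_mm3 = 12.87,
                                t = 1, ap = 0.59) {
  region <- boxRegion(c(2.0, 1.3, Vwm_mm3 / 2.6))
  v <- vapply(seq_len(reps), function(k) {
    cavalieriEstimate(region, t = t, ap = ap,
                      seed = childSeed(seed, "cavalieri-rep", k))$Vhat_mm3
  }, numeric(1))
  list(meanVhat_mm3 = mean(v), relError = mean(v) / Vwm_mm3 - 1,
       reps = reps, Vtrue_mm3 = Vwm_mm3)
}

#' Capillary length/volume/surface recovery experiment
#'
#' Surveys a calibration-pinned cohort ([recoveryCohort()]) with IUR
#' sections and the three probes, and compares the group-mean estimated
#' totals with the group-mean ground truths (the phantom's analytic
#' reference volume is used so the comparison isolates probe error).
#'
#' @param seed integer seed.
#' @param nPerGroup animals per group.
#' @param fieldsPerSection probe fields per section.
#' @param t_mm slab pitch for block sampling; the default 0.5 mm doubles
#'   the section count per animal.
#' @param nReplicates independent surveys pooled per animal. Probe noise
#'   is dominated by local density fluctuation shared by all probes of a
#'   section (and, for capillary volume, by the heavy-tailed profile
#'   areas of the wide radius distributions), so the defaults — about 35
#'   sections x 12 fields x 3 replicate surveys per animal — are sized
#'   to hold the group-mean Monte-Carlo error near 1.5%, several times
#'   below the 5% recovery tolerance.
#' @return data.frame with one row per group and measure: mean estimate,
#'   mean truth and relative error.
#' @export
recoveryExperiment <- function(seed = 1, nPerGroup = 7,
                               fieldsPerSection = 12, t_mm = 0.5,
                               nReplicates = 3) {
  coh <- recoveryCohort(seed = seed, nPerGroup = nPerGroup)
  params <- utils::modifyList(probeDefaults(),
                              list(fieldsPerSection = fieldsPerSection,
                                   t_mm = t_mm))
  a <- animals(coh)
  est <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    net <- animalNetwork(coh, a$animal[i])
    counts <- do.call(rbind, lapply(seq_len(nReplicates), function(r) {
      surveyNetwork(net, params,
                    seed = childSeed(a$seed[i], "survey", r))
    }))
    Lv <- lengthDensity(sum(counts$Q), sum(counts$A_mm2))
    Vv <- volumeDensity(sum(counts$Pcap), sum(counts$Pref))
    Sv <- surfaceDensity(sum(counts$I), sum(counts$L_mm))
    tot <- stereoTotals(Lv, Vv, Sv, networkTruth(net)$Vwm_mm3)
    est[[i]] <- data.frame(
      group = a$group[i], L_m = tot$L_m, Vcap_mm3 = tot$Vcap_mm3,
      Scap_mm2 = tot$Scap_mm2, L_true_m = a$L_true_m[i],
      Vcap_true_mm3 = a$Vcap_true_mm3[i],
      Scap_true_mm2 = a$Scap_true_mm2[i], stringsAsFactors = FALSE)
  }
  est <- do.call(rbind, c(est, list(make.row.names = FALSE)))
  rows <- list()
  meas <- rbind(
    c("length", "L_m", "L_true_m"),
    c("volume", "Vcap_mm3", "Vcap_true_mm3"),
    c("surface", "Scap_mm2", "Scap_true_mm2"))
  for (g in unique(est$group)) {
    sub <- est[est$group == g, ]
    for (i in seq_len(nrow(meas))) {
      mhat <- mean(sub[[meas[i, 2]]])
      mtrue <- mean(sub[[meas[i, 3]]])
      rows[[length(rows) + 1]] <- data.frame(
        group = g, measure = meas[i, 1], estimate = mhat, truth = mtrue,
        relError = mhat / mtrue - 1, n = nrow(sub),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Near-uniform direction lattice on the sphere (spherical Fibonacci
# points): the z components stratify (-1, 1) so a randomly rotated copy
# integrates smooth orientation functionals with negligible error while
# remaining exactly isotropic in expectation.
.fibonacciSphere <- function(K) {
  i <- seq_len(K) - 1
  z <- (2 * i + 1) / K - 1
  az <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(az), s * sin(az), z)
}

# Uniform random rotation matrix (normalized quaternion).
.randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Anisotropy bias experiment
#'
#' A network of cylinders all parallel to the z axis, probed with
#' counting frames under two section designs: axis-aligned planes
#' (normal along the fibre axis), where every fibre crosses every plane
#' and the length estimator overcounts by a factor of about two, and
#' isotropic uniform random planes, which restore unbiasedness — the
#' geometric case for the isector step. For a fixed-axis network the
#' per-plane profile intensity is `Lv * |cos(theta)|` (CV 58% across
#' orientations), so the isotropic arm draws its orientations as a
#' randomly rotated spherical Fibonacci lattice: exactly isotropic in
#' expectation, but orientation-stratified so the Monte-Carlo error of
#' the bias measurement is dominated by counting noise rather than
#' orientation sampling.
#'
#' @param seed integer seed.
#' @param nPlanes section planes in the isotropic arm. One counting
#'   frame is laid per plane, so the pooled count is close to Poisson
#'   and its Monte-Carlo error at the default size is about 0.6%, well
#'   inside the 2% tolerance the experiment is judged against.
#' @param nAligned section planes in the axis-aligned arm.
#' @return list with `biasAligned`, `biasIsector` (relative errors of
#'   the pooled length-density estimates) and the true density `LvTrue`.
#' @export
anisotropyExperiment <- function(seed = 1, nPlanes = 2048, nAligned = 60) {
  # a large phantom keeps the finite-realization fluctuation of the
  # sampled interior density (~1/sqrt(segments)) below the counting noise
  region <- boxRegion(c(2, 2, 2))
  net <- generateNetwork(region, targetLength = 8000, radiusMeanUm = 1.5,
                         radiusCV = 0, orientation = "fixed",
                         axis = c(0, 0, 1),
                         seed = childSeed(seed, "aniso-net"))
  LvTrue <- networkTruth(net)$L_mm / regionVolume(region)
  inner <- erodeRegion(region, 0.34)
  frh <- 0.10; spread <- 0.08

  arm <- function(normals, tag) {
    Q <- 0; A <- 0
    for (k in seq_len(nrow(normals))) {
      ctr <- withSeed(childSeed(seed, tag, "ctr", k),
                      drop(runifRegion(inner, 1)))
      pl <- isectorPlane(ctr, offset = 0.03,
                         seed = childSeed(seed, tag, "off", k),
                         normal = normals[k, ])
      prof <- sectionNetwork(net, pl)
      fc <- withSeed(childSeed(seed, tag, "field", k),
                     stats::runif(2, -spread, spread))
      near <- prof[abs(prof$u - fc[1]) <= prof$major + frh &
                   abs(prof$v - fc[2]) <= prof$major + frh, ,
                   drop = FALSE]
      fr <- countingFrame(fc[1] - frh, fc[1] + frh,
                          fc[2] - frh, fc[2] + frh)
      Q <- Q + countFrame(near, fr)
      A <- A + fr$area
    }
    lengthDensity(Q, A) / LvTrue - 1
  }

  rot <- withSeed(childSeed(seed, "rotation"), .randomRotation())
  iurNormals <- .fibonacciSphere(nPlanes) %*% t(rot)
  aligned <- matrix(rep(c(0, 0, 1), nAligned), ncol = 3, byrow = TRUE)
  list(biasAligned = arm(aligned, "ali"),
       biasIsector = arm(iurNormals, "iur"),
       LvTrue = LvTrue)
}

#' Group-significance pattern experiment
#'
#' Repeatedly generates calibrated cohorts (n per group as configured,
#' published group means and SDs) and records how often the unpaired t
#' tests reproduce the reference significance pattern: total capillary
#' length different at p < 0.01, total capillary volume at p < 0.05, and
#' no significant white-matter volume difference.
#'
#' @param seed integer seed.
#' @param nSeeds number of cohort replicates.
#' @param nPerGroup animals per group.
#' @return list of rates: `rateLengthP01`, `rateVolumeP05`,
#'   `rateVwmNonsig`, plus `nSeeds`.
#' @export
significanceExperiment <- function(seed = 1, nSeeds = 200, nPerGroup = 7) {
  hitL <- 0; hitV <- 0; hitW <- 0
  for (k in seq_len(nSeeds)) {
    coh <- generateCohort(nPerGroup = nPerGroup,
                          seed = childSeed(seed, "sig", k))
    a <- animals(coh)
    wt <- a[a$group == "wild_type", ]; tg <- a[a$group == "tg2576", ]
    if (unpairedT(wt$L_true_m, tg$L_true_m)$p < 0.01) hitL <- hitL + 1
    if (unpairedT(wt$Vcap_true_mm3, tg$Vcap_true_mm3)$p < 0.05) {
      hitV <- hitV + 1
    }
    if (unpairedT(wt$Vwm_mm3, tg$Vwm_mm3)$p >= 0.05) hitW <- hitW + 1
  }
  list(rateLengthP01 = hitL / nSeeds, rateVolumeP05 = hitV / nSeeds,
       rateVwmNonsig = hitW / nSeeds, nSeeds = nSeeds)
}
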