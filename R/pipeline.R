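#' Default probe and sampling geometry
#'
#' Sampling-design parameters for the simulated histology chain. The
#' published probe constants (`t = 1` mm slabs, `a(p) = 0.59` mm^2) are
#' used for the Cavalieri stage; frame/grid/line dimensions are chosen so
#' a default animal yields roughly 600-1000 counted profiles (estimator
#' CE of a few percent, ordinary stereological practice); the erosion
#' margin keeps every probe field strictly inside the phantom, where the
#' capillary density equals its analytic value exactly.
#'
#' @return named list of parameters (all lengths mm).
#' @export
probeDefaults <- function() {
  list(
    t_mm = 1,                # Cavalieri slab thickness
    ap_mm2 = 0.59,           # Cavalieri area per grid point
    sliceAxis = "z",
    blockSpacing = 0.25,     # block-sampling grid spacing
    blocksPerSlab = c(3, 4),
    margin = 0.47,           # erosion margin for field placement
    planeOffset = 0.05,      # isector plane offset half-range
    fieldsPerSection = 10,
    fieldSize = 0.14,        # field (photograph) side length
    fieldSpread = 0.2,       # in-plane jitter of field centres
    frameSize = 0.11,        # counting-frame side length
    frameRule = "gundersen_full",
    gridSpacing = 0.003,     # point grid for Vv
    lineSpacing = 0.006)     # test lines for Sv
}

#' Cavalieri estimate of a region's volume
#'
#' Runs the full Cavalieri design on a region: systematic slabs with a
#' random start along `axis`, a freshly offset point grid on each slab
#' face, and `V = t * a(p) * sum(P)`.
#'
#' @param region a [WMRegion-class].
#' @param t slab thickness (mm).
#' @param ap area per grid point (mm^2).
#' @param axis slicing axis.
#' @param seed integer seed.
#' @return list with `Vhat_mm3`, `sumP`, `levels`, `perSection`.
#' @export
#' @examples
#' cavalieriEstimate(boxRegion(c(2, 1.3, 4.95)), seed = 1)$Vhat_mm3
cavalieriEstimate <- function(region, t = 1, ap = 0.59, axis = "z",
                              seed = 1) {
  slabs <- cavalieriSlabs(region, t = t, axis = axis,
                          seed = childSeed(seed, "slabs"))
  bb <- regionBounds(region)
  hi <- bb[paste0(axis, "max")]
  levels <- slabs$lower + t
  levels <- levels[levels < hi]
  perSection <- integer(length(levels))
  for (k in seq_along(levels)) {
    rects <- regionCrossSection(region, levels[k], axis)
    grid <- pointGrid(sqrt(ap), seed = childSeed(seed, "grid", k))
    perSection[k] <- countGridHitsRegion(grid, rects)
  }
  sumP <- sum(perSection)
  list(Vhat_mm3 = cavalieriVolume(sumP, ap, t), sumP = sumP,
       levels = levels, perSection = perSection)
}

#' Survey a phantom with the full probe battery
#'
#' The simulated counterpart of the histology chain: Cavalieri slabs of
#' the (eroded) region, 3-4 tissue blocks per slab from a random point
#' grid, one isector section per block, and per section a set of
#' photograph fields, each counted with the unbiased frame (profile
#' count Q over frame area A), the fine point grid (Pcap over Pref) and
#' the test lines (intersections I over line length L).
#'
#' @param network a [CapillaryNetwork-class].
#' @param params sampling parameters, see [probeDefaults()].
#' @param seed integer seed.
#' @param planeNormal optional fixed section normal (non-IUR sections,
#'   for bias demonstrations); default NULL draws isector planes.
#' @return data.frame of per-field count records: `section, field, Q,
#'   A_mm2, Pcap, Pref, I, L_mm`.
#' @export
surveyNetwork <- function(network, params = probeDefaults(), seed = 1,
                          planeNormal = NULL) {
  region <- network@region
  eroded <- erodeRegion(region, params$margin)
  slabs <- cavalieriSlabs(eroded, t = params$t_mm, axis = params$sliceAxis,
                          seed = childSeed(seed, "slabs"))
  centers <- NULL
  for (k in seq_len(nrow(slabs))) {
    blk <- sampleBlocks(eroded, c(slabs$lower[k], slabs$upper[k]),
                        spacing = params$blockSpacing,
                        kRange = params$blocksPerSlab,
                        axis = params$sliceAxis,
                        seed = childSeed(seed, "blocks", k))
    centers <- rbind(centers, blk)
  }
  stopIfNot(!is.null(centers) && nrow(centers) > 0,
            "no tissue blocks could be sampled")

  fh <- params$fieldSize / 2
  frh <- params$frameSize / 2
  rows <- vector("list", nrow(centers) * params$fieldsPerSection)
  ri <- 1L
  for (s in seq_len(nrow(centers))) {
    plane <- isectorPlane(centers[s, ], offset = params$planeOffset,
                          seed = childSeed(seed, "plane", s),
                          normal = planeNormal)
    prof <- sectionNetwork(network, plane)
    for (f in seq_len(params$fieldsPerSection)) {
      ctr <- withSeed(childSeed(seed, "fieldpos", s, f),
                      stats::runif(2, -params$fieldSpread,
                                   params$fieldSpread))
      field <- c(ctr[1] - fh, ctr[1] + fh, ctr[2] - fh, ctr[2] + fh)
      # keep only profiles that can reach this field
      near <- prof[abs(prof$u - ctr[1]) <= prof$major + fh &
                   abs(prof$v - ctr[2]) <= prof$major + fh, , drop = FALSE]
      frame <- countingFrame(ctr[1] - frh, ctr[1] + frh,
                             ctr[2] - frh, ctr[2] + frh,
                             rule = params$frameRule)
      q <- countFrame(near, frame)
      grid <- pointGrid(params$gridSpacing,
                        seed = childSeed(seed, "grid", s, f))
      pp <- countGridHitsProfiles(grid, near, field)
      lines <- makeTestLines(field, params$lineSpacing,
                             seed = childSeed(seed, "lines", s, f))
      il <- countLineIntersections(lines, near)
      rows[[ri]] <- data.frame(section = s, field = f,
                               Q = q, A_mm2 = frame$area,
                               Pcap = pp[["Pcap"]], Pref = pp[["Pref"]],
                               I = il$I, L_mm = il$L)
      ri <- ri + 1L
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Estimate one animal's stereological totals
#'
#' Pools the per-field counts of [surveyNetwork()] by ratio-of-sums,
#' forms the three densities, and multiplies by the reference volume
#' (Cavalieri-estimated, or the phantom's analytic volume when the goal
#' is to isolate probe error from reference-volume error).
#'
#' @param network a [CapillaryNetwork-class].
#' @param params sampling parameters, see [probeDefaults()].
#' @param seed integer seed.
#' @param vwm `"cavalieri"` or `"true"`.
#' @param planeNormal optional fixed section normal (see
#'   [surveyNetwork()]).
#' @return list with `counts` (per-field records), `sums`, `densities`
#'   (`Lv`, `Vv`, `Sv`), `Vwm_mm3` and `totals`.
#' @export
estimateAnimal <- function(network, params = probeDefaults(), seed = 1,
                           vwm = c("cavalieri", "true"),
                           planeNormal = NULL) {
  vwm <- match.arg(vwm)
  counts <- surveyNetwork(network, params, seed, planeNormal = planeNormal)
  sums <- list(Q = sum(counts$Q), A_mm2 = sum(counts$A_mm2),
               Pcap = sum(counts$Pcap), Pref = sum(counts$Pref),
               I = sum(counts$I), L_mm = sum(counts$L_mm))
  dens <- list(Lv = lengthDensity(sums$Q, sums$A_mm2),
               Vv = volumeDensity(sums$Pcap, sums$Pref),
               Sv = surfaceDensity(sums$I, sums$L_mm))
  Vwm <- if (vwm == "cavalieri") {
    cavalieriEstimate(network@region, t = params$t_mm, ap = params$ap_mm2,
                      axis = params$sliceAxis,
                      seed = childSeed(seed, "cavalieri"))$Vhat_mm3
  } else {
    networkTruth(network)$Vwm_mm3
  }
  list(counts = counts, sums = sums, densities = dens, Vwm_mm3 = Vwm,
       totals = stereoTotals(dens$Lv, dens$Vv, dens$Sv, Vwm))
}

#' Run the estimation pipeline over a cohort
#'
#' Materialises each animal's phantom from its stored seed, surveys it,
#' and returns per-animal estimates next to the ground truths.
#'
#' @param cohort a [StereoCohort-class].
#' @param params sampling parameters, see [probeDefaults()].
#' @param vwm `"cavalieri"` or `"true"` reference volume.
#' @param orientation network orientation mode passed to
#'   [animalNetwork()].
#' @return list with `estimates` (one row per animal: estimates and
#'   truths) and `counts` (per-field records, all animals).
#' @export
estimateCohort <- function(cohort, params = probeDefaults(),
                           vwm = c("cavalieri", "true"),
                           orientation = "isotropic") {
  vwm <- match.arg(vwm)
  a <- animals(cohort)
  est <- vector("list", nrow(a))
  cnt <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    net <- animalNetwork(cohort, a$animal[i], orientation = orientation)
    one <- estimateAnimal(net, params, seed = childSeed(a$seed[i], "survey"),
                          vwm = vwm)
    est[[i]] <- data.frame(
      animal = a$animal[i], group = a$group[i],
      Vwm_mm3 = one$Vwm_mm3, L_m = one$totals$L_m,
      Vcap_mm3 = one$totals$Vcap_mm3, Scap_mm2 = one$totals$Scap_mm2,
      Lv = one$densities$Lv, Vv = one$densities$Vv, Sv = one$densities$Sv,
      Vwm_true_mm3 = a$Vwm_mm3[i], L_true_m = a$L_true_m[i],
      Vcap_true_mm3 = a$Vcap_true_mm3[i],
      Scap_true_mm2 = a$Scap_true_mm2[i],
      stringsAsFactors = FALSE)
    cnt[[i]] <- cbind(animal = a$animal[i], group = a$group[i],
                      one$counts, stringsAsFactors = FALSE)
  }
  list(estimates = do.call(rbind, c(est, list(make.row.names = FALSE))),
       counts = do.call(rbind, c(cnt, list(make.row.names = FALSE))))
}

#' Estimate totals from a count-record table
#'
#' The boundary at which real (non-synthetic) counts enter the pipeline:
#' a tidy table with one row per field (`animal, Q, A_mm2, Pcap, Pref, I,
#' L_mm`) is pooled per animal by ratio-of-sums and converted to
#' densities and totals with the supplied reference volumes.
#'
#' @param counts data.frame (or path to a CSV) of per-field count
#'   records.
#' @param vwm data.frame `animal, Vwm_mm3` (or a single volume recycled
#'   to all animals).
#' @return data.frame of per-animal densities and totals.
#' @export
estimateFromCounts <- function(counts, vwm) {
  if (is.character(counts)) counts <- utils::read.csv(counts)
  need <- c("animal", "Q", "A_mm2", "Pcap", "Pref", "I", "L_mm")
  stopIfNot(all(need %in% names(counts)),
            paste("counts must contain columns:",
                  paste(need, collapse = ", ")))
  if (is.numeric(vwm) && length(vwm) == 1) {
    vwm <- data.frame(animal = unique(counts$animal), Vwm_mm3 = vwm)
  }
  out <- lapply(split(counts, counts$animal), function(cc) {
    v <- vwm$Vwm_mm3[match(cc$animal[1], vwm$animal)]
    stopIfNot(is.finite(v) && v > 0,
              paste("no reference volume for animal", cc$animal[1]))
    Lv <- lengthDensity(sum(cc$Q), sum(cc$A_mm2))
    Vv <- volumeDensity(sum(cc$Pcap), sum(cc$Pref))
    Sv <- surfaceDensity(sum(cc$I), sum(cc$L_mm))
    tot <- stereoTotals(Lv, Vv, Sv, v)
    data.frame(animal = cc$animal[1], Vwm_mm3 = v, Lv = Lv, Vv = Vv,
               Sv = Sv, L_m = tot$L_m, Vcap_mm3 = tot$Vcap_mm3,
               Scap_mm2 = tot$Scap_mm2, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
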