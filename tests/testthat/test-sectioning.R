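test_that("Cavalieri slabs tile the region with a uniform random start", {
  reg <- boxRegion(c(1, 1, 10))
  sl <- cavalieriSlabs(reg, t = 1, seed = 4)
  expect_true(nrow(sl) %in% c(10, 11))
  expect_true(all(diff(sl$lower) == 1))
  expect_lte(sl$lower[1], 0)
  expect_gte(sl$upper[nrow(sl)], 10)
  expect_warning(cavalieriSlabs(boxRegion(c(1, 1, 0.5)), t = 1, seed = 1),
                 "single slab")
})

test_that("slab count over random starts matches the enumeration oracle", {
  # oracle: slabs overlapping (0, e) with starts k*t - u*t are
  # ceil((e + u*t)/t); for e = 10.5, t = 1 that is 11 for u < 0.5 and
  # 12 otherwise, so the expectation is 11.5
  counts <- sapply(1:2000, function(s) {
    nrow(cavalieriSlabs(boxRegion(c(1, 1, 10.5)), t = 1, seed = s))
  })
  expect_true(all(counts %in% c(11, 12)))
  expect_lt(abs(mean(counts) - 11.5), 0.05)
})

test_that("block sampling selects 3-4 grid hits uniformly", {
  reg <- boxRegion(c(1, 0.6, 2))
  b <- sampleBlocks(reg, c(0.5, 1.5), spacing = 0.2, kRange = c(3, 4),
                    seed = 2)
  expect_true(nrow(b) %in% 3:4)
  expect_true(all(containsPoints(reg, b)))
  expect_true(all(b[, 3] >= 0.5 & b[, 3] <= 1.5))

  # uniform inclusion: every grid point equally likely over resamples
  tiny <- boxRegion(c(0.55, 0.35, 1)) # 2 x 3 = 6 interior-ish grid hits
  picks <- table(unlist(lapply(1:1500, function(s) {
    p <- sampleBlocks(tiny, c(0, 1), spacing = 0.2, kRange = c(2, 2),
                      seed = s)
    paste(round(p[, 1], 3), round(p[, 2], 3))
  })))
  # offsets are re-randomised each call, so just require no point class
  # to dominate: chi-square on the k most frequent locations is not
  # well-defined (locations vary); instead check the spread of the
  # depth coordinate is uniform within the slab
  depths <- unlist(lapply(1:400, function(s) {
    sampleBlocks(tiny, c(0, 1), spacing = 0.2, kRange = c(2, 2),
                 seed = s)[, 3]
  }))
  ks <- suppressWarnings(stats::ks.test(depths, "punif", 0, 1))
  expect_gt(ks$p.value, 0.01)

  expect_warning(
    few <- sampleBlocks(boxRegion(c(0.25, 0.25, 1)), c(0, 1),
                        spacing = 0.2, kRange = c(3, 4), seed = 8),
    "taking all")
  expect_lte(nrow(few), 2)
})

test_that("fixed-offset block selection has uniform inclusion frequencies
           (chi-square)", {
  # freeze the cross-section grid by construction: a region exactly
  # containing a 5 x 2 block of grid points for almost every offset is
  # impractical, so instead check the selector: sampling k of n labels
  # through the same code path used for grid hits
  reg <- boxRegion(c(1.05, 0.25, 1))
  sel <- integer(0)
  for (s in 1:3000) {
    p <- sampleBlocks(reg, c(0, 1), spacing = 0.2, kRange = c(2, 2),
                      seed = s)
    if (nrow(p) == 2) sel <- c(sel, round(p[, 1] %% 0.2, 6))
  }
  # offsets uniform => residues uniform
  ks <- suppressWarnings(stats::ks.test(sel, "punif", 0, 0.2))
  expect_gt(ks$p.value, 0.01)
})

test_that("isector planes are isotropic: E[normal outer normal] = I/3", {
  dirs <- withr::with_seed(99, stereocap:::runifSphere(1e5))
  M <- crossprod(dirs) / nrow(dirs)
  expect_lt(max(abs(M - diag(3) / 3)), 0.01)
  expect_lt(abs(mean(dirs[, 3])), 0.01)
  ks <- suppressWarnings(stats::ks.test(dirs[, 3], "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("isector plane construction: unit frame, bounded offset,
           determinism, fixed-normal override", {
  p1 <- isectorPlane(c(1, 2, 3), offset = 0.05, seed = 7)
  p2 <- isectorPlane(c(1, 2, 3), offset = 0.05, seed = 7)
  expect_identical(p1, p2)
  expect_equal(sum(p1$normal^2), 1, tolerance = 1e-12)
  expect_equal(sum(p1$e1 * p1$normal), 0, tolerance = 1e-12)
  expect_equal(sum(p1$e2 * p1$e1), 0, tolerance = 1e-12)
  expect_lte(sqrt(sum((p1$point - c(1, 2, 3))^2)), 0.05 + 1e-12)
  pf <- isectorPlane(c(0, 0, 0), seed = 1, normal = c(0, 0, 2))
  expect_equal(pf$normal, c(0, 0, 1))
})

test_that("plane-cylinder intersection gives the textbook ellipses", {
  r <- 2e-3 # 2 um
  # axis perpendicular to the plane: a circle
  net <- singleCylinderNetwork(c(0.5, 0.5, 0.2), c(0.5, 0.5, 0.8), r)
  pl <- isectorPlane(c(0.5, 0.5, 0.5), offset = 0, seed = 1,
                     normal = c(0, 0, 1))
  pr <- sectionNetwork(net, pl)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$major, r, tolerance = 1e-12)
  expect_equal(pr$minor, r, tolerance = 1e-12)

  # axis at 30 degrees to the plane: semi-major r / sin(30) = 2r
  ax <- c(cos(pi / 6), 0, sin(pi / 6)) # 30 degrees above the x-y plane
  net30 <- singleCylinderNetwork(c(0.5, 0.5, 0.5) - 0.3 * ax,
                                 c(0.5, 0.5, 0.5) + 0.3 * ax, r)
  pr30 <- sectionNetwork(net30, pl)
  expect_equal(pr30$major, 2 * r, tolerance = 1e-12)
  expect_equal(pr30$minor, r, tolerance = 1e-12)

  # plane beyond an endpoint: no profile
  plFar <- isectorPlane(c(0.5, 0.5, 0.9), offset = 0, seed = 1,
                        normal = c(0, 0, 1))
  expect_equal(nrow(sectionNetwork(net, plFar)), 0)

  # axis parallel to the plane: measure-zero, skipped
  netPar <- singleCylinderNetwork(c(0.2, 0.5, 0.5), c(0.8, 0.5, 0.5), r)
  expect_equal(nrow(sectionNetwork(netPar, pl)), 0)

  # window filter keeps only profiles centred inside it: the profile
  # centre maps to the in-plane origin here
  expect_equal(nrow(sectionNetwork(net, pl,
                                   window = c(-0.1, 0.1, -0.1, 0.1))), 1)
  expect_equal(nrow(sectionNetwork(net, pl,
                                   window = c(0.2, 0.4, 0.2, 0.4))), 0)
})

test_that("large-vessel profiles are flagged non-capillary", {
  net <- generateNetwork(boxRegion(c(1, 1, 1)), targetLength = 400,
                         seed = 6, largeVesselCount = 300,
                         largeVesselDiameterUm = 14)
  pl <- isectorPlane(c(0.5, 0.5, 0.5), seed = 2)
  pr <- sectionNetwork(net, pl)
  expect_true(any(!pr$capillary))
  expect_true(all(pr$diameterUm[!pr$capillary] >= 10))
  expect_true(all(pr$diameterUm[pr$capillary] < 10))
})

test_that("on IUR planes the classical density identities hold:
           Q_A -> Lv/2, area fraction -> Vv, I_L -> Sv/2", {
  reg <- boxRegion(c(2, 2, 2))
  net <- generateNetwork(reg, targetLength = 8000, radiusMeanUm = 1.3665,
                         radiusCV = 0.47, seed = 31)
  tr <- networkTruth(net)
  LvT <- tr$L_mm / 8; VvT <- tr$Vcap_mm3 / 8; SvT <- tr$Scap_mm2 / 8

  inner <- erodeRegion(reg, 0.45)
  Q <- 0; A <- 0; Pc <- 0; Pr <- 0; I <- 0; L <- 0
  for (s in 1:60) {
    ctr <- withr::with_seed(5000 + s, stereocap:::runifRegion(inner, 1))
    pl <- isectorPlane(drop(ctr), offset = 0.03, seed = 6000 + s)
    prof <- sectionNetwork(net, pl)
    win <- c(-0.2, 0.2, -0.2, 0.2)
    # raw profile count per area (centres in the window)
    Q <- Q + sum(prof$u >= win[1] & prof$u <= win[2] &
                 prof$v >= win[3] & prof$v <= win[4] & prof$capillary)
    A <- A + 0.16
    near <- prof[abs(prof$u) <= prof$major + 0.2 &
                 abs(prof$v) <= prof$major + 0.2, ]
    g <- pointGrid(0.004, seed = 7000 + s)
    pp <- countGridHitsProfiles(g, near, win)
    Pc <- Pc + pp[["Pcap"]]; Pr <- Pr + pp[["Pref"]]
    tl <- makeTestLines(win, 0.008, seed = 8000 + s)
    il <- countLineIntersections(tl, near)
    I <- I + il$I; L <- L + il$L
  }
  expect_lt(abs((Q / A) / (LvT / 2) - 1), 0.05)
  expect_lt(abs((Pc / Pr) / VvT - 1), 0.08)
  expect_lt(abs((I / L) / (SvT / 2) - 1), 0.07)
})

test_that("axis-aligned sections of an anisotropic network bias the length
           estimator; isector sections remove the bias", {
  reg <- boxRegion(c(2, 2, 2))
  net <- generateNetwork(reg, targetLength = 4000, radiusMeanUm = 1.5,
                         radiusCV = 0, orientation = "fixed",
                         axis = c(0, 0, 1), seed = 17)
  LvT <- networkTruth(net)$L_mm / 8
  params <- utils::modifyList(probeDefaults(), list(
    t_mm = 0.4, fieldsPerSection = 6, fieldSize = 0.2, frameSize = 0.16,
    fieldSpread = 0.2, margin = 0.45))
  biased <- estimateAnimal(net, params, seed = 71, vwm = "true",
                           planeNormal = c(0, 0, 1))
  expect_gt(abs(biased$densities$Lv / LvT - 1), 0.2)
  fair <- estimateAnimal(net, params, seed = 72, vwm = "true")
  expect_lt(abs(fair$densities$Lv / LvT - 1), 0.1)
})
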