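# The three 2D probes: unbiased counting frame, point grid, test lines.
# All in-plane coordinates are mm; profiles are the ellipse rows produced
# by sectionNetwork().

# Affine map taking an ellipse to the unit circle: translate to its
# centre, rotate by -angle, scale by 1/major, 1/minor.
.toUnit <- function(pts, profile) {
  ca <- cos(profile$angle); sa <- sin(profile$angle)
  dx <- pts[, 1] - profile$u
  dy <- pts[, 2] - profile$v
  cbind(( ca * dx + sa * dy) / profile$major,
        (-sa * dx + ca * dy) / profile$minor)
}

#' Point-in-ellipse test
#'
#' @param points numeric matrix (n x 2) of in-plane coordinates (mm).
#' @param profile one row of [sectionNetwork()] output.
#' @param strict require strict interior (default) or closed membership.
#' @return logical vector.
#' @export
pointsInEllipse <- function(points, profile, strict = TRUE) {
  q <- .toUnit(matrix(as.numeric(points), ncol = 2), profile)
  d2 <- rowSums(q^2)
  if (strict) d2 < 1 else d2 <= 1
}

# Distance from the origin to the segment p1-p2 (rows may be vectors).
.distOriginSegment <- function(p1, p2) {
  d <- p2 - p1
  dd <- sum(d * d)
  t <- if (dd <= 0) 0 else max(0, min(1, -sum(p1 * d) / dd))
  p <- p1 + t * d
  sqrt(sum(p * p))
}

# Does the closed ellipse meet the closed segment a-b (world coords)?
.ellipseMeetsSegment <- function(a, b, profile) {
  q <- .toUnit(rbind(a, b), profile)
  .distOriginSegment(q[1, ], q[2, ]) <= 1
}

#' Count transversal crossings of a segment with an ellipse boundary
#'
#' Solves the quadratic for the segment in the ellipse's unit-circle
#' frame. Two interior roots mean the segment passes through the ellipse
#' (2 crossings); one root means it ends inside (1); a tangency (double
#' root) counts once; a segment entirely inside or outside contributes 0.
#'
#' @param a,b segment endpoints, length-2 numeric (mm).
#' @param profile one row of [sectionNetwork()] output.
#' @return integer crossing count.
#' @export
segmentEllipseCrossings <- function(a, b, profile) {
  q <- .toUnit(rbind(a, b), profile)
  p <- q[1, ]; d <- q[2, ] - q[1, ]
  A <- sum(d * d)
  if (A <= 0) return(0L)
  B <- 2 * sum(p * d)
  C <- sum(p * p) - 1
  disc <- B^2 - 4 * A * C
  eps <- 1e-12 * max(1, A^2)
  if (disc < -eps) return(0L)
  if (abs(disc) <= eps) { # tangency counts once
    t0 <- -B / (2 * A)
    return(if (t0 >= 0 && t0 <= 1) 1L else 0L)
  }
  s <- sqrt(disc)
  roots <- c((-B - s) / (2 * A), (-B + s) / (2 * A))
  sum(roots >= 0 & roots <= 1)
}

#' Unbiased counting frame
#'
#' A rectangle with inclusion edges top and right and forbidden
#' (prohibiting) edges bottom and left; the `gundersen_full` rule adds the
#' upward extension of the left edge above the top-left corner and the
#' downward extension of the right-edge line below the bottom-right
#' corner, which guarantees that a tiling of frames counts every convex
#' profile exactly once whatever its size. The `paper_simple` rule is the
#' plain top/right-inclusion, bottom/left-forbidden reading.
#'
#' @param xmin,xmax,ymin,ymax frame rectangle (mm).
#' @param rule `"gundersen_full"` (default) or `"paper_simple"`.
#' @return a `countingFrame` list with the rectangle, rule and `area`.
#' @export
countingFrame <- function(xmin, xmax, ymin, ymax,
                          rule = c("gundersen_full", "paper_simple")) {
  rule <- match.arg(rule)
  stopIfNot(xmax > xmin && ymax > ymin, "frame must have positive area")
  structure(list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
                 rule = rule, area = (xmax - xmin) * (ymax - ymin)),
            class = "countingFrame")
}

#' Count capillary profiles with an unbiased counting frame
#'
#' A (capillary-flagged) profile is counted when it intersects the closed
#' frame and does not touch any forbidden line. Touching an inclusion
#' edge (top or right) is admissible; at exact simultaneous contact the
#' forbidden line wins. Profiles flagged non-capillary (parent diameter
#' >= 10 um) are never counted.
#'
#' @param profiles data.frame from [sectionNetwork()].
#' @param frame a [countingFrame()].
#' @return integer count (the frame's contribution to sum(Q)).
#' @export
countFrame <- function(profiles, frame) {
  if (nrow(profiles) == 0) return(0L)
  profiles <- profiles[profiles$capillary, , drop = FALSE]
  if (nrow(profiles) == 0) return(0L)
  big <- 1e3 # far endpoint standing in for an infinite extension
  c1 <- c(frame$xmin, frame$ymin); c2 <- c(frame$xmax, frame$ymin)
  c3 <- c(frame$xmax, frame$ymax); c4 <- c(frame$xmin, frame$ymax)
  forb <- list(list(c1, c2), list(c1, c4)) # bottom, left
  if (frame$rule == "gundersen_full") {
    forb <- c(forb, list(list(c4, c4 + c(0, big)),   # left edge, upward
                         list(c2, c2 - c(0, big))))  # right line, downward
  }
  n <- 0L
  for (i in seq_len(nrow(profiles))) {
    pr <- as.list(profiles[i, ])
    centerIn <- pr$u >= frame$xmin && pr$u <= frame$xmax &&
                pr$v >= frame$ymin && pr$v <= frame$ymax
    meets <- centerIn ||
      .ellipseMeetsSegment(c1, c2, pr) || .ellipseMeetsSegment(c2, c3, pr) ||
      .ellipseMeetsSegment(c3, c4, pr) || .ellipseMeetsSegment(c4, c1, pr)
    if (!meets) next
    touched <- FALSE
    for (fb in forb) {
      if (.ellipseMeetsSegment(fb[[1]], fb[[2]], pr)) { touched <- TRUE; break }
    }
    if (!touched) n <- n + 1L
  }
  n
}

#' Point grid probe
#'
#' An equidistant square grid with a uniform random offset inside one
#' cell; `a(p) = spacing^2` is the area each point represents.
#'
#' @param spacing grid spacing (mm).
#' @param offset length-2 offset in `[0, spacing)^2`, drawn from `seed`
#'   when omitted.
#' @param seed integer seed.
#' @return a `pointGrid` list with `spacing`, `offset`, `ap` (mm^2).
#' @export
pointGrid <- function(spacing, offset = NULL, seed = 1) {
  stopIfNot(spacing > 0, "grid spacing must be positive")
  if (is.null(offset)) offset <- withSeed(seed, stats::runif(2, 0, spacing))
  stopIfNot(all(offset >= 0 & offset < spacing),
            "offset must lie in [0, spacing)")
  structure(list(spacing = spacing, offset = as.numeric(offset),
                 ap = spacing^2), class = "pointGrid")
}

# Grid nodes falling inside a bounding rectangle (closed).
.gridNodes <- function(grid, rect) {
  s <- grid$spacing
  xs <- seq(grid$offset[1] + s * ceiling((rect[1] - grid$offset[1]) / s - 1e-12),
            rect[2] + 1e-12, by = s)
  ys <- seq(grid$offset[2] + s * ceiling((rect[3] - grid$offset[2]) / s - 1e-12),
            rect[4] + 1e-12, by = s)
  xs <- xs[xs >= rect[1] - 1e-12 & xs <= rect[2] + 1e-12]
  ys <- ys[ys >= rect[3] - 1e-12 & ys <= rect[4] + 1e-12]
  if (!length(xs) || !length(ys)) return(matrix(numeric(0), ncol = 2))
  as.matrix(expand.grid(x = xs, y = ys))
}

#' Count grid points hitting a planar region
#'
#' The Cavalieri point count: number of grid nodes inside the (closed)
#' cross-section rectangles.
#'
#' @param grid a [pointGrid()].
#' @param rects matrix of rectangles `umin, umax, vmin, vmax` as returned
#'   by [regionCrossSection()].
#' @return integer count (a per-section contribution to sum(P)).
#' @export
countGridHitsRegion <- function(grid, rects) {
  rects <- matrix(as.numeric(rects), ncol = 4)
  if (nrow(rects) == 0) return(0L)
  bb <- c(min(rects[, 1]), max(rects[, 2]), min(rects[, 3]), max(rects[, 4]))
  nodes <- .gridNodes(grid, bb)
  if (!nrow(nodes)) return(0L)
  hit <- rep(FALSE, nrow(nodes))
  for (i in seq_len(nrow(rects))) {
    hit <- hit | (nodes[, 1] >= rects[i, 1] & nodes[, 1] <= rects[i, 2] &
                  nodes[, 2] >= rects[i, 3] & nodes[, 2] <= rects[i, 4])
  }
  as.integer(sum(hit))
}

#' Count grid points hitting capillary profiles and the reference area
#'
#' The test point of each drawn cross is its grid node; a node scores for
#' a capillary profile when it lies strictly inside that ellipse (one
#' score per point-profile pair, so `sum(P_cap)` estimates the summed
#' profile area, the planar counterpart of the summed cylinder volume),
#' and for the reference space when it lies in the field rectangle (the
#' field is wholly white matter by construction).
#'
#' @param grid a [pointGrid()].
#' @param profiles data.frame from [sectionNetwork()].
#' @param field field rectangle `c(xmin, xmax, ymin, ymax)` (mm).
#' @return integer vector `c(Pcap, Pref)`.
#' @export
countGridHitsProfiles <- function(grid, profiles, field) {
  nodes <- .gridNodes(grid, field)
  if (!nrow(nodes)) return(c(Pcap = 0L, Pref = 0L))
  pref <- nrow(nodes)
  pcap <- 0L
  caps <- profiles[profiles$capillary, , drop = FALSE]
  for (i in seq_len(nrow(caps))) {
    pcap <- pcap + sum(pointsInEllipse(nodes, as.list(caps[i, ])))
  }
  c(Pcap = as.integer(pcap), Pref = as.integer(pref))
}

#' Test-line probe
#'
#' A family of parallel lines with uniform random orientation and offset,
#' clipped to the field rectangle. With IUR section planes this makes the
#' test lines isotropic in 3D, as the surface-density estimator requires.
#'
#' @param field field rectangle `c(xmin, xmax, ymin, ymax)` (mm).
#' @param spacing perpendicular line spacing (mm).
#' @param seed integer seed.
#' @return list with `segments` (data.frame `x1, y1, x2, y2`),
#'   `totalLength` (mm), `angle`, `spacing`.
#' @export
makeTestLines <- function(field, spacing, seed = 1) {
  stopIfNot(spacing > 0, "line spacing must be positive")
  withSeed(seed, {
    theta <- stats::runif(1, 0, pi)
    u <- stats::runif(1, 0, spacing)
    d <- c(cos(theta), sin(theta))     # line direction
    m <- c(-sin(theta), cos(theta))    # line normal
    corners <- rbind(c(field[1], field[3]), c(field[2], field[3]),
                     c(field[1], field[4]), c(field[2], field[4]))
    cv <- corners %*% m
    cs <- seq(min(cv) - spacing + u, max(cv), by = spacing)
    segs <- NULL
    for (cc in cs) {
      p0 <- cc * m
      # Liang-Barsky clip of the infinite line p0 + t d to the rectangle
      tmin <- -Inf; tmax <- Inf; ok <- TRUE
      for (k in 1:2) {
        lo <- field[2 * k - 1]; hi <- field[2 * k]
        if (abs(d[k]) < 1e-15) {
          if (p0[k] < lo || p0[k] > hi) { ok <- FALSE; break }
        } else {
          t1 <- (lo - p0[k]) / d[k]; t2 <- (hi - p0[k]) / d[k]
          tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
        }
      }
      if (ok && tmax > tmin) {
        a <- p0 + tmin * d; b <- p0 + tmax * d
        segs <- rbind(segs, c(a, b))
      }
    }
    if (is.null(segs)) {
      segs <- matrix(numeric(0), ncol = 4)
    }
    colnames(segs) <- c("x1", "y1", "x2", "y2")
    segs <- as.data.frame(segs)
    len <- if (nrow(segs)) sum(sqrt((segs$x2 - segs$x1)^2 +
                                    (segs$y2 - segs$y1)^2)) else 0
    list(segments = segs, totalLength = len, angle = theta,
         spacing = spacing)
  })
}

#' Count intersections of test lines with capillary profile boundaries
#'
#' Each transversal crossing between a clipped test segment and a
#' capillary ellipse boundary scores once (a segment passing through a
#' profile scores 2, a tangency 1, a segment entirely inside 0).
#' Boundaries are summed over profiles, matching the total luminal
#' surface the estimator targets.
#'
#' @param lines a [makeTestLines()] object.
#' @param profiles data.frame from [sectionNetwork()].
#' @return list with `I` (intersection count) and `L` (total test-line
#'   length, mm).
#' @export
countLineIntersections <- function(lines, profiles) {
  segs <- lines$segments
  caps <- profiles[profiles$capillary, , drop = FALSE]
  total <- 0L
  if (nrow(segs) && nrow(caps)) {
    p1 <- cbind(segs$x1, segs$y1)
    p2 <- cbind(segs$x2, segs$y2)
    for (j in seq_len(nrow(caps))) {
      total <- total + .crossingsAllSegments(as.list(caps[j, ]), p1, p2)
    }
  }
  list(I = as.integer(total), L = lines$totalLength)
}

# Vectorized crossing count of one ellipse against many segments; same
# root-counting rules as segmentEllipseCrossings().
.crossingsAllSegments <- function(pr, p1, p2) {
  q1 <- .toUnit(p1, pr)
  q2 <- .toUnit(p2, pr)
  d <- q2 - q1
  A <- rowSums(d * d)
  B <- 2 * rowSums(q1 * d)
  C <- rowSums(q1 * q1) - 1
  disc <- B^2 - 4 * A * C
  eps <- 1e-12 * pmax(1, A^2)
  n <- numeric(length(A))
  tang <- abs(disc) <= eps & A > 0
  if (any(tang)) {
    t0 <- -B[tang] / (2 * A[tang])
    n[tang] <- as.numeric(t0 >= 0 & t0 <= 1)
  }
  reg <- disc > eps & A > 0
  if (any(reg)) {
    s <- sqrt(disc[reg])
    r1 <- (-B[reg] - s) / (2 * A[reg])
    r2 <- (-B[reg] + s) / (2 * A[reg])
    n[reg] <- (r1 >= 0 & r1 <= 1) + (r2 >= 0 & r2 <= 1)
  }
  sum(n)
}
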