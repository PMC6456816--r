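#' Systematic Cavalieri slabs
#'
#' Tiles the region along one axis with systematic slabs of thickness `t`
#' starting at a uniform random offset, mimicking exhaustive 1-mm slicing
#' of a hemisphere. Each slab's lower face is the section plane that gets
#' point-counted.
#'
#' @param region a [WMRegion-class].
#' @param t slab thickness (mm).
#' @param axis slicing axis, `"x"`, `"y"` or `"z"`.
#' @param seed integer seed for the random start.
#' @return data.frame with columns `lower`, `upper` (mm), attribute
#'   `axis`; slabs cover the region's extent along the axis.
#' @export
#' @examples
#' nrow(cavalieriSlabs(boxRegion(c(1, 1, 10)), t = 1, seed = 1)) # 10 or 11
cavalieriSlabs <- function(region, t = 1, axis = "z", seed = 1) {
  stopIfNot(t > 0, "slab thickness t must be positive")
  axis <- match.arg(axis, c("x", "y", "z"))
  bb <- regionBounds(region)
  lo <- bb[paste0(axis, "min")]
  hi <- bb[paste0(axis, "max")]
  if (t >= hi - lo) {
    warning("slab thickness exceeds the region extent; a single slab")
  }
  u <- withSeed(seed, stats::runif(1))
  start0 <- lo - u * t
  starts <- seq(start0, hi, by = t)
  slabs <- data.frame(lower = starts, upper = starts + t)
  slabs <- slabs[slabs$upper > lo & slabs$lower < hi, , drop = FALSE]
  rownames(slabs) <- NULL
  attr(slabs, "axis") <- axis
  attr(slabs, "t") <- t
  slabs
}

#' Sample tissue-block locations from a slab cross-section
#'
#' Lays a point grid with a uniform random offset on the slab's
#' cross-section, keeps the points that hit the region, and samples
#' `kRange[1]` to `kRange[2]` of them uniformly without replacement as
#' block centres (fewer, with a warning, if the grid yields fewer hits).
#' The returned centres get a depth coordinate uniform within the slab
#' (clipped to the region's extent along the slicing axis).
#'
#' @param region a [WMRegion-class] (typically pre-eroded so blocks stay
#'   clear of the boundary).
#' @param slab one row of [cavalieriSlabs()] output (or a length-2 vector
#'   `c(lower, upper)`).
#' @param spacing grid spacing (mm).
#' @param kRange integer range of blocks to take per slab.
#' @param axis slicing axis.
#' @param seed integer seed.
#' @return numeric matrix (k x 3) of block centres in xyz (mm); 0 rows
#'   with a warning when the grid misses the region.
#' @export
sampleBlocks <- function(region, slab, spacing = 0.2, kRange = c(3, 4),
                         axis = "z", seed = 1) {
  axis <- match.arg(axis, c("x", "y", "z"))
  slab <- as.numeric(slab[1:2])
  bb <- regionBounds(region)
  lo <- max(slab[1], bb[paste0(axis, "min")])
  hi <- min(slab[2], bb[paste0(axis, "max")])
  stopIfNot(hi > lo, "slab does not intersect the region")

  withSeed(seed, {
    level <- stats::runif(1, lo, hi)
    rects <- regionCrossSection(region, level, axis)
    if (nrow(rects) == 0) {
      warning("slab cross-section is empty")
      return(matrix(numeric(0), ncol = 3))
    }
    off <- stats::runif(2, 0, spacing)
    umin <- min(rects[, 1]); umax <- max(rects[, 2])
    vmin <- min(rects[, 3]); vmax <- max(rects[, 4])
    us <- seq(umin - spacing + off[1], umax, by = spacing)
    vs <- seq(vmin - spacing + off[2], vmax, by = spacing)
    pts <- as.matrix(expand.grid(u = us, v = vs))
    hit <- rep(FALSE, nrow(pts))
    for (i in seq_len(nrow(rects))) {
      hit <- hit | (pts[, 1] >= rects[i, 1] & pts[, 1] <= rects[i, 2] &
                    pts[, 2] >= rects[i, 3] & pts[, 2] <= rects[i, 4])
    }
    pts <- pts[hit, , drop = FALSE]
    if (nrow(pts) == 0) {
      warning("no grid points hit the region in this slab")
      return(matrix(numeric(0), ncol = 3))
    }
    k <- if (kRange[2] > kRange[1]) {
      sample(seq(kRange[1], kRange[2]), 1)
    } else kRange[1]
    if (nrow(pts) < k) {
      warning(sprintf("only %d grid hit(s); taking all", nrow(pts)))
      k <- nrow(pts)
    }
    sel <- pts[sample.int(nrow(pts), k), , drop = FALSE]
    depth <- stats::runif(k, lo, hi)
    out <- switch(axis,
      x = cbind(depth, sel[, 1], sel[, 2]),
      y = cbind(sel[, 1], depth, sel[, 2]),
      z = cbind(sel[, 1], sel[, 2], depth))
    colnames(out) <- c("x", "y", "z")
    out
  })
}

#' Deterministic in-plane basis from a normal
#'
#' Builds a right-handed orthonormal frame `(e1, e2, normal)` by a fixed
#' Gram-Schmidt rule (reference axis z, falling back to x near the pole)
#' so that section coordinates are reproducible given the normal.
#'
#' @param normal unit 3-vector.
#' @return list with unit vectors `e1`, `e2`.
#' @export
planeBasis <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Isotropic uniform random (isector) section plane
#'
#' Draws a plane whose normal is uniform on the unit sphere
#' (z ~ U(-1,1), azimuth ~ U(0, 2*pi)) and whose offset along the normal
#' is uniform within `c(-offset, offset)` of the block centre — the
#' simulation counterpart of embedding a tissue block in a randomly
#' rotated sphere before sectioning.
#'
#' @param center block centre, xyz (mm).
#' @param offset half-range of the plane offset along the normal (mm).
#' @param seed integer seed.
#' @param normal optionally force a fixed normal (non-IUR section, for
#'   bias demonstrations); still randomises the offset.
#' @return list with `point`, `normal`, `e1`, `e2` (and the seed).
#' @export
isectorPlane <- function(center, offset = 0.05, seed = 1, normal = NULL) {
  withSeed(seed, {
    n <- if (is.null(normal)) drop(runifSphere(1)) else {
      normal / sqrt(sum(normal^2))
    }
    d <- stats::runif(1, -offset, offset)
    basis <- planeBasis(n)
    list(point = as.numeric(center) + d * n, normal = as.numeric(n),
         e1 = basis$e1, e2 = basis$e2, seed = seed)
  })
}

#' Intersect a capillary network with a section plane
#'
#' Emits one elliptical profile per cylinder whose axis segment crosses
#' the plane strictly between its endpoints: semi-minor axis `r`,
#' semi-major axis `r / sin(phi)` where `phi` is the angle between the
#' cylinder axis and the plane, centred where the axis pierces the plane,
#' with the major axis along the projected cylinder direction. Profiles
#' from vessels with diameter >= 10 um carry `capillary = FALSE` so the
#' counting stage can apply the capillary filter. Cylinders lying in the
#' plane (sin(phi) = 0, a measure-zero event) are skipped.
#'
#' @param network a [CapillaryNetwork-class].
#' @param plane a plane from [isectorPlane()].
#' @param window optional in-plane rectangle `c(umin, umax, vmin, vmax)`;
#'   profiles are kept when their centre lies inside it.
#' @return data.frame: `cylinder, u, v, major, minor, angle, diameterUm,
#'   capillary` (lengths in mm, angle in radians).
#' @export
#' @examples
#' net <- generateNetwork(boxRegion(c(1, 1, 1)), targetLength = 50, seed = 2)
#' pl <- isectorPlane(c(0.5, 0.5, 0.5), seed = 3)
#' head(sectionNetwork(net, pl))
sectionNetwork <- function(network, plane, window = NULL) {
  cyl <- cylinders(network)
  p0 <- plane$point; n <- plane$normal
  da <- (cyl[, 1] - p0[1]) * n[1] + (cyl[, 2] - p0[2]) * n[2] +
        (cyl[, 3] - p0[3]) * n[3]
  db <- (cyl[, 4] - p0[1]) * n[1] + (cyl[, 5] - p0[2]) * n[2] +
        (cyl[, 6] - p0[3]) * n[3]
  cross <- which(da * db < 0) # strictly between the endpoints
  empty <- data.frame(cylinder = integer(0), u = numeric(0), v = numeric(0),
                      major = numeric(0), minor = numeric(0),
                      angle = numeric(0), diameterUm = numeric(0),
                      capillary = logical(0))
  if (!length(cross)) return(empty)

  A <- cyl[cross, 1:3, drop = FALSE]
  B <- cyl[cross, 4:6, drop = FALSE]
  r <- cyl[cross, 7]
  tpar <- da[cross] / (da[cross] - db[cross])
  C <- A + (B - A) * tpar
  axis <- B - A
  alen <- sqrt(rowSums(axis^2))
  u3 <- axis / alen
  sinphi <- abs(u3 %*% n)[, 1]
  ok <- sinphi > 1e-12
  if (!any(ok)) return(empty)
  C <- C[ok, , drop = FALSE]; u3 <- u3[ok, , drop = FALSE]
  r <- r[ok]; sinphi <- sinphi[ok]; cross <- cross[ok]

  rel <- sweep(C, 2, p0)
  uu <- rel %*% plane$e1
  vv <- rel %*% plane$e2
  # in-plane direction of the major axis = projected cylinder axis
  proj1 <- u3 %*% plane$e1
  proj2 <- u3 %*% plane$e2
  ang <- ifelse(sinphi > 1 - 1e-12, 0, atan2(proj2, proj1))

  out <- data.frame(cylinder = cross, u = uu[, 1], v = vv[, 1],
                    major = r / sinphi, minor = r, angle = as.numeric(ang),
                    diameterUm = 2000 * r,
                    capillary = 2000 * r < 10)
  if (!is.null(window)) {
    out <- out[out$u >= window[1] & out$u <= window[2] &
               out$v >= window[3] & out$v <= window[4], , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
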