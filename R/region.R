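#' Construct a white-matter region
#'
#' `wmRegion()` builds a region from an explicit box matrix;
#' `boxRegion()` is the common case of a single origin-anchored box with
#' edge lengths `dims` (mm).
#'
#' @param boxes numeric matrix (n x 6): `xmin, xmax, ymin, ymax, zmin, zmax`.
#' @param dims numeric length-3 vector of positive edge lengths (mm).
#' @return a [WMRegion-class].
#' @export
#' @examples
#' r <- boxRegion(c(4, 2, 1.609))
#' regionVolume(r) # 12.872
wmRegion <- function(boxes) {
  boxes <- as.matrix(boxes)
  colnames(boxes) <- c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax")
  new("WMRegion", boxes = boxes)
}

#' @rdname wmRegion
#' @export
boxRegion <- function(dims) {
  stopIfNot(length(dims) == 3 && all(is.finite(dims)) && all(dims > 0),
            "dims must be three positive finite edge lengths (mm)")
  wmRegion(matrix(c(0, dims[1], 0, dims[2], 0, dims[3]), nrow = 1))
}

#' @rdname wmRegion
#' @export
setMethod("regionVolume", "WMRegion", function(x) {
  b <- x@boxes
  sum((b[, 2] - b[, 1]) * (b[, 4] - b[, 3]) * (b[, 6] - b[, 5]))
})

#' @rdname wmRegion
#' @export
setMethod("regionBounds", "WMRegion", function(x) {
  b <- x@boxes
  c(xmin = min(b[, 1]), xmax = max(b[, 2]),
    ymin = min(b[, 3]), ymax = max(b[, 4]),
    zmin = min(b[, 5]), zmax = max(b[, 6]))
})

#' @rdname containsPoints
#' @export
setMethod("containsPoints", "WMRegion", function(x, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  b <- x@boxes
  inside <- rep(FALSE, nrow(points))
  for (i in seq_len(nrow(b))) {
    inside <- inside |
      (points[, 1] >= b[i, 1] & points[, 1] <= b[i, 2] &
       points[, 2] >= b[i, 3] & points[, 2] <= b[i, 4] &
       points[, 3] >= b[i, 5] & points[, 3] <= b[i, 6])
  }
  inside
})

setMethod("show", "WMRegion", function(object) {
  cat(sprintf("WMRegion: %d box(es), volume %.4f mm^3\n",
              nrow(object@boxes), regionVolume(object)))
  invisible(object)
})

#' Shrink a region inwards
#'
#' Erodes every box of the region by `margin` on all six faces. Used to
#' sample probe-field locations that stay clear of the phantom boundary:
#' for networks with uniformly distributed midpoints the interior
#' length/volume/surface density equals total/volume exactly, so
#' interior-only field sampling keeps the probe estimators unbiased.
#'
#' @param x a [WMRegion-class].
#' @param margin erosion distance (mm), applied to each face.
#' @return an eroded [WMRegion-class]; boxes that vanish are dropped.
#' @export
erodeRegion <- function(x, margin) {
  stopIfNot(margin >= 0, "margin must be non-negative")
  b <- x@boxes
  b[, c(1, 3, 5)] <- b[, c(1, 3, 5)] + margin
  b[, c(2, 4, 6)] <- b[, c(2, 4, 6)] - margin
  keep <- b[, 2] > b[, 1] & b[, 4] > b[, 3] & b[, 6] > b[, 5]
  stopIfNot(any(keep), "erosion margin swallows the whole region")
  wmRegion(b[keep, , drop = FALSE])
}

#' Planar cross-section of a region
#'
#' Intersects the region with the plane `axis = level` and returns the
#' cross-section as a set of axis-aligned rectangles in the two remaining
#' coordinates (in their natural order, e.g. x,y for `axis = "z"`).
#'
#' @param x a [WMRegion-class].
#' @param level coordinate of the cutting plane (mm).
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @return numeric matrix (possibly 0-row) with columns
#'   `umin, umax, vmin, vmax`.
#' @export
regionCrossSection <- function(x, level, axis = "z") {
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  b <- x@boxes
  lo <- b[, 2 * ax - 1]
  hi <- b[, 2 * ax]
  hit <- level > lo & level < hi
  keep <- setdiff(1:3, ax)
  cols <- c(2 * keep[1] - 1, 2 * keep[1], 2 * keep[2] - 1, 2 * keep[2])
  out <- b[hit, cols, drop = FALSE]
  colnames(out) <- c("umin", "umax", "vmin", "vmax")
  out
}

# Uniform random points inside a region (box chosen w.p. proportional to
# its volume). Returns n x 3 matrix.
runifRegion <- function(region, n) {
  b <- region@boxes
  vols <- (b[, 2] - b[, 1]) * (b[, 4] - b[, 3]) * (b[, 6] - b[, 5])
  idx <- if (nrow(b) == 1) rep(1L, n) else {
    sample.int(nrow(b), n, replace = TRUE, prob = vols)
  }
  cbind(stats::runif(n, b[idx, 1], b[idx, 2]),
        stats::runif(n, b[idx, 3], b[idx, 4]),
        stats::runif(n, b[idx, 5], b[idx, 6]))
}
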