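# Independent geometric oracles used across the suite. They share no code
# with the package: the quadratic form is written out directly and all
# intersection decisions come from dense sampling.

# Quadratic form of a point w.r.t. an ellipse (1 on the boundary).
oracleQuad <- function(x, y, pr) {
  dx <- x - pr$u; dy <- y - pr$v
  ca <- cos(pr$angle); sa <- sin(pr$angle)
  ((ca * dx + sa * dy) / pr$major)^2 + ((-sa * dx + ca * dy) / pr$minor)^2
}

# Does the closed ellipse meet the closed segment? Dense sampling of the
# segment; margin = how far the decision is from a tangency (values of
# min q near 1 are degenerate and should be skipped by callers). Long
# segments (e.g. the frame's forbidden-ray extensions) are first clipped
# to the part within reach of the ellipse so the sampling stays dense.
oracleMeetsSegment <- function(a, b, pr, nSamp = 4001) {
  d <- b - a
  len2 <- sum(d * d)
  t0 <- 0; t1 <- 1
  if (len2 > 0) {
    tc <- sum((c(pr$u, pr$v) - a) * d) / len2
    reach <- (max(pr$major, pr$minor) + 1e-9) / sqrt(len2)
    t0 <- max(0, tc - reach); t1 <- min(1, tc + reach)
    if (t1 <= t0) {
      # segment never comes within one semi-major axis of the centre
      return(list(meets = FALSE, margin = Inf))
    }
  }
  t <- seq(t0, t1, length.out = nSamp)
  q <- oracleQuad(a[1] + t * d[1], a[2] + t * d[2], pr)
  list(meets = min(q) <= 1, margin = abs(min(q) - 1))
}

# Transversal crossing count: sign changes of q - 1 along the segment.
oracleCrossings <- function(a, b, pr, nSamp = 20001) {
  t <- seq(0, 1, length.out = nSamp)
  f <- oracleQuad(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]), pr) - 1
  sgn <- sign(f)
  list(crossings = sum(abs(diff(sgn)) == 2), margin = min(abs(f)))
}

# Counting-frame decision by dense sampling: intersects the closed frame
# (any of a dense set of ellipse points, boundary and interior, inside
# the rectangle, or any frame corner inside the ellipse) and touches no
# forbidden line. Returns the decision and a degeneracy margin.
oracleFrameCounts <- function(pr, frame, nSamp = 721) {
  th <- seq(0, 2 * pi, length.out = nSamp)
  margin <- Inf
  # dense ellipse points at several radial depths
  px <- NULL; py <- NULL
  for (rho in c(1, 0.75, 0.5, 0.25, 0.01)) {
    ca <- cos(pr$angle); sa <- sin(pr$angle)
    ex <- rho * pr$major * cos(th); ey <- rho * pr$minor * sin(th)
    px <- c(px, pr$u + ca * ex - sa * ey)
    py <- c(py, pr$v + sa * ex + ca * ey)
  }
  inRect <- px >= frame$xmin & px <= frame$xmax &
            py >= frame$ymin & py <= frame$ymax
  cornerIn <- any(oracleQuad(c(frame$xmin, frame$xmax, frame$xmax,
                               frame$xmin),
                             c(frame$ymin, frame$ymin, frame$ymax,
                               frame$ymax), pr) <= 1)
  meets <- any(inRect) || cornerIn
  big <- 1e3
  forb <- list(
    rbind(c(frame$xmin, frame$ymin), c(frame$xmax, frame$ymin)), # bottom
    rbind(c(frame$xmin, frame$ymin), c(frame$xmin, frame$ymax)), # left
    rbind(c(frame$xmin, frame$ymax), c(frame$xmin, frame$ymax + big)),
    rbind(c(frame$xmax, frame$ymin), c(frame$xmax, frame$ymin - big)))
  touch2 <- logical(4)
  for (k in 1:4) {
    o <- oracleMeetsSegment(forb[[k]][1, ], forb[[k]][2, ], pr)
    touch2[k] <- o$meets
    margin <- min(margin, o$margin)
  }
  list(gundersen = meets && !any(touch2),
       simple = meets && !any(touch2[1:2]),
       margin = margin)
}

# Build a profile row with the sectionNetwork() schema.
makeProfile <- function(u, v, major, minor, angle = 0, capillary = TRUE) {
  data.frame(cylinder = 1L, u = u, v = v, major = major, minor = minor,
             angle = angle, diameterUm = 2000 * minor,
             capillary = capillary)
}

# Tiny single-cylinder network built directly (bypasses the generator) so
# sectioning geometry can be checked against hand values.
singleCylinderNetwork <- function(a, b, r, boxDims = c(1, 1, 1)) {
  cyl <- matrix(c(a, b, r), nrow = 1)
  colnames(cyl) <- c("ax", "ay", "az", "bx", "by", "bz", "r")
  len <- sqrt(sum((b - a)^2))
  methods::new("CapillaryNetwork", cylinders = cyl,
               region = boxRegion(boxDims),
               truth = list(L_mm = len, Vcap_mm3 = pi * r^2 * len,
                            Scap_mm2 = 2 * pi * r * len,
                            Vwm_mm3 = prod(boxDims)),
               meta = list(orientation = "fixed", seed = NA))
}
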