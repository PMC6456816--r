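#' Derive a reproducible child seed
#'
#' Folds a master seed and an arbitrary sequence of tags (animal ids,
#' stage names, section indices, ...) into a new 31-bit seed with a rolling
#' polynomial hash. The same master seed and tags always give the same
#' child, independent of evaluation order, so every animal/section/field
#' can draw its randomness from its own stream.
#'
#' @param seed integer master seed.
#' @param ... tags (coerced to character) identifying the random stream.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' childSeed(1, "animal", 3, "section", 7)
childSeed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(abs(as.double(seed)) %% m)
  tags <- unlist(lapply(list(...), as.character), use.names = FALSE)
  for (tag in tags) {
    for (code in utf8ToInt(tag)) {
      h <- (h * 131 + code) %% m
    }
  }
  # nonlinear finalizer: two modular-squaring rounds. The rolling hash is
  # affine in its inputs, so families of sibling seeds (rep 1, 2, 3, ...)
  # would otherwise form arithmetic progressions, which leak detectable
  # structure into the first draws of the seeded generator.
  for (r in 1:2) {
    h1 <- floor(h / 65536)
    h0 <- h - h1 * 65536
    sq <- ((h1 * h1) %% m) * 2 %% m       # (h1^2 * 2^32) mod m
    sq <- (sq + ((2 * h1 * h0) %% m) * 65536) %% m
    sq <- (sq + h0 * h0) %% m
    h <- (sq + 0x9E3779B9 %% m + r) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Uniform directions on the unit sphere: z ~ U(-1, 1), azimuth ~ U(0, 2*pi).
runifSphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  az <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(x = s * cos(az), y = s * sin(az), z = z)
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
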