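#' @rdname wmRegion
#' @param x a `WMRegion` (or object containing one).
#' @export
setGeneric("regionVolume", function(x) standardGeneric("regionVolume"))

#' @rdname wmRegion
#' @export
setGeneric("regionBounds", function(x) standardGeneric("regionBounds"))

#' Exact point membership in a region
#'
#' @param x a [WMRegion-class].
#' @param points numeric matrix (n x 3) of xyz coordinates in mm.
#' @return logical vector: point lies in the closed region.
#' @export
setGeneric("containsPoints",
           function(x, points) standardGeneric("containsPoints"))

#' @rdname generateNetwork
#' @export
setGeneric("cylinders", function(x) standardGeneric("cylinders"))

#' @rdname generateNetwork
#' @export
setGeneric("networkTruth", function(x) standardGeneric("networkTruth"))

#' @rdname generateNetwork
#' @export
setGeneric("nCylinders", function(x) standardGeneric("nCylinders"))

#' @rdname generateCohort
#' @export
setGeneric("animals", function(x) standardGeneric("animals"))

#' @rdname generateCohort
#' @export
setGeneric("latencies", function(x) standardGeneric("latencies"))
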