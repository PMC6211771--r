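#' @include AllClasses.R
NULL

#' Accessors for fanotune containers
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x a fanotune object.
#' @return \code{spikeCounts} returns the underlying count array;
#'   \code{directions} the direction labels in degrees; \code{countWindow}
#'   the counting window; \code{crBound} the Cramer-Rao bound in degrees;
#'   \code{fisherInfo} a two-column matrix of \code{J0} and \code{J_eps}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spikeCounts", function(x) standardGeneric("spikeCounts"))

#' @rdname accessors
#' @export
setGeneric("directions", function(x) standardGeneric("directions"))

#' @rdname accessors
#' @export
setGeneric("countWindow", function(x) standardGeneric("countWindow"))

#' @rdname accessors
#' @export
setGeneric("crBound", function(x) standardGeneric("crBound"))

#' @rdname accessors
#' @export
setGeneric("fisherInfo", function(x) standardGeneric("fisherInfo"))

#' @rdname accessors
#' @export
setMethod("spikeCounts", "CountMatrix", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("spikeCounts", "BinnedSpikeTensor", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("directions", "CountMatrix", function(x) x@directions)

#' @rdname accessors
#' @export
setMethod("directions", "BinnedSpikeTensor", function(x) x@directions)

#' @rdname accessors
#' @export
setMethod("countWindow", "CountMatrix", function(x) x@window)

#' @rdname accessors
#' @export
setMethod("crBound", "DecodingResult", function(x) x@cr_bound_deg)

#' @rdname accessors
#' @export
setMethod("fisherInfo", "DecodingResult",
          function(x) cbind(J0 = x@J0, J_eps = x@J_eps))
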