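#' Accessors for tauGWAS data classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `callMatrix` (character calls), `genotypeMatrix` (encoded values),
#' `adjustedMatrix` (continuous residualized values), `deltaK` (per-sample
#' additive-shift remainder), `encodingOf` / `encodingValues` /
#' `encodingLabel`, `numAxes` (K), `basisVectors` and `eigenValues`.
#'
#' @param x an object of the documented class.
#' @return The matrix, vector or scalar named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("callMatrix", function(x) standardGeneric("callMatrix"))
#' @rdname accessors
#' @export
setMethod("callMatrix", "GenotypeCalls", function(x) assay(x, "calls"))

#' @rdname accessors
#' @export
setGeneric("genotypeMatrix", function(x) standardGeneric("genotypeMatrix"))
#' @rdname accessors
#' @export
setMethod("genotypeMatrix", "EncodedGenotypes",
    function(x) assay(x, "genotypes"))

#' @rdname accessors
#' @export
setGeneric("adjustedMatrix", function(x) standardGeneric("adjustedMatrix"))
#' @rdname accessors
#' @export
setMethod("adjustedMatrix", "AdjustedGenotypes",
    function(x) assay(x, "adjusted"))

#' @rdname accessors
#' @export
setGeneric("deltaK", function(x) standardGeneric("deltaK"))
#' @rdname accessors
#' @export
setMethod("deltaK", "AdjustedGenotypes",
    function(x) setNames(colData(x)$deltaK, colnames(x)))

#' @rdname accessors
#' @export
setGeneric("encodingOf", function(x) standardGeneric("encodingOf"))
#' @rdname accessors
#' @export
setMethod("encodingOf", "EncodedGenotypes", function(x) x@encoding)

#' @rdname accessors
#' @export
setGeneric("encodingValues", function(x) standardGeneric("encodingValues"))
#' @rdname accessors
#' @export
setMethod("encodingValues", "Encoding", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("encodingValues", "EncodedGenotypes", function(x) x@encoding@values)

#' @rdname accessors
#' @export
setGeneric("encodingLabel", function(x) standardGeneric("encodingLabel"))
#' @rdname accessors
#' @export
setMethod("encodingLabel", "Encoding", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("encodingLabel", "EncodedGenotypes", function(x) x@encoding@label)
#' @rdname accessors
#' @export
setMethod("encodingLabel", "AdjustedGenotypes", function(x) x@encodingLabel)

#' @rdname accessors
#' @export
setGeneric("numAxes", function(x) standardGeneric("numAxes"))
#' @rdname accessors
#' @export
setMethod("numAxes", "AdjustedGenotypes", function(x) x@K)
#' @rdname accessors
#' @export
setMethod("numAxes", "EigenBasis", function(x) ncol(x@vectors))

#' @rdname accessors
#' @export
setGeneric("basisVectors", function(x) standardGeneric("basisVectors"))
#' @rdname accessors
#' @export
setMethod("basisVectors", "EigenBasis", function(x) x@vectors)

#' @rdname accessors
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))
#' @rdname accessors
#' @export
setMethod("eigenValues", "EigenBasis", function(x) x@eigenvalues)
#' @rdname accessors
#' @export
setMethod("eigenValues", "AdjustedGenotypes", function(x) x@eigenvalues)
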