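## Accessor generics and methods for the core containers.

#' @rdname accessors
#' @param object a proteoMR container object.
#' @export
setGeneric("dosage", function(object) standardGeneric("dosage"))

#' Accessors for proteoMR containers
#'
#' \code{dosage} returns the samples x variants dosage matrix;
#' \code{variantInfo} the variant metadata; \code{assayValues} the
#' samples x analytes abundance matrix; \code{analyteInfo} the analyte
#' annotation; \code{transformState} the transform state of a
#' \linkS4class{ProteinMatrix}; \code{instruments} the instrument table of an
#' \linkS4class{InstrumentSet} and \code{ldMatrix} its signed LD matrix.
#'
#' @name accessors
#' @rdname accessors
#' @export
setMethod("dosage", "GenotypeMatrix", function(object) object@dosage)

#' @rdname accessors
#' @export
setGeneric("variantInfo", function(object) standardGeneric("variantInfo"))

#' @rdname accessors
#' @export
setMethod("variantInfo", "GenotypeMatrix", function(object) object@variants)

#' @rdname accessors
#' @export
setGeneric("assayValues", function(object) standardGeneric("assayValues"))

#' @rdname accessors
#' @export
setMethod("assayValues", "ProteinMatrix", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("analyteInfo", function(object) standardGeneric("analyteInfo"))

#' @rdname accessors
#' @export
setMethod("analyteInfo", "ProteinMatrix", function(object) object@analytes)

#' @rdname accessors
#' @export
setGeneric("transformState", function(object) standardGeneric("transformState"))

#' @rdname accessors
#' @export
setMethod("transformState", "ProteinMatrix", function(object) object@state)

#' @rdname accessors
#' @export
setGeneric("instruments", function(object) standardGeneric("instruments"))

#' @rdname accessors
#' @export
setMethod("instruments", "InstrumentSet", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("ldMatrix", function(object) standardGeneric("ldMatrix"))

#' @rdname accessors
#' @export
setMethod("ldMatrix", "InstrumentSet", function(object) object@ld)

#' @rdname accessors
#' @export
setGeneric("gateStatus", function(object) standardGeneric("gateStatus"))

#' @rdname accessors
#' @export
setMethod("gateStatus", "MREstimate", function(object) object@gate)
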