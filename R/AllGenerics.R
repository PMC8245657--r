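#' Accessors for neoprofiler S4 classes
#'
#' Standard accessors: slot access from user code should go through these.
#'
#' @param x a [TranscriptModel-class] or [SyntheticPatient-class] object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneSymbol", function(x) standardGeneric("geneSymbol"))
#' @rdname accessors
#' @export
setGeneric("cdsSequence", function(x) standardGeneric("cdsSequence"))
#' @rdname accessors
#' @export
setGeneric("proteinSequence", function(x) standardGeneric("proteinSequence"))
#' @rdname accessors
#' @export
setGeneric("exonBoundaries", function(x) standardGeneric("exonBoundaries"))
#' @rdname accessors
#' @export
setGeneric("cdsStrand", function(x) standardGeneric("cdsStrand"))
#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setGeneric("subtype", function(x) standardGeneric("subtype"))
#' @rdname accessors
#' @export
setGeneric("trueVariants", function(x) standardGeneric("trueVariants"))
#' @rdname accessors
#' @export
setGeneric("alleleCounts", function(x) standardGeneric("alleleCounts"))
#' @rdname accessors
#' @export
setGeneric("rnaReadCounts", function(x) standardGeneric("rnaReadCounts"))
#' @rdname accessors
#' @export
setGeneric("hlaAlleles", function(x) standardGeneric("hlaAlleles"))

#' @rdname accessors
setMethod("geneSymbol", "TranscriptModel", function(x) x@geneSymbol)
#' @rdname accessors
setMethod("cdsSequence", "TranscriptModel", function(x) x@cds)
#' @rdname accessors
setMethod("proteinSequence", "TranscriptModel", function(x) x@protein)
#' @rdname accessors
setMethod("exonBoundaries", "TranscriptModel", function(x) x@exonBoundaries)
#' @rdname accessors
setMethod("cdsStrand", "TranscriptModel", function(x) x@strand)
#' @rdname accessors
setMethod("patientId", "SyntheticPatient", function(x) x@patientId)
#' @rdname accessors
setMethod("subtype", "SyntheticPatient", function(x) x@subtype)
#' @rdname accessors
setMethod("trueVariants", "SyntheticPatient", function(x) x@trueVariants)
#' @rdname accessors
setMethod("alleleCounts", "SyntheticPatient", function(x) x@alleleCounts)
#' @rdname accessors
setMethod("rnaReadCounts", "SyntheticPatient", function(x) x@rnaReadCounts)
#' @rdname accessors
setMethod("hlaAlleles", "SyntheticPatient", function(x) x@hlaAlleles)
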