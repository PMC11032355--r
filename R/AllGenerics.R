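#' @rdname GenomeRecord-class
#' @param object,x a \code{GenomeRecord} / \code{GenusSimulation}.
#' @export
setGeneric("speciesId", function(x) standardGeneric("speciesId"))

#' @rdname GenomeRecord-class
#' @export
setGeneric("markerGenes", function(x) standardGeneric("markerGenes"))

#' @rdname GenomeRecord-class
#' @export
setGeneric("rrnaCopies", function(x) standardGeneric("rrnaCopies"))

#' @rdname GenusSimulation-class
#' @export
setGeneric("simTree", function(x) standardGeneric("simTree"))

#' @rdname GenusSimulation-class
#' @export
setGeneric("simGenomes", function(x) standardGeneric("simGenomes"))

#' @rdname GenusSimulation-class
#' @export
setGeneric("eventLog", function(x) standardGeneric("eventLog"))

#' @rdname VariantCatalog-class
#' @export
setGeneric("variantLabels", function(x) standardGeneric("variantLabels"))

#' @rdname VariantCatalog-class
#' @export
setGeneric("variantSequences", function(x) standardGeneric("variantSequences"))
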