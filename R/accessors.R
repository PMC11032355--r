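#' @rdname GenomeRecord-class
#' @aliases speciesId,GenomeRecord-method
setMethod("speciesId", "GenomeRecord", function(x) x@speciesId)

#' @rdname GenomeRecord-class
#' @aliases markerGenes,GenomeRecord-method
setMethod("markerGenes", "GenomeRecord", function(x) x@genes)

#' @rdname GenomeRecord-class
#' @aliases rrnaCopies,GenomeRecord-method
setMethod("rrnaCopies", "GenomeRecord", function(x) x@rrnaCopies)

#' @rdname GenusSimulation-class
#' @aliases simTree,GenusSimulation-method
setMethod("simTree", "GenusSimulation", function(x) x@tree)

#' @rdname GenusSimulation-class
#' @aliases simGenomes,GenusSimulation-method
setMethod("simGenomes", "GenusSimulation", function(x) x@genomes)

#' @rdname GenusSimulation-class
#' @aliases eventLog,GenusSimulation-method
setMethod("eventLog", "GenusSimulation", function(x) x@events)

#' @rdname GenusSimulation-class
#' @aliases speciesId,GenusSimulation-method
setMethod("speciesId", "GenusSimulation", function(x)
  vapply(x@genomes, function(g) g@speciesId, character(1), USE.NAMES = FALSE))

#' @rdname VariantCatalog-class
#' @aliases variantLabels,VariantCatalog-method
setMethod("variantLabels", "VariantCatalog", function(x) names(x@variants))

#' @rdname VariantCatalog-class
#' @aliases variantSequences,VariantCatalog-method
setMethod("variantSequences", "VariantCatalog", function(x) x@variants)

setMethod("show", "GenomeRecord", function(object) {
  cat("GenomeRecord:", object@speciesId, "\n")
  cat(" ", length(object@genes), "marker genes;",
      length(object@rrnaCopies), "rRNA copies\n")
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "GenusSimulation", function(object) {
  cat("GenusSimulation with", length(object@genomes), "genomes\n")
  cat("  tree depth:",
      format(max(ape::node.depth.edgelength(object@tree)), digits = 4),
      "substitutions/site\n")
  ev <- table(object@events$event_type)
  if (length(ev)) {
    cat("  events:", paste(sprintf("%s=%d", names(ev), ev), collapse = ", "),
        "\n")
  } else cat("  events: none\n")
})

setMethod("show", "AlignmentResult", function(object) {
  cat("AlignmentResult: length", nchar(object@alignedA),
      sprintf("(%d matches, %d mismatches, %d gap columns in %d openings)\n",
              object@matches, object@mismatches, object@gapColumns,
              object@gapOpenings))
  cat("  score:", object@score, " identity:",
      format(percentIdentity(object), digits = 6), "%\n")
})

setMethod("show", "ANIResult", function(object) {
  cat(sprintf("ANI: %.3f%% (forward %.3f%%, reverse %.3f%%)\n",
              object@ani, object@forward$ani, object@reverse$ani))
  cat(sprintf("  fragments used: %d/%d and %d/%d\n",
              object@forward$nUsed, object@forward$nTotal,
              object@reverse$nUsed, object@reverse$nTotal))
})

setMethod("show", "RateFit", function(object) {
  cat("RateFit:", object@model, "\n")
  co <- paste(sprintf("%s=%.5g", names(object@coefficients),
                      object@coefficients), collapse = ", ")
  cat("  coefficients:", co, "\n")
  cat(sprintf("  rss=%.6g on n=%d points", object@rss, object@n))
  if (!is.na(object@fStatistic))
    cat(sprintf("; F=%.4g, p=%.4g, selected=%s",
                object@fStatistic, object@pValue, object@selected))
  cat("\n")
})

setMethod("show", "VariantCatalog", function(object) {
  cat("VariantCatalog with", length(object@variants), "variants:",
      paste(names(object@variants), collapse = ", "), "\n")
  cat("  minSep =", object@minSep, "; assignRadius =", object@assignRadius,
      "\n")
})

setMethod("show", "SCOTable", function(object) {
  cat("SCOTable:", nrow(object@sequences), "single-copy orthologs x",
      ncol(object@sequences), "species (", object@seqType, ")\n")
})
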