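#' @rdname VirtualTagIndex-class
#' @param object,x a \linkS4class{VirtualTagIndex}, \linkS4class{TagLibrary}
#'   or \linkS4class{ExpressionScenario} as appropriate.
#' @export
setGeneric("tagKeys", function(x) standardGeneric("tagKeys"))

#' @rdname VirtualTagIndex-class
#' @export
setMethod("tagKeys", "VirtualTagIndex", function(x) names(x@tag2gene))

#' @rdname VirtualTagIndex-class
#' @export
setGeneric("tagGenes", function(x) standardGeneric("tagGenes"))

#' @rdname VirtualTagIndex-class
#' @export
setMethod("tagGenes", "VirtualTagIndex", function(x) x@tag2gene)

#' @rdname VirtualTagIndex-class
#' @export
setGeneric("ambiguousTags", function(x) standardGeneric("ambiguousTags"))

#' @rdname VirtualTagIndex-class
#' @export
setMethod("ambiguousTags", "VirtualTagIndex", function(x) {
  names(x@tag2gene)[lengths(x@tag2gene) > 1L]
})

#' @rdname VirtualTagIndex-class
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))

#' @rdname VirtualTagIndex-class
#' @export
setMethod("siteTable", "VirtualTagIndex", function(x) x@sites)

#' @rdname VirtualTagIndex-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname VirtualTagIndex-class
#' @export
setMethod("geneIds", "VirtualTagIndex", function(x) x@geneIds)

#' @rdname VirtualTagIndex-class
#' @export
setMethod("geneIds", "ExpressionScenario", function(x) x@geneIds)

#' @rdname TagLibrary-class
#' @export
setGeneric("libraryId", function(x) standardGeneric("libraryId"))

#' @rdname TagLibrary-class
#' @export
setMethod("libraryId", "TagLibrary", function(x) x@libraryId)

#' @rdname TagLibrary-class
#' @export
setGeneric("cleanCounts", function(x) standardGeneric("cleanCounts"))

#' @rdname TagLibrary-class
#' @export
setMethod("cleanCounts", "TagLibrary", function(x) x@cleanCounts)

#' @rdname TagLibrary-class
#' @export
setGeneric("totalCleanTags", function(x) standardGeneric("totalCleanTags"))

#' @rdname TagLibrary-class
#' @export
setMethod("totalCleanTags", "TagLibrary", function(x) sum(x@cleanCounts))

#' @rdname TagLibrary-class
#' @export
setGeneric("filterStats", function(x) standardGeneric("filterStats"))

#' @rdname TagLibrary-class
#' @export
setMethod("filterStats", "TagLibrary", function(x) x@filterStats)

#' @rdname ExpressionScenario-class
#' @export
setGeneric("baselineAbundance", function(x) standardGeneric("baselineAbundance"))

#' @rdname ExpressionScenario-class
#' @export
setMethod("baselineAbundance", "ExpressionScenario", function(x) {
  structure(x@baselineAbundance, names = x@geneIds)
})

#' @rdname ExpressionScenario-class
#' @param condition \code{"A"} (baseline) or \code{"B"} (treatment).
#' @export
setGeneric("conditionAbundance",
           function(x, condition = "A") standardGeneric("conditionAbundance"))

#' @rdname ExpressionScenario-class
#' @export
setMethod("conditionAbundance", "ExpressionScenario",
  function(x, condition = "A") {
    condition <- match.arg(condition, c("A", "B"))
    ab <- if (condition == "A") x@baselineAbundance else x@abundanceB
    structure(ab, names = x@geneIds)
  })

#' @rdname ExpressionScenario-class
#' @export
setGeneric("deLabels", function(x) standardGeneric("deLabels"))

#' @rdname ExpressionScenario-class
#' @export
setMethod("deLabels", "ExpressionScenario", function(x) {
  structure(x@deLabels, names = x@geneIds)
})

#' @rdname ExpressionScenario-class
#' @export
setGeneric("plantedLog2fc", function(x) standardGeneric("plantedLog2fc"))

#' @rdname ExpressionScenario-class
#' @export
setMethod("plantedLog2fc", "ExpressionScenario", function(x) {
  structure(x@conditionLog2fc, names = x@geneIds)
})

#' Per-library clean-tag totals of a count container
#'
#' @param x a \linkS4class{TagCountExperiment}.
#' @return named numeric vector of clean-tag totals per library.
#' @export
cleanTotals <- function(x) {
  stopifnot(is(x, "TagCountExperiment"))
  structure(as.numeric(SummarizedExperiment::colData(x)$cleanTotal),
            names = colnames(x))
}

setMethod("show", "VirtualTagIndex", function(object) {
  cat("VirtualTagIndex\n")
  cat("  genes in reference: ", length(object@geneIds), "\n", sep = "")
  cat("  CATG sites indexed: ", nrow(object@sites), "\n", sep = "")
  cat("  distinct tags:      ", length(object@tag2gene), "\n", sep = "")
  cat("  ambiguous tags:     ",
      sum(lengths(object@tag2gene) > 1L), "\n", sep = "")
})

setMethod("show", "TagLibrary", function(object) {
  fs <- object@filterStats
  cat("TagLibrary '", object@libraryId, "'\n", sep = "")
  cat("  raw reads:     ", fs[["raw_total"]], "\n", sep = "")
  cat("  clean tags:    ", sum(object@cleanCounts),
      " (", length(object@cleanCounts), " distinct)\n", sep = "")
  cat("  removed:       ",
      paste(sprintf("%s=%d", .FILTER_CLASSES, fs[.FILTER_CLASSES]),
            collapse = ", "), "\n", sep = "")
})

setMethod("show", "NoiseProfile", function(object) {
  cat("NoiseProfile\n")
  cat(sprintf("  per-base error rate: %g\n", object@perBaseErrorRate))
  cat(sprintf("  junk fractions: adaptor=%g empty=%g length=%g ambiguous=%g\n",
              object@adaptorFraction, object@emptyFraction,
              object@lengthAnomalyFraction, object@ambiguousBaseFraction))
  cat(sprintf("  seed: %d\n", object@seed))
})

setMethod("show", "ExpressionScenario", function(object) {
  tab <- table(factor(object@deLabels, levels = c("up", "down", "null")))
  cat("ExpressionScenario\n")
  cat("  genes: ", length(object@geneIds), "\n", sep = "")
  cat(sprintf("  planted DE: %d up, %d down (null %d)\n",
              tab[["up"]], tab[["down"]], tab[["null"]]))
})
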