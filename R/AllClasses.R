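#' @import methods
#' @importFrom S4Vectors DataFrame metadata
NULL

TAG_LENGTH <- 21L
ANCHOR <- "CATG"
SUFFIX_LENGTH <- TAG_LENGTH - nchar(ANCHOR) # 17 nt variable region

#' Virtual reference tag index
#'
#' Maps every possible CATG + 17 nt tag extractable from a transcript set to
#' the genes that carry it on the sense strand.  Tags found in more than one
#' gene are flagged ambiguous; sites whose 17 nt window contains an ambiguous
#' base (N) are skipped at construction time.
#'
#' @slot tag2gene named list; each element is the character vector of gene
#'   identifiers carrying that 21 nt tag verbatim.
#' @slot sites data.frame with columns \code{gene_id} and \code{offset}
#'   (0-based offset of the CATG start; the tag occupies the half-open
#'   interval [offset, offset + 21)).
#' @slot geneIds character, all gene identifiers of the source transcript
#'   set, including genes that contributed no valid site.
#'
#' @seealso [buildTagIndex()], [resolveTags()]
#' @export
setClass("VirtualTagIndex",
  representation(
    tag2gene = "list",
    sites = "data.frame",
    geneIds = "character"
  )
)

setValidity("VirtualTagIndex", function(object) {
  tags <- names(object@tag2gene)
  if (length(object@tag2gene) > 0L) {
    if (is.null(tags) || anyNA(tags)) {
      return("tag2gene must be named by tag sequence")
    }
    if (any(nchar(tags) != TAG_LENGTH)) {
      return(sprintf("all index tags must be %d nt long", TAG_LENGTH))
    }
    if (!all(startsWith(tags, ANCHOR))) {
      return(sprintf("all index tags must begin with %s", ANCHOR))
    }
  }
  if (!all(c("gene_id", "offset") %in% names(object@sites))) {
    return("sites must have columns gene_id and offset")
  }
  TRUE
})

#' Cleaned tag library
#'
#' A per-library multiset of clean 21 nt tags together with exact accounting
#' of what the five cleaning filters removed.  Every retained tag is 21 nt,
#' free of ambiguous bases, and has library copy number >= 2.
#'
#' @slot libraryId single library identifier.
#' @slot cleanCounts named integer vector, tag sequence -> copy number (>= 2).
#' @slot filterStats named integer vector with elements \code{raw_total},
#'   \code{adaptor}, \code{empty}, \code{low_quality}, \code{length},
#'   \code{singleton}: reads removed by each filter class, each raw read
#'   charged to exactly one class.
#'
#' @seealso [cleanTags()]
#' @export
setClass("TagLibrary",
  representation(
    libraryId = "character",
    cleanCounts = "integer",
    filterStats = "integer"
  )
)

.FILTER_CLASSES <- c("adaptor", "empty", "low_quality", "length", "singleton")

setValidity("TagLibrary", function(object) {
  if (length(object@libraryId) != 1L) return("libraryId must be length 1")
  need <- c("raw_total", .FILTER_CLASSES)
  if (!all(need %in% names(object@filterStats))) {
    return(paste("filterStats must contain:", paste(need, collapse = ", ")))
  }
  fs <- object@filterStats
  if (fs[["raw_total"]] !=
      sum(object@cleanCounts) + sum(fs[.FILTER_CLASSES])) {
    return("read conservation violated: raw_total != clean + removed")
  }
  if (length(object@cleanCounts) > 0L) {
    if (any(object@cleanCounts < 2L)) {
      return("every retained tag must have copy number >= 2")
    }
    if (any(nchar(names(object@cleanCounts)) != TAG_LENGTH)) {
      return(sprintf("retained tags must be %d nt", TAG_LENGTH))
    }
    if (any(grepl("N", names(object@cleanCounts), fixed = TRUE))) {
      return("retained tags must not contain ambiguous bases")
    }
  }
  TRUE
})

#' Noise model for simulated tag libraries
#'
#' Parameters of the read-level noise channel applied by
#' [simulateTagLibrary()]: per-base substitution error on informative reads
#' and the four junk-read classes removed by the cleaning filters.  Junk
#' classes are mutually exclusive per read and assigned in the fixed priority
#' order adaptor > empty > length > ambiguous-base.
#'
#' @slot perBaseErrorRate substitution probability per nucleotide, in
#'   [0, 0.25].
#' @slot adaptorFraction fraction of reads that are tag + 3' adaptor.
#' @slot emptyFraction fraction that are adaptor-only (no tag).
#' @slot lengthAnomalyFraction fraction with length != 21 nt.
#' @slot ambiguousBaseFraction fraction carrying >= 1 N.
#' @slot seed integer seed driving the whole simulation of one library.
#'
#' @export
setClass("NoiseProfile",
  representation(
    perBaseErrorRate = "numeric",
    adaptorFraction = "numeric",
    emptyFraction = "numeric",
    lengthAnomalyFraction = "numeric",
    ambiguousBaseFraction = "numeric",
    seed = "integer"
  )
)

setValidity("NoiseProfile", function(object) {
  fr <- c(object@adaptorFraction, object@emptyFraction,
          object@lengthAnomalyFraction, object@ambiguousBaseFraction)
  if (any(fr < 0) || any(fr > 1)) return("junk fractions must lie in [0,1]")
  if (sum(fr) > 1 + 1e-12) return("junk fractions must jointly sum to <= 1")
  if (object@perBaseErrorRate < 0 || object@perBaseErrorRate > 0.25) {
    return("perBaseErrorRate must lie in [0, 0.25]")
  }
  TRUE
})

#' Expression scenario with planted differential structure
#'
#' Ground truth for a two-condition contrast: per-gene baseline relative
#' abundance, planted log2 fold changes, and up/down/null truth labels.
#' Condition A uses the baseline abundances; condition B multiplies the
#' baseline by 2^log2fc and renormalizes, so both condition vectors are
#' probability vectors.
#'
#' @slot geneIds character gene identifiers.
#' @slot baselineAbundance numeric, condition A relative abundance (sums to 1).
#' @slot conditionLog2fc numeric planted log2 fold change (0 for null genes).
#' @slot deLabels character, one of "up", "down", "null" per gene.
#' @slot abundanceB numeric, condition B relative abundance (sums to 1).
#' @slot seed integer seed used to draw the scenario.
#'
#' @seealso [makeDEScenario()]
#' @export
setClass("ExpressionScenario",
  representation(
    geneIds = "character",
    baselineAbundance = "numeric",
    conditionLog2fc = "numeric",
    deLabels = "character",
    abundanceB = "numeric",
    seed = "integer"
  )
)

setValidity("ExpressionScenario", function(object) {
  n <- length(object@geneIds)
  if (length(object@baselineAbundance) != n ||
      length(object@conditionLog2fc) != n ||
      length(object@deLabels) != n ||
      length(object@abundanceB) != n) {
    return("all per-gene slots must have the same length")
  }
  if (anyDuplicated(object@geneIds)) return("gene ids must be unique")
  if (any(object@baselineAbundance < 0) || any(object@abundanceB < 0)) {
    return("abundances must be non-negative")
  }
  if (abs(sum(object@baselineAbundance) - 1) > 1e-8 ||
      abs(sum(object@abundanceB) - 1) > 1e-8) {
    return("abundance vectors must each sum to 1")
  }
  if (!all(object@deLabels %in% c("up", "down", "null"))) {
    return("deLabels must be up/down/null")
  }
  if (any((object@conditionLog2fc != 0) != (object@deLabels != "null"))) {
    return("|log2fc| > 0 iff label != null")
  }
  TRUE
})

#' Gene-by-library tag count container
#'
#' A \linkS4class{SummarizedExperiment} holding the unambiguous tag counts of
#' one or more libraries ("counts" assay) plus, in \code{colData}, the
#' per-library clean-tag totals and mapping statistics needed for TPM
#' normalization and the Audic-Claverie test.  Genes with all-zero rows are
#' retained so the full reference gene set stays available as an enrichment
#' background.
#'
#' @seealso [assembleCountMatrix()], [callDE()]
#' @export
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("TagCountExperiment", contains = "SummarizedExperiment")

setValidity("TagCountExperiment", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    return("a 'counts' assay is required")
  }
  counts <- SummarizedExperiment::assay(object, "counts")
  if (any(counts < 0)) return("counts must be non-negative")
  cd <- SummarizedExperiment::colData(object)
  if (!"cleanTotal" %in% names(cd)) {
    return("colData must contain per-library cleanTotal")
  }
  if (any(colSums(counts) > cd$cleanTotal)) {
    return("column sums must not exceed clean-tag totals")
  }
  TRUE
})
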