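# Tag-to-gene mapping and count-matrix assembly.

#' Map a clean tag library to genes
#'
#' Resolves every distinct clean tag once through [resolveTags()] and
#' credits its whole count to its unique gene, or to the ambiguous or
#' unmapped tallies — no fractional allocation, since tags identifying more
#' than one gene are removed.  Percentages use the total clean tags as
#' denominator, matching the conventional library-statistics table: "mapped"
#' counts tags hitting at least one gene at the governing match level
#' (including ambiguous ones), "unambiguous" counts tags credited to exactly
#' one gene.
#'
#' @param lib a \linkS4class{TagLibrary}.
#' @param index a \linkS4class{VirtualTagIndex}.
#' @return a list with \code{geneCounts} (named integer over all reference
#'   genes; zero where no tag mapped), \code{stats} (one-row data.frame:
#'   \code{library_id}, \code{raw_total}, \code{clean_total},
#'   \code{mapped}, \code{mapped_pct}, \code{unambiguous},
#'   \code{unambiguous_pct}, \code{ambiguous}, \code{unmapped},
#'   \code{genes_detected}) and \code{resolution} (the per-tag audit table
#'   with counts attached).
#' @export
mapLibrary <- function(lib, index) {
  stopifnot(is(lib, "TagLibrary"), is(index, "VirtualTagIndex"))
  cc <- cleanCounts(lib)
  total <- sum(cc)
  res <- resolveTags(names(cc), index)
  res$count <- as.integer(cc)

  geneCounts <- structure(integer(length(geneIds(index))),
                          names = geneIds(index))
  hit <- res$status == "gene"
  if (any(hit)) {
    per <- tapply(res$count[hit], res$gene_id[hit], sum)
    geneCounts[names(per)] <- as.integer(per)
  }
  nUnamb <- sum(res$count[hit])
  nAmb <- sum(res$count[res$status == "ambiguous"])
  nUn <- sum(res$count[res$status == "unmapped"])
  stopifnot(nUnamb + nAmb + nUn == total) # accounting identity, exact
  stats <- data.frame(
    library_id = libraryId(lib),
    raw_total = filterStats(lib)[["raw_total"]],
    clean_total = total,
    mapped = nUnamb + nAmb,
    mapped_pct = if (total > 0) 100 * (nUnamb + nAmb) / total else 0,
    unambiguous = nUnamb,
    unambiguous_pct = if (total > 0) 100 * nUnamb / total else 0,
    ambiguous = nAmb,
    unmapped = nUn,
    genes_detected = sum(geneCounts > 0L),
    stringsAsFactors = FALSE
  )
  list(geneCounts = geneCounts, stats = stats, resolution = res)
}

#' Assemble mapped libraries into a count container
#'
#' Combines per-library gene counts into a gene-by-library
#' \linkS4class{TagCountExperiment}.  Rows are the union of genes across
#' libraries (all reference genes when the libraries were mapped against the
#' same index); missing entries are zero; clean totals and mapping
#' statistics are carried in \code{colData} and \code{metadata}.
#'
#' @param mapped named list of [mapLibrary()] results, or a list with
#'   library ids recoverable from each \code{stats$library_id}.
#' @return a \linkS4class{TagCountExperiment}.
#'
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
#' @export
assembleCountMatrix <- function(mapped) {
  stopifnot(length(mapped) >= 1L)
  ids <- names(mapped)
  if (is.null(ids)) {
    ids <- vapply(mapped, function(m) m$stats$library_id, character(1))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate library ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  genes <- sort(unique(unlist(lapply(mapped,
                                     function(m) names(m$geneCounts)))))
  counts <- matrix(0L, nrow = length(genes), ncol = length(ids),
                   dimnames = list(genes, ids))
  for (j in seq_along(mapped)) {
    gc <- mapped[[j]]$geneCounts
    counts[names(gc), j] <- as.integer(gc)
  }
  statsTab <- do.call(rbind, lapply(mapped, function(m) m$stats))
  rownames(statsTab) <- NULL
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(
      cleanTotal = statsTab$clean_total,
      mapped = statsTab$mapped,
      unambiguous = statsTab$unambiguous,
      ambiguous = statsTab$ambiguous,
      unmapped = statsTab$unmapped,
      genesDetected = statsTab$genes_detected,
      row.names = ids
    )
  )
  out <- new("TagCountExperiment", se)
  S4Vectors::metadata(out)$mappingStats <- statsTab
  out
}

#' Library-statistics table in the conventional layout
#'
#' Formats mapping statistics as the standard DGE library-statistics table:
#' one column per library, rows for raw reads, clean tags, tags mapped to
#' gene (count and %), unambiguous tags mapped (count and %), and
#' unambiguous tag-mapped genes.
#'
#' @param tce a \linkS4class{TagCountExperiment} from [assembleCountMatrix()].
#' @return data.frame with a \code{statistic} column and one column per
#'   library.
#' @export
mappingStatsTable <- function(tce) {
  stopifnot(is(tce, "TagCountExperiment"))
  st <- S4Vectors::metadata(tce)$mappingStats
  if (is.null(st)) stop("no mapping statistics recorded in metadata")
  fmt <- function(x) formatC(x, format = "d")
  pct <- function(x) sprintf("%.2f%%", x)
  rows <- list(
    c("Raw data", fmt(st$raw_total)),
    c("Total number of clean tags", fmt(st$clean_total)),
    c("Clean tags mapped to gene", fmt(st$mapped)),
    c("% of clean tags mapped to gene", pct(st$mapped_pct)),
    c("Unambiguous tags mapped to gene", fmt(st$unambiguous)),
    c("% of unambiguous tags mapped to gene", pct(st$unambiguous_pct)),
    c("Unambiguous tag-mapped genes", fmt(st$genes_detected))
  )
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("statistic", st$library_id)
  out
}
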