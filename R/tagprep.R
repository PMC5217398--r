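# Raw-read cleaning, copy-number classification and saturation analysis.

#' Clean raw tag reads into a tag library
#'
#' Applies the five DGE cleaning filters in their standard order, each read
#' charged to exactly one class so that accounting is exact:
#' \enumerate{
#'   \item adaptor reads — the 3' adaptor's leading k-mer occurs after some
#'     tag sequence (position > 1);
#'   \item empty reads — the adaptor k-mer starts the read (adaptor only,
#'     no tag);
#'   \item low-quality reads — ambiguous base calls (any N);
#'   \item wrong-length reads — length different from 21 nt;
#'   \item singletons — tags with library copy number < 2, removed after
#'     exact-sequence aggregation.
#' }
#'
#' @param reads character vector of raw read sequences, or a
#'   \link[Biostrings]{DNAStringSet}.  Pre-aggregated tag/count input is
#'   supported through \code{counts}.
#' @param adaptor 3' adaptor sequence (non-empty); only its first
#'   \code{adaptorK} nt are matched.
#' @param libraryId identifier stored in the library.
#' @param counts optional integer vector parallel to \code{reads} giving the
#'   multiplicity of each row (for 2-column tag/count TSV input).
#' @param adaptorK adaptor k-mer length used for substring matching.
#' @return a \linkS4class{TagLibrary}.
#'
#' @examples
#' reads <- c(rep(paste0("CATG", strrep("A", 17)), 3), strrep("G", 20))
#' cleanTags(reads, libraryId = "demo")
#' @export
cleanTags <- function(reads, adaptor = DEFAULT_ADAPTOR, libraryId = "lib1",
                      counts = NULL, adaptorK = 8L) {
  if (is(reads, "DNAStringSet") || is(reads, "XStringSet")) {
    reads <- as.character(reads)
  }
  stopifnot(is.character(reads), nzchar(adaptor))
  reads <- toupper(unname(reads))
  if (is.null(counts)) counts <- base::rep(1L, length(reads))
  stopifnot(length(counts) == length(reads), all(counts >= 0))
  counts <- as.integer(counts)

  kmer <- substr(adaptor, 1L, min(adaptorK, nchar(adaptor)))
  pos <- if (length(reads) > 0L) {
    as.integer(regexpr(kmer, reads, fixed = TRUE))
  } else integer(0)

  cls <- base::rep("pass", length(reads))
  cls[nchar(reads) != TAG_LENGTH] <- "length"
  cls[grepl("N", reads, fixed = TRUE)] <- "low_quality"
  cls[pos == 1L] <- "empty"
  cls[pos > 1L] <- "adaptor"

  removed <- vapply(c("adaptor", "empty", "low_quality", "length"),
                    function(k) sum(counts[cls == k]), numeric(1))
  keep <- cls == "pass"
  agg <- if (any(keep)) {
    tapply(counts[keep], reads[keep], sum)
  } else {
    structure(numeric(0), names = character(0))
  }
  agg <- structure(as.integer(agg), names = names(agg))
  singleton <- sum(agg[agg < 2L])
  clean <- agg[agg >= 2L]
  clean <- clean[order(names(clean))]

  new("TagLibrary",
      libraryId = libraryId,
      cleanCounts = clean,
      filterStats = c(raw_total = sum(counts),
                      adaptor = as.integer(removed[["adaptor"]]),
                      empty = as.integer(removed[["empty"]]),
                      low_quality = as.integer(removed[["low_quality"]]),
                      length = as.integer(removed[["length"]]),
                      singleton = as.integer(singleton)))
}

#' Read a 2-column tag/count TSV into a tag library
#'
#' Convenience wrapper around [cleanTags()] for pre-counted input (columns
#' \code{tag}, \code{count}, with or without header).  The same five filters
#' apply; counts weight each row.
#'
#' @param path TSV path.
#' @param ... passed to [cleanTags()].
#' @return a \linkS4class{TagLibrary}.
#' @export
readTagCounts <- function(path, ...) {
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("^tag\\b", first)
  df <- utils::read.delim(path, header = hasHeader,
                          col.names = c("tag", "count"),
                          stringsAsFactors = FALSE)
  cleanTags(df$tag, counts = df$count, ...)
}

#' Copy-number classification of clean tags
#'
#' Classifies clean tags by their library copy number into the supplied bins
#' and reports each bin's share of the total clean tags (copy mass), the
#' standard way DGE library complexity is summarized.
#'
#' @param lib a \linkS4class{TagLibrary}.
#' @param breaks increasing integer thresholds starting at 2; bin i is
#'   [breaks[i], breaks[i+1]) and the last bin is [last break, Inf), so the
#'   bins cover [2, Inf).
#' @return data.frame with columns \code{bin}, \code{n_distinct_tags},
#'   \code{n_tag_copies}, \code{pct_of_clean_tags}; attribute \code{empty}
#'   is TRUE for an empty library (percentages reported as 0).
#' @export
copyNumberDistribution <- function(lib, breaks = c(2L, 6L, 11L, 21L,
                                                   51L, 101L)) {
  stopifnot(is(lib, "TagLibrary"))
  breaks <- as.integer(sort(unique(breaks)))
  if (breaks[1] != 2L) stop("bins must cover [2, Inf): first break must be 2")
  edges <- c(breaks, Inf)
  labs <- vapply(seq_len(length(edges) - 1L), function(i) {
    if (is.infinite(edges[i + 1])) sprintf(">%d", edges[i] - 1L)
    else sprintf("%d-%d", edges[i], edges[i + 1] - 1L)
  }, character(1))
  cc <- cleanCounts(lib)
  total <- sum(cc)
  bin <- cut(cc, breaks = edges, labels = labs, right = FALSE)
  nTags <- as.integer(table(bin))
  copies <- vapply(levels(bin), function(l) sum(cc[bin == l]), numeric(1))
  pct <- if (total > 0) 100 * copies / total else base::rep(0, length(labs))
  out <- data.frame(bin = labs, n_distinct_tags = nTags,
                    n_tag_copies = as.integer(copies),
                    pct_of_clean_tags = unname(pct),
                    stringsAsFactors = FALSE)
  attr(out, "empty") <- total == 0
  out
}

#' Library saturation analysis
#'
#' Subsamples the clean-tag multiset without replacement at a grid of depth
#' fractions and counts the genes detected (>= 1 clean tag resolving
#' unambiguously to the gene) at each depth.  Subsamples are nested — one
#' permutation of the reads is drawn and prefixes taken — so each curve is
#' monotone by construction; the per-step new-gene rate shows whether the
#' library depth approaches saturation.
#'
#' @param lib a \linkS4class{TagLibrary}.
#' @param index a \linkS4class{VirtualTagIndex}.
#' @param fractions increasing depth fractions in (0, 1]; must include 1.
#' @param seed integer seed for the permutation.
#' @return data.frame with columns \code{fraction}, \code{n_reads},
#'   \code{genes_detected}, \code{new_genes_per_read}.
#' @export
saturationCurve <- function(lib, index,
                            fractions = seq(0.1, 1, by = 0.1), seed = 1L) {
  stopifnot(is(lib, "TagLibrary"), is(index, "VirtualTagIndex"))
  fractions <- sort(fractions)
  if (any(fractions <= 0) || any(fractions > 1)) {
    stop("fractions must lie in (0, 1]")
  }
  if (abs(fractions[length(fractions)] - 1) > 1e-12) {
    stop("fractions must include 1.0 (the full library)")
  }
  cc <- cleanCounts(lib)
  total <- sum(cc)
  res <- resolveTags(names(cc), index)
  geneOfTag <- ifelse(res$status == "gene", res$gene_id, NA_character_)
  reads <- base::rep(geneOfTag, cc) # per-read resolved gene (NA if none)
  perm <- withSeed(seed, sample.int(length(reads)))
  reads <- reads[perm]
  # first-occurrence position of each detected gene in the permuted stream
  firstPos <- tapply(seq_along(reads)[!is.na(reads)],
                     reads[!is.na(reads)], min)
  nAt <- pmin(total, ceiling(fractions * total))
  detected <- vapply(nAt, function(n) sum(firstPos <= n), numeric(1))
  newRate <- c(detected[1] / nAt[1],
               diff(detected) / pmax(1, diff(nAt)))
  data.frame(fraction = fractions, n_reads = nAt,
             genes_detected = as.integer(detected),
             new_genes_per_read = newRate)
}
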