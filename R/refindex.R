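#' Build the virtual reference tag library
#'
#' Scans every transcript on the sense strand for CATG sites and extracts all
#' possible CATG + 17 nt tags (one entry per occurrence with at least 17
#' downstream nucleotides, overlapping sites included).  Sites whose 17 nt
#' window contains an ambiguous base are skipped.  Tags found verbatim in
#' more than one gene are flagged ambiguous and are never credited to a
#' single gene at mapping time.
#'
#' @param transcripts named \link[Biostrings]{DNAStringSet} (or named
#'   character vector) of oriented transcript sequences, one per gene.
#' @param antisense logical; also scan the reverse complement.  Off by
#'   default: unigene-style references are oriented transcripts and the
#'   chemistry reads the mRNA 3' end.
#' @return a \linkS4class{VirtualTagIndex}.
#'
#' @examples
#' tx <- Biostrings::DNAStringSet(c(g1 = paste0("AACATG", strrep("A", 17))))
#' idx <- buildTagIndex(tx)
#' tagKeys(idx)
#'
#' @importFrom Biostrings DNAStringSet vmatchPattern reverseComplement
#' @export
buildTagIndex <- function(transcripts, antisense = FALSE) {
  seqs <- asTranscriptChar(transcripts)
  genes <- names(seqs)
  if (antisense) {
    rc <- as.character(reverseComplement(DNAStringSet(seqs)))
    seqs <- paste0(seqs, "N", rc) # N spacer: no spurious spanning sites
    names(seqs) <- genes
  }
  dss <- DNAStringSet(seqs)
  hits <- vmatchPattern(ANCHOR, dss)
  starts <- lapply(hits, function(ir) S4Vectors::start(ir))
  nper <- lengths(starts)
  gene_of <- rep(genes, nper)
  pos <- unlist(starts, use.names = FALSE)
  if (length(pos) == 0L) {
    return(new("VirtualTagIndex", tag2gene = list(),
               sites = data.frame(gene_id = character(0),
                                  offset = integer(0)),
               geneIds = genes))
  }
  widths <- nchar(seqs)[match(gene_of, genes)]
  ok <- pos + TAG_LENGTH - 1L <= widths
  gene_of <- gene_of[ok]
  pos <- pos[ok]
  tags <- substr(unname(seqs[match(gene_of, genes)]), pos, pos + TAG_LENGTH - 1L)
  valid <- !grepl("N", tags, fixed = TRUE)
  gene_of <- gene_of[valid]
  pos <- pos[valid]
  tags <- tags[valid]
  sites <- data.frame(gene_id = gene_of, offset = pos - 1L,
                      stringsAsFactors = FALSE)
  tag2gene <- lapply(split(gene_of, tags), function(g) sort(unique(g)))
  new("VirtualTagIndex", tag2gene = tag2gene, sites = sites,
      geneIds = genes)
}

#' Resolve query tags to genes
#'
#' Applies the perfect-match-first, single-mismatch tag-to-gene policy: a tag
#' matching an index key verbatim is resolved at the perfect level and any
#' 1-mismatch hits are ignored; otherwise all index keys at Hamming distance
#' 1 within the 17 nt variable region are collected (the CATG anchor must
#' match exactly, since the restriction site defines the read).  At the
#' governing level the tag resolves to a gene only if exactly one gene is
#' hit; several genes make it ambiguous ("tags identifying more than one
#' gene are removed"), none at either level leaves it unmapped.
#'
#' @param tags character vector of 21 nt query tags.
#' @param index a \linkS4class{VirtualTagIndex}.
#' @return a \code{data.frame} with one row per query: \code{tag},
#'   \code{status} (\code{"gene"}, \code{"ambiguous"}, \code{"unmapped"}),
#'   \code{gene_id} (NA unless status is \code{"gene"}) and
#'   \code{match_class} (\code{"perfect"}, \code{"mismatch1"}, \code{"none"}).
#' @export
resolveTags <- function(tags, index) {
  stopifnot(is(index, "VirtualTagIndex"))
  if (length(tags) == 0L) {
    return(data.frame(tag = character(0), status = character(0),
                      gene_id = character(0), match_class = character(0),
                      stringsAsFactors = FALSE))
  }
  if (any(nchar(tags) != TAG_LENGTH)) {
    stop(sprintf("query tags must be %d nt long", TAG_LENGTH))
  }
  keys <- names(index@tag2gene)
  status <- base::rep("unmapped", length(tags))
  gene <- base::rep(NA_character_, length(tags))
  mclass <- base::rep("none", length(tags))

  hit <- match(tags, keys)
  perfect <- !is.na(hit)
  if (any(perfect)) {
    gsets <- index@tag2gene[hit[perfect]]
    uniq <- lengths(gsets) == 1L
    status[perfect] <- ifelse(uniq, "gene", "ambiguous")
    gene[perfect][uniq] <- unlist(gsets[uniq], use.names = FALSE)
    mclass[perfect] <- "perfect"
  }

  # 1-mismatch pass for tags with no perfect hit and an intact anchor
  todo <- which(!perfect & startsWith(tags, ANCHOR))
  if (length(todo) > 0L) {
    q <- tags[todo]
    m <- length(q)
    variants <- character(0)
    origin <- integer(0)
    for (p in seq_len(SUFFIX_LENGTH)) {
      ppos <- nchar(ANCHOR) + p
      cur <- substr(q, ppos, ppos)
      pre <- substr(q, 1L, ppos - 1L)
      suf <- substr(q, ppos + 1L, TAG_LENGTH)
      for (b in DNA_BASES) {
        keep <- cur != b
        if (any(keep)) {
          variants <- c(variants, paste0(pre[keep], b, suf[keep]))
          origin <- c(origin, todo[keep])
        }
      }
    }
    vhit <- match(variants, keys)
    found <- !is.na(vhit)
    if (any(found)) {
      gl <- index@tag2gene[vhit[found]]
      per_query <- split(unlist(gl, use.names = FALSE),
                         base::rep(origin[found], lengths(gl)))
      for (nm in names(per_query)) {
        i <- as.integer(nm)
        gs <- unique(per_query[[nm]])
        if (length(gs) == 1L) {
          status[i] <- "gene"; gene[i] <- gs; mclass[i] <- "mismatch1"
        } else {
          status[i] <- "ambiguous"; mclass[i] <- "mismatch1"
        }
      }
    }
  }
  data.frame(tag = tags, status = status, gene_id = gene,
             match_class = mclass, stringsAsFactors = FALSE)
}

#' Write a tag index to TSV
#'
#' Writes the index as a 3-column TSV (tag, semicolon-joined gene ids,
#' ambiguous flag) plus a one-row summary TSV (genes with >= 1 site, total
#' sites, distinct tags, ambiguous tags).
#'
#' @param index a \linkS4class{VirtualTagIndex}.
#' @param path output TSV path; the summary is written next to it with
#'   suffix \code{.summary.tsv}.
#' @return invisibly, the index TSV path.
#' @export
writeTagIndex <- function(index, path) {
  stopifnot(is(index, "VirtualTagIndex"))
  df <- data.frame(
    tag = names(index@tag2gene),
    gene_ids = vapply(index@tag2gene, paste, character(1), collapse = ";"),
    ambiguous = lengths(index@tag2gene) > 1L,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$tag), , drop = FALSE]
  writeTsv(df, path)
  summ <- data.frame(
    genes_total = length(index@geneIds),
    genes_with_site = length(unique(index@sites$gene_id)),
    total_sites = nrow(index@sites),
    distinct_tags = length(index@tag2gene),
    ambiguous_tags = sum(lengths(index@tag2gene) > 1L)
  )
  writeTsv(summ, sub("\\.tsv$", ".summary.tsv", path))
  invisible(path)
}
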