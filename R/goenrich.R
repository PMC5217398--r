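# Hypergeometric GO-term over-representation analysis.

#' GO-term enrichment of a DEG set by the hypergeometric test
#'
#' For each term, tests whether the term's genes are over-represented in the
#' DEG set relative to the background universe (by default the full
#' tag-mapped reference gene set): with N universe genes, M of them carrying
#' the term, and a DEG set of n genes of which m carry the term, the
#' p-value is the upper hypergeometric tail
#' \deqn{p = \sum_{i=m}^{\min(M,n)} \frac{{M \choose i}{N-M \choose n-i}}
#'   {{N \choose n}}.}
#' Benjamini-Hochberg adjustment is applied across the tested terms (within
#' each namespace when one is supplied); a term is flagged enriched under
#' the dual threshold p < \code{pThreshold} and fdr < \code{fdrThreshold}.
#'
#' @param degSet character vector of DEG gene ids (subset of
#'   \code{universe}).
#' @param annotation data.frame with columns \code{gene} and \code{term}
#'   (one row per gene-term pair); annotations outside the universe are
#'   dropped.
#' @param universe character vector, the background gene set.
#' @param pThreshold,fdrThreshold dual enrichment thresholds (defaults 0.01
#'   and 0.05).
#' @param termNamespace optional named character vector term -> namespace;
#'   BH is then applied within each namespace.
#' @return data.frame sorted by p-value with columns \code{term},
#'   \code{n_universe}, \code{n_term}, \code{n_set}, \code{n_hit},
#'   \code{p_value}, \code{fdr}, \code{enriched} (and \code{namespace} if
#'   supplied).
#'
#' @importFrom stats phyper p.adjust
#' @export
goEnrich <- function(degSet, annotation, universe,
                     pThreshold = 0.01, fdrThreshold = 0.05,
                     termNamespace = NULL) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  degSet <- unique(degSet)
  if (!all(degSet %in% universe)) {
    stop("DEG set must be a subset of the universe: ",
         paste(utils::head(setdiff(degSet, universe), 3), collapse = ", "))
  }
  stopifnot(all(c("gene", "term") %in% names(annotation)))
  ann <- unique(annotation[annotation$gene %in% universe,
                           c("gene", "term")])
  N <- length(universe)
  n <- length(degSet)
  termGenes <- split(ann$gene, ann$term)
  M <- lengths(termGenes)
  m <- vapply(termGenes, function(g) sum(g %in% degSet), integer(1))
  p <- phyper(m - 1L, M, N - M, n, lower.tail = FALSE)
  out <- data.frame(
    term = names(termGenes),
    n_universe = N, n_term = as.integer(M), n_set = n,
    n_hit = m, p_value = unname(p),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(termNamespace)) {
    out$namespace <- unname(termNamespace[out$term])
    out$fdr <- stats::ave(out$p_value, out$namespace,
                          FUN = function(z) p.adjust(z, "BH"))
  } else {
    out$fdr <- p.adjust(out$p_value, "BH")
  }
  out$enriched <- out$p_value < pThreshold & out$fdr < fdrThreshold
  out[order(out$p_value, out$term), , drop = FALSE]
}

#' Close annotations over a term parent table
#'
#' Optional pre-processing for annotation sets that are not closed over the
#' GO graph: propagates every gene-term annotation to all ancestor terms by
#' transitive closure of a child -> parent table.
#'
#' @param annotation data.frame with columns \code{gene}, \code{term}.
#' @param parents data.frame with columns \code{term}, \code{parent}.
#' @return annotation data.frame including all ancestor annotations
#'   (deduplicated).
#' @export
propagateAnnotations <- function(annotation, parents) {
  stopifnot(all(c("gene", "term") %in% names(annotation)),
            all(c("term", "parent") %in% names(parents)))
  parentOf <- split(parents$parent, parents$term)
  cur <- unique(annotation[, c("gene", "term")])
  all <- cur
  repeat {
    up <- cur[cur$term %in% names(parentOf), , drop = FALSE]
    if (nrow(up) == 0L) break
    ex <- lengths(parentOf[up$term])
    nxt <- data.frame(gene = base::rep(up$gene, ex),
                      term = unlist(parentOf[up$term], use.names = FALSE),
                      stringsAsFactors = FALSE)
    nxt <- unique(nxt)
    new <- nxt[!paste(nxt$gene, nxt$term) %in% paste(all$gene, all$term), ,
               drop = FALSE]
    if (nrow(new) == 0L) break
    all <- rbind(all, new)
    cur <- new
  }
  all[order(all$gene, all$term), , drop = FALSE]
}

#' Read a 2-column gene-to-GO annotation TSV
#'
#' @param path TSV with columns gene and term (header optional).
#' @return data.frame with columns \code{gene}, \code{term}.
#' @export
readAnnotation <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("^gene\\b", first)
  utils::read.delim(path, header = hasHeader,
                    col.names = c("gene", "term"),
                    stringsAsFactors = FALSE)
}
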