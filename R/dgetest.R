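# TPM normalization, the Audic-Claverie exact test, differential-expression
# calling, time-point set decomposition, and the qRT-PCR 2^-ddCt helper.

#' Tags-per-million normalization
#'
#' TPM here is the classic DGE library-size normalization — tag count per
#' million clean tags of its library — not the modern length-aware
#' transcript metric.
#'
#' @param count tag count(s), non-negative.
#' @param cleanTotal total clean tags of the library (>= 1).
#' @return \code{count / cleanTotal * 1e6}.
#' @examples
#' tpmNormalize(100, 1e6) # 100
#' @export
tpmNormalize <- function(count, cleanTotal) {
  stopifnot(all(count >= 0), all(cleanTotal >= 1))
  count / cleanTotal * 1e6
}

# log p(k | x) for the Audic-Claverie conditional distribution of the count
# k in library 2 given count x in library 1, with totals n1 and n2:
#   p(k|x) = (n2/n1)^k (x+k)! / (x! k! (1 + n2/n1)^(x+k+1))
# evaluated in log space with lgamma so overflow is impossible.
.acLogProb <- function(k, x, n1, n2) {
  lr <- log(n2) - log(n1)
  lden <- log(n1 + n2) - log(n1) # log(1 + n2/n1)
  k * lr + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
    (x + k + 1) * lden
}

# Upper tail sum_{k >= y} p(k|x): summed outward in chunks until the
# increment is below machine precision (the distribution is
# negative-binomial-shaped with finite mean (x+1) n2/n1, so the sum
# converges geometrically past the mode).
.acUpperTail <- function(x, y, n1, n2) {
  total <- 0
  k0 <- y
  chunk <- 512L
  mean_k <- (x + 1) * n2 / n1
  repeat {
    ks <- seq.int(k0, k0 + chunk - 1L)
    inc <- sum(exp(.acLogProb(ks, x, n1, n2)))
    total <- total + inc
    k0 <- k0 + chunk
    if (k0 > mean_k && (inc <= total * 1e-15 || inc == 0)) break
  }
  min(total, 1)
}

# One-sided tail: the smaller of the excess tail sum_{k >= y} p(k|x) and the
# deficit tail, the latter computed as the excess tail of the exchanged pair
# sum_{k >= x} p(k|y; n2, n1).  By the negative-binomial / binomial tail
# duality both equal the matching tails of y | x + y ~ Binom(x+y,
# n2/(n1+n2)), so the construction is exactly symmetric under exchanging
# the two libraries.  The observed point is always included in its tail.
.acOneSided <- function(x, y, n1, n2) {
  min(.acUpperTail(x, y, n1, n2), .acUpperTail(y, x, n2, n1))
}

#' Audic-Claverie two-sided p-value for a tag-count difference
#'
#' Exact test for a difference in a tag's count between two libraries of
#' known clean-tag totals, based on the conditional distribution of one
#' count given the other (equivalently, of y given x + y, a binomial with
#' success probability n2/(n1+n2)).  The two-sided p-value is
#' min(1, 2 x smaller tail), with the observed count included in its tail;
#' the deficit-side tail is computed as the excess tail of the exchanged
#' pair, which by the exact tail duality of the conditional distribution
#' makes the p-value invariant under exchanging the two libraries.
#' All arithmetic is in log space, so large counts and totals are safe.
#'
#' @param x,y tag counts in libraries 1 and 2 (non-negative integers;
#'   vectorized).
#' @param n1,n2 total clean tags of libraries 1 and 2 (>= 1).
#' @return two-sided p-value(s) in [0, 1].
#'
#' @examples
#' audicClaveriePValue(0, 0, 1e5, 1e5) # 1: no evidence from zero counts
#' audicClaveriePValue(0, 64, 1e5, 1e5) # vanishingly small
#' @export
audicClaveriePValue <- function(x, y, n1, n2) {
  stopifnot(all(x >= 0), all(y >= 0), all(n1 >= 1), all(n2 >= 1))
  n <- max(length(x), length(y), length(n1), length(n2))
  x <- base::rep(as.numeric(x), length.out = n)
  y <- base::rep(as.numeric(y), length.out = n)
  n1 <- base::rep(as.numeric(n1), length.out = n)
  n2 <- base::rep(as.numeric(n2), length.out = n)
  p <- vapply(seq_len(n), function(i) {
    min(1, 2 * .acOneSided(x[i], y[i], n1[i], n2[i]))
  }, numeric(1))
  pmin(pmax(p, 0), 1)
}

#' Call differential expression between two libraries
#'
#' For every gene with a nonzero count in at least one of the two libraries,
#' computes TPMs, the log2 ratio (treatment over reference), the two-sided
#' Audic-Claverie p-value on the raw counts, and the Benjamini-Hochberg
#' adjusted value over exactly that tested family; genes at zero in both
#' libraries are excluded from testing and from the adjustment family so
#' untestable genes do not dilute the FDR.  A gene is called up when
#' fdr < \code{fdrThreshold} and log2 ratio >= \code{lfcThreshold}, down
#' symmetrically, otherwise ns.
#'
#' The log2 ratio is computed on TPM; when one side is zero, that side only
#' is floored at \code{zeroFloor} tags (default 0.5) to keep the ratio
#' finite — the p-value always uses the raw integer counts.
#'
#' @param tce a \linkS4class{TagCountExperiment}.
#' @param a,b column names of the reference (a) and treatment (b) libraries.
#' @param fdrThreshold FDR threshold for a call (default 0.001).
#' @param lfcThreshold |log2 ratio| threshold for a call (default 1).
#' @param zeroFloor pseudo-count (in tags) applied to a zero side when
#'   computing the ratio only.
#' @return a \link[S4Vectors]{DataFrame} with one row per gene (all genes,
#'   untested ones carry NA p-values and call "ns"): columns \code{x},
#'   \code{y}, \code{tpm_a}, \code{tpm_b}, \code{log2_ratio},
#'   \code{p_value}, \code{fdr}, \code{call}.  Metadata records the
#'   contrast and totals.
#'
#' @importFrom stats p.adjust
#' @export
callDE <- function(tce, a, b, fdrThreshold = 0.001, lfcThreshold = 1,
                   zeroFloor = 0.5) {
  stopifnot(is(tce, "TagCountExperiment"))
  missing <- setdiff(c(a, b), colnames(tce))
  if (length(missing) > 0L) {
    stop("library not present in count matrix: ",
         paste(missing, collapse = ", "))
  }
  counts <- SummarizedExperiment::assay(tce, "counts")
  totals <- cleanTotals(tce)
  n1 <- totals[[a]]
  n2 <- totals[[b]]
  if (n1 < 1 || n2 < 1) stop("clean-tag totals must be >= 1")
  x <- counts[, a]
  y <- counts[, b]

  tpm_a <- tpmNormalize(x, n1)
  tpm_b <- tpmNormalize(y, n2)
  xr <- ifelse(x == 0, zeroFloor, x)
  yr <- ifelse(y == 0, zeroFloor, y)
  log2_ratio <- log2((yr / n2) / (xr / n1))

  tested <- x + y > 0
  p <- base::rep(NA_real_, length(x))
  p[tested] <- audicClaveriePValue(x[tested], y[tested], n1, n2)
  fdr <- base::rep(NA_real_, length(x))
  fdr[tested] <- p.adjust(p[tested], method = "BH")

  call <- base::rep("ns", length(x))
  call[tested & fdr < fdrThreshold & log2_ratio >= lfcThreshold] <- "up"
  call[tested & fdr < fdrThreshold & log2_ratio <= -lfcThreshold] <- "down"

  out <- S4Vectors::DataFrame(
    x = x, y = y, tpm_a = tpm_a, tpm_b = tpm_b,
    log2_ratio = log2_ratio, p_value = p, fdr = fdr, call = call,
    row.names = rownames(counts)
  )
  S4Vectors::metadata(out) <- list(a = a, b = b, n1 = n1, n2 = n2,
                                   fdrThreshold = fdrThreshold,
                                   lfcThreshold = lfcThreshold,
                                   zeroFloor = zeroFloor)
  out
}

#' Decompose differential calls across two time points
#'
#' Partitions the genes differentially expressed at either of two stress
#' durations into the eight disjoint classes of the standard two-time-point
#' Venn layout: common direction, direction reversal, and each
#' time-point-only class.
#'
#' @param deT1,deT2 [callDE()] results over the same gene universe.
#' @return named list of gene-id character vectors: \code{common_up},
#'   \code{common_down}, \code{up_then_down}, \code{down_then_up},
#'   \code{only_t1_up}, \code{only_t1_down}, \code{only_t2_up},
#'   \code{only_t2_down}.  The sets are pairwise disjoint and their union
#'   is every gene DE at either time point.
#' @export
vennDecompose <- function(deT1, deT2) {
  if (!setequal(rownames(deT1), rownames(deT2))) {
    stop("the two call tables must share one gene universe")
  }
  c1 <- structure(deT1$call, names = rownames(deT1))
  c2 <- structure(deT2$call, names = rownames(deT2))[names(c1)]
  g <- names(c1)
  list(
    common_up     = g[c1 == "up" & c2 == "up"],
    common_down   = g[c1 == "down" & c2 == "down"],
    up_then_down  = g[c1 == "up" & c2 == "down"],
    down_then_up  = g[c1 == "down" & c2 == "up"],
    only_t1_up    = g[c1 == "up" & c2 == "ns"],
    only_t1_down  = g[c1 == "down" & c2 == "ns"],
    only_t2_up    = g[c1 == "ns" & c2 == "up"],
    only_t2_down  = g[c1 == "ns" & c2 == "down"]
  )
}

#' Venn decomposition set sizes
#' @param venn a [vennDecompose()] result.
#' @return named integer vector of set sizes.
#' @export
vennCounts <- function(venn) {
  vapply(venn, length, integer(1))
}

#' Relative expression by the 2^-ddCt method
#'
#' Standard qRT-PCR relative quantification: the target gene's Ct is
#' normalized to a reference gene within each sample (dCt), the treated
#' sample's dCt is referred to the calibrator's (ddCt), and the fold change
#' is 2^-ddCt.
#'
#' @param ctTargetSample,ctRefSample Ct of target and reference gene in the
#'   sample of interest.
#' @param ctTargetCalibrator,ctRefCalibrator Ct of target and reference gene
#'   in the calibrator sample.
#' @return fold change(s), \code{2^-ddCt}.
#' @examples
#' ddctFoldChange(20, 18, 22, 19) # ddCt = 2 - 3 = -1 -> fold change 2
#' @export
ddctFoldChange <- function(ctTargetSample, ctRefSample,
                           ctTargetCalibrator, ctRefCalibrator) {
  stopifnot(all(is.finite(c(ctTargetSample, ctRefSample,
                            ctTargetCalibrator, ctRefCalibrator))))
  ddct <- (ctTargetSample - ctRefSample) -
    (ctTargetCalibrator - ctRefCalibrator)
  2^(-ddct)
}
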