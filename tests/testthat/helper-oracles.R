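# Independent oracles and fixture builders used across the suite.  Each
# oracle is a deliberately naive reimplementation of the property it
# checks, kept free of the package's own code paths.

# --- naive window-scan tag extraction -------------------------------------
# Character-by-character scan: every CATG occurrence with >= 17 downstream
# nt and no N in the 21 nt window yields (tag, gene, offset).
naiveScanIndex <- function(seqs) {
  stopifnot(!is.null(names(seqs)))
  rows <- list()
  for (g in names(seqs)) {
    s <- seqs[[g]]
    w <- nchar(s)
    i <- 1L
    while (i + 3L <= w) {
      if (substr(s, i, i + 3L) == "CATG" && i + 20L <= w) {
        tag <- substr(s, i, i + 20L)
        if (!grepl("N", tag, fixed = TRUE)) {
          rows[[length(rows) + 1L]] <- list(tag = tag, gene = g,
                                            offset = i - 1L)
        }
      }
      i <- i + 1L
    }
  }
  if (length(rows) == 0L) {
    return(list(sites = data.frame(tag = character(0), gene = character(0),
                                   offset = integer(0)),
                tag2gene = list()))
  }
  df <- do.call(rbind, lapply(rows, as.data.frame))
  list(sites = df,
       tag2gene = lapply(split(df$gene, df$tag),
                         function(g) sort(unique(g))))
}

# --- brute-force Hamming resolution ---------------------------------------
hammingDist <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

bruteResolve <- function(tag, tag2gene) {
  if (substr(tag, 1, 4) != "CATG") {
    return(list(status = "unmapped", gene = NA_character_))
  }
  keys <- names(tag2gene)
  d <- vapply(keys, hammingDist, numeric(1), a = tag)
  level <- if (any(d == 0)) 0 else if (any(d == 1)) 1 else NA
  if (is.na(level)) return(list(status = "unmapped", gene = NA_character_))
  genes <- sort(unique(unlist(tag2gene[keys[d == level]])))
  if (length(genes) == 1L) list(status = "gene", gene = genes)
  else list(status = "ambiguous", gene = NA_character_)
}

# --- Audic-Claverie via the conditional-binomial form ---------------------
# p(k|x) = C(x+k, k) q^k (1-q)^(x+1), q = n2/(n1+n2), summed term by term.
# One-sided tail = smaller of the excess tail sum_{k>=y} p(k|x) and the
# excess tail of the exchanged pair (the deficit tail, by tail duality).
acpTail <- function(x, y, n1, n2) {
  q <- n2 / (n1 + n2)
  kmax <- max(y, ceiling((x + 1) * n2 / n1)) + 4000L
  ks <- y:kmax
  min(1, sum(exp(lchoose(x + ks, ks) + ks * log(q) +
                   (x + 1) * log1p(-q))))
}
acpOracle <- function(x, y, n1, n2) {
  one <- min(acpTail(x, y, n1, n2), acpTail(y, x, n2, n1))
  min(1, 2 * one)
}

# --- hypergeometric upper tail by exhaustive subset enumeration -----------
# Universe 1..N, term genes 1..M; enumerates every n-subset and counts
# those containing >= m term genes.  Feasible for choose(N, n) <~ 2e5.
hyperEnumOracle <- function(N, M, n, m) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= M)
  mean(hits >= m)
}

# exact integer tails (numerators over the common denominator choose(N, n))
hyperIntUpper <- function(N, M, n, m) {
  i <- m:min(M, n)
  sum(choose(M, i) * choose(N - M, n - i))
}
hyperIntLower <- function(N, M, n, m) {
  if (m < 0) return(0)
  i <- 0:m
  sum(choose(M, i) * choose(N - M, n - i))
}

# --- per-gene Venn case analysis ------------------------------------------
vennOracle <- function(call1, call2) {
  stopifnot(identical(names(call1), names(call2)))
  out <- list(common_up = character(0), common_down = character(0),
              up_then_down = character(0), down_then_up = character(0),
              only_t1_up = character(0), only_t1_down = character(0),
              only_t2_up = character(0), only_t2_down = character(0))
  for (g in names(call1)) {
    a <- call1[[g]]; b <- call2[[g]]
    key <- if (a == "up" && b == "up") "common_up"
      else if (a == "down" && b == "down") "common_down"
      else if (a == "up" && b == "down") "up_then_down"
      else if (a == "down" && b == "up") "down_then_up"
      else if (a == "up") "only_t1_up"
      else if (a == "down") "only_t1_down"
      else if (b == "up") "only_t2_up"
      else if (b == "down") "only_t2_down"
      else NA_character_
    if (!is.na(key)) out[[key]] <- c(out[[key]], g)
  }
  out
}

# --- fixture builders -----------------------------------------------------
# minimal count container for two libraries
makeCountTce <- function(cA, cB, n1, n2, genes = names(cA)) {
  m <- matrix(as.integer(c(cA, cB)), ncol = 2,
              dimnames = list(genes, c("A", "B")))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(cleanTotal = c(n1, n2),
                                   row.names = c("A", "B")))
  new("TagCountExperiment", se)
}

# random 21 nt tags with a CATG anchor
randomTags <- function(n) {
  vapply(seq_len(n), function(i) {
    paste0("CATG", paste(sample(c("A", "C", "G", "T"), 17, replace = TRUE),
                         collapse = ""))
  }, character(1))
}
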