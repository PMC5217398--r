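# Synthetic transcriptomes, expression scenarios and noisy tag libraries
# with ground-truth manifests.

# Default 3' adaptor used by the simulator and the cleaning demo: the public
# Illumina small-RNA 3' adaptor sequence.
DEFAULT_ADAPTOR <- "TCGTATGCCGTCTTCTGCTTG"

#' Generate a synthetic transcriptome
#'
#' Draws random transcript sequences and guarantees that every gene carries
#' at least one CATG site with at least 17 nt downstream, i.e. at least one
#' extractable 21 nt tag: sequences that lack a valid site by chance get a
#' CATG planted at a random valid position.  Deterministic for a fixed seed.
#'
#' @param nGenes number of genes (>= 1).
#' @param lengthRange integer length-2 vector, transcript length range in nt;
#'   the minimum must be >= 25 so a 21 nt tag fits downstream of a CATG.
#' @param seed integer seed.
#' @return a named \link[Biostrings]{DNAStringSet}; names are zero-padded
#'   gene identifiers (\code{g0001}, ...).
#'
#' @examples
#' tx <- generateTranscriptome(5, c(100, 200), seed = 1)
#' width(tx)
#'
#' @importFrom Biostrings DNAStringSet width
#' @export
generateTranscriptome <- function(nGenes, lengthRange = c(200L, 1200L),
                                  seed = 1L) {
  stopifnot(nGenes >= 1, length(lengthRange) == 2L)
  lengthRange <- as.integer(sort(lengthRange))
  if (lengthRange[1] < 25L) {
    stop("minimum transcript length must be >= 25 nt (cannot host a 21 bp tag)")
  }
  withSeed(seed, {
    lens <- sample(seq(lengthRange[1], lengthRange[2]), nGenes, replace = TRUE)
    seqs <- randomDNA(lens)
    # plant a valid CATG site where none occurred by chance
    for (i in seq_len(nGenes)) {
      if (length(validAnchorStarts(seqs[i])) == 0L) {
        at <- sample(seq_len(lens[i] - TAG_LENGTH + 1L), 1L)
        substr(seqs[i], at, at + 3L) <- ANCHOR
      }
    }
    names(seqs) <- sprintf("g%0*d", max(4L, nchar(nGenes)), seq_len(nGenes))
    DNAStringSet(seqs)
  })
}

# 1-based start positions of CATG occurrences with >= 17 valid downstream nt.
validAnchorStarts <- function(seq) {
  w <- nchar(seq)
  pos <- integer(0)
  from <- 1L
  repeat {
    hit <- regexpr(ANCHOR, substr(seq, from, w), fixed = TRUE)
    if (hit < 0L) break
    p <- from + as.integer(hit) - 1L
    pos <- c(pos, p)
    from <- p + 1L
  }
  pos <- pos[pos + TAG_LENGTH - 1L <= w]
  pos[!grepl("N", substr(base::rep(seq, length(pos)), pos,
                         pos + TAG_LENGTH - 1L), fixed = TRUE)]
}

# 3'-most extractable tag per gene (NlaIII chemistry: polyT bead capture of
# the 3' fragment means the sequenced tag is the one at the 3'-most site).
threePrimeTags <- function(seqs) {
  vapply(seqs, function(s) {
    pos <- validAnchorStarts(s)
    if (length(pos) == 0L) return(NA_character_)
    p <- max(pos)
    substr(s, p, p + TAG_LENGTH - 1L)
  }, character(1))
}

#' Construct a noise profile
#'
#' @param perBaseErrorRate substitution probability per nucleotide of an
#'   informative read, in [0, 0.25].
#' @param adaptorFraction,emptyFraction,lengthAnomalyFraction,ambiguousBaseFraction
#'   fractions of reads emitted as the four junk classes (tag + 3' adaptor;
#'   adaptor only; length != 21 nt; containing N).  Must jointly sum
#'   to <= 1.
#' @param seed integer seed driving one simulated library.
#' @return a \linkS4class{NoiseProfile}.
#' @export
noiseProfile <- function(perBaseErrorRate = 0.005,
                         adaptorFraction = 0.02,
                         emptyFraction = 0.01,
                         lengthAnomalyFraction = 0.01,
                         ambiguousBaseFraction = 0.01,
                         seed = 1L) {
  new("NoiseProfile",
      perBaseErrorRate = perBaseErrorRate,
      adaptorFraction = adaptorFraction,
      emptyFraction = emptyFraction,
      lengthAnomalyFraction = lengthAnomalyFraction,
      ambiguousBaseFraction = ambiguousBaseFraction,
      seed = as.integer(seed))
}

#' Noise-free profile shorthand
#' @param seed integer seed.
#' @return a \linkS4class{NoiseProfile} with all rates zero.
#' @export
noiselessProfile <- function(seed = 1L) {
  noiseProfile(0, 0, 0, 0, 0, seed = seed)
}

#' Plant a differential-expression scenario
#'
#' Draws per-gene baseline relative abundances from a gamma distribution
#' (shape 2, heavier-than-uniform spread typical of transcript abundance)
#' and plants a fraction of genes as differentially expressed with the
#' stated |log2 fold change|, split evenly between up- and down-regulated.
#' Condition B abundances are baseline times 2^log2fc, renormalized to a
#' probability vector.
#'
#' @param transcripts transcript set (named DNAStringSet or character); only
#'   the gene names are used.
#' @param fracDE fraction of genes planted as DE, in [0, 0.5].
#' @param log2fcMagnitude planted |log2 fold change| (> 0).
#' @param seed integer seed.
#' @param abundanceShape gamma shape of the baseline abundance draw.
#' @return an \linkS4class{ExpressionScenario}.
#'
#' @importFrom stats rgamma
#' @export
makeDEScenario <- function(transcripts, fracDE = 0.1, log2fcMagnitude = 2,
                           seed = 1L, abundanceShape = 2) {
  genes <- if (is.character(transcripts) && is.null(names(transcripts))) {
    transcripts
  } else {
    names(asTranscriptChar(transcripts))
  }
  n <- length(genes)
  if (n == 0L) stop("empty transcript set")
  stopifnot(fracDE >= 0, fracDE <= 0.5, log2fcMagnitude > 0)
  withSeed(seed, {
    ab <- rgamma(n, shape = abundanceShape)
    ab <- ab / sum(ab)
    lfc <- numeric(n)
    labels <- base::rep("null", n)
    nDE <- round(fracDE * n)
    if (nDE > 0L) {
      de <- sample(n, nDE)
      nUp <- ceiling(nDE / 2)
      up <- de[seq_len(nUp)]
      down <- de[-seq_len(nUp)]
      lfc[up] <- log2fcMagnitude
      lfc[down] <- -log2fcMagnitude
      labels[up] <- "up"
      labels[down] <- "down"
    }
    abB <- ab * 2^lfc
    abB <- abB / sum(abB)
    new("ExpressionScenario", geneIds = genes, baselineAbundance = ab,
        conditionLog2fc = lfc, deLabels = labels, abundanceB = abB,
        seed = as.integer(seed))
  })
}

#' Simulate one raw tag library with a ground-truth manifest
#'
#' Each informative read is the 3'-most CATG + 17 nt tag of a gene drawn
#' multinomially by abundance, passed through a per-base substitution error
#' channel.  Junk reads (adaptor-contaminated, adaptor-only, wrong-length,
#' N-containing) are injected at the profile's fractions; the classes are
#' mutually exclusive per read, assigned in the priority order
#' adaptor > empty > length > ambiguous-base.  An optional leaky-site rate
#' emits a non-3'-most tag of the drawn gene, creating realistic multi-site
#' cases.  The manifest records every read's class and true origin.
#'
#' @param transcripts named DNAStringSet or character vector.
#' @param abundance per-gene relative abundance, aligned with
#'   \code{transcripts} (same length, or named by gene id).
#' @param depth number of reads to emit (>= 1).
#' @param noise a \linkS4class{NoiseProfile}; its seed drives the library.
#' @param adaptor 3' adaptor sequence used to build adaptor/empty reads.
#' @param leakySiteRate probability that an informative read of a multi-site
#'   gene comes from a random non-3'-most site.
#' @return a list with elements \code{reads} (character vector of raw reads,
#'   length \code{depth}) and \code{manifest}, itself a list with
#'   \code{reads} (per-read data.frame: class, gene_id, site_offset,
#'   true_tag), \code{geneCounts} (named true informative counts per gene),
#'   \code{nInformative}, \code{nJunk}, \code{depth} and \code{seed}.
#'
#' @importFrom stats rbinom runif
#' @export
simulateTagLibrary <- function(transcripts, abundance, depth, noise,
                               adaptor = DEFAULT_ADAPTOR,
                               leakySiteRate = 0) {
  seqs <- asTranscriptChar(transcripts)
  genes <- names(seqs)
  if (!is.null(names(abundance))) {
    stopifnot(setequal(names(abundance), genes))
    abundance <- abundance[genes]
  }
  stopifnot(length(abundance) == length(genes), depth >= 1,
            is(noise, "NoiseProfile"))
  abundance <- abundance / sum(abundance)
  tag3p <- threePrimeTags(seqs)
  if (any(is.na(tag3p) & abundance > 0)) {
    bad <- genes[is.na(tag3p) & abundance > 0][1]
    stop("gene with positive abundance but no valid CATG site: ", bad)
  }
  sitesByGene <- lapply(seqs, validAnchorStarts)

  withSeed(noise@seed, {
    depth <- as.integer(depth)
    u <- runif(depth)
    cuts <- cumsum(c(noise@adaptorFraction, noise@emptyFraction,
                     noise@lengthAnomalyFraction,
                     noise@ambiguousBaseFraction))
    cls <- base::rep("informative", depth)
    cls[u < cuts[4]] <- "ambiguous_base"
    cls[u < cuts[3]] <- "length"
    cls[u < cuts[2]] <- "empty"
    cls[u < cuts[1]] <- "adaptor"

    reads <- character(depth)
    gene_id <- base::rep(NA_character_, depth)
    site_offset <- base::rep(NA_integer_, depth)
    true_tag <- base::rep(NA_character_, depth)

    # informative reads: gene drawn by abundance, 3'-most (or leaky) tag
    inf <- which(cls == "informative")
    if (length(inf) > 0L) {
      gi <- sample.int(length(genes), length(inf), replace = TRUE,
                       prob = abundance)
      gene_id[inf] <- genes[gi]
      pos <- vapply(gi, function(g) max(sitesByGene[[g]]), integer(1))
      if (leakySiteRate > 0) {
        leak <- runif(length(inf)) < leakySiteRate
        multi <- vapply(gi, function(g) length(sitesByGene[[g]]) > 1L,
                        logical(1))
        for (j in which(leak & multi)) {
          s <- sitesByGene[[gi[j]]]
          pos[j] <- s[sample.int(length(s) - 1L, 1L)] # any non-3'-most site
        }
      }
      site_offset[inf] <- pos - 1L
      tg <- substr(unname(seqs[gi]), pos, pos + TAG_LENGTH - 1L)
      true_tag[inf] <- tg
      reads[inf] <- sequencingErrors(tg, noise@perBaseErrorRate)
    }

    # junk reads, one deterministic construction per class
    adK <- substr(adaptor, 1L, min(8L, nchar(adaptor)))
    ad <- which(cls == "adaptor")
    if (length(ad) > 0L) {
      # tag prefix followed by the adaptor: adaptor k-mer sits at pos > 1
      src <- junkSourceTags(tag3p, abundance, length(ad))
      reads[ad] <- paste0(substr(src, 1L, TAG_LENGTH - nchar(adK)), adK)
    }
    em <- which(cls == "empty")
    if (length(em) > 0L) {
      filler <- strrep(adaptor, ceiling(TAG_LENGTH / nchar(adaptor)))
      reads[em] <- substr(filler, 1L, TAG_LENGTH)
    }
    ln <- which(cls == "length")
    if (length(ln) > 0L) {
      src <- junkSourceTags(tag3p, abundance, length(ln))
      shorter <- runif(length(ln)) < 0.5
      longer <- paste0(src, sample(DNA_BASES, length(ln), replace = TRUE))
      reads[ln] <- ifelse(shorter, substr(src, 1L, TAG_LENGTH - 1L), longer)
    }
    am <- which(cls == "ambiguous_base")
    if (length(am) > 0L) {
      src <- junkSourceTags(tag3p, abundance, length(am))
      at <- sample.int(TAG_LENGTH, length(am), replace = TRUE)
      substr(src, at, at) <- base::rep("N", length(am))
      reads[am] <- src
    }

    geneCounts <- structure(integer(length(genes)), names = genes)
    tab <- table(gene_id[inf])
    geneCounts[names(tab)] <- as.integer(tab)

    list(
      reads = reads,
      manifest = list(
        reads = data.frame(class = cls, gene_id = gene_id,
                           site_offset = site_offset, true_tag = true_tag,
                           stringsAsFactors = FALSE),
        geneCounts = geneCounts,
        nInformative = length(inf),
        nJunk = depth - length(inf),
        depth = depth,
        seed = noise@seed
      )
    )
  })
}

# draw source tags for junk-read construction by the same abundance law
junkSourceTags <- function(tag3p, abundance, n) {
  pick <- sample.int(length(tag3p), n, replace = TRUE, prob = abundance)
  unname(tag3p[pick])
}

# independent per-base substitution errors on a vector of 21 nt tags
sequencingErrors <- function(tags, rate) {
  if (rate <= 0 || length(tags) == 0L) return(tags)
  nerr <- rbinom(length(tags), TAG_LENGTH, rate)
  for (i in which(nerr > 0L)) {
    at <- sample.int(TAG_LENGTH, nerr[i])
    for (p in at) {
      cur <- substr(tags[i], p, p)
      substr(tags[i], p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
    }
  }
  tags
}

#' Synthesize a gene-to-GO annotation with one planted enriched term
#'
#' Builds an annotation table over a scenario's genes: every gene receives
#' one to three random background terms, and one planted term is attached
#' to most of the truly differential genes plus a small background rate, so
#' that enrichment of a DEG set against the full background has a known
#' best term.
#'
#' @param scenario an \linkS4class{ExpressionScenario}.
#' @param nTerms number of background terms.
#' @param plantedTerm identifier of the planted term.
#' @param plantedCoverage fraction of DE genes annotated with the planted
#'   term.
#' @param backgroundRate fraction of null genes annotated with it.
#' @param seed integer seed.
#' @return data.frame with columns \code{gene}, \code{term}.
#' @export
synthesizeAnnotation <- function(scenario, nTerms = 20L,
                                 plantedTerm = "GO:PLANTED",
                                 plantedCoverage = 0.8,
                                 backgroundRate = 0.05, seed = 1L) {
  stopifnot(is(scenario, "ExpressionScenario"))
  genes <- geneIds(scenario)
  labels <- unname(deLabels(scenario))
  withSeed(seed, {
    terms <- sprintf("GO:%07d", seq_len(nTerms))
    kPer <- sample(1:3, length(genes), replace = TRUE)
    ann <- data.frame(
      gene = base::rep(genes, kPer),
      term = unlist(lapply(kPer, function(k) sample(terms, k))),
      stringsAsFactors = FALSE
    )
    de <- genes[labels != "null"]
    null <- genes[labels == "null"]
    planted <- c(de[runif(length(de)) < plantedCoverage],
                 null[runif(length(null)) < backgroundRate])
    if (length(planted) > 0L) {
      ann <- rbind(ann, data.frame(gene = planted, term = plantedTerm,
                                   stringsAsFactors = FALSE))
    }
    unique(ann[order(ann$gene, ann$term), , drop = FALSE])
  })
}

#' Write simulated outputs to disk
#'
#' Writes transcripts as FASTA, a library's raw reads as FASTA, the per-read
#' manifest as TSV and the scenario parameters as YAML, matching the plain
#' text interchange formats of the rest of the pipeline.
#'
#' @param transcripts named DNAStringSet.
#' @param dir output directory (created if needed).
#' @param libraries named list of \code{simulateTagLibrary()} results.
#' @param scenario optional \linkS4class{ExpressionScenario} to describe.
#' @return invisibly, the directory.
#' @importFrom Biostrings writeXStringSet
#' @export
writeSimulation <- function(transcripts, dir, libraries = list(),
                            scenario = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeXStringSet(DNAStringSet(asTranscriptChar(transcripts)),
                  file.path(dir, "transcripts.fasta"))
  for (id in names(libraries)) {
    lib <- libraries[[id]]
    fa <- file.path(dir, paste0(id, ".reads.fasta"))
    writeLines(paste0(">read", seq_along(lib$reads), "\n", lib$reads), fa)
    writeTsv(lib$manifest$reads, file.path(dir, paste0(id, ".manifest.tsv")))
  }
  if (!is.null(scenario)) {
    yaml::write_yaml(list(
      n_genes = length(scenario@geneIds),
      seed = scenario@seed,
      de_labels = table(scenario@deLabels),
      log2fc_magnitude = max(abs(scenario@conditionLog2fc))
    ), file.path(dir, "scenario.yaml"))
  }
  invisible(dir)
}
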