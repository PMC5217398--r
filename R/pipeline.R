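# End-to-end orchestration: config validation, staged execution, reports.

#' Read and validate a run configuration
#'
#' A run is described by a single YAML file (or equivalent list): a
#' reference (FASTA path or synthetic spec), libraries (reads path,
#' tag/count TSV, or synthetic condition + depth), contrasts, optional Venn
#' pairs and annotation, thresholds, adaptor and one master seed that
#' drives all randomness.
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @return the validated config list (with defaults filled in).
#' @export
readRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- config
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$adaptor <- cfg$adaptor %||% DEFAULT_ADAPTOR
  th <- cfg$thresholds %||% list()
  cfg$thresholds <- list(
    fdr = th$fdr %||% 0.001,
    lfc = th$lfc %||% 1,
    go_p = th$go_p %||% 0.01,
    go_fdr = th$go_fdr %||% 0.05
  )
  if (any(unlist(cfg$thresholds) <= 0)) stop("thresholds must be positive")
  if (is.null(cfg$reference)) stop("config must define a reference")
  if (is.null(cfg$libraries) || length(cfg$libraries) == 0L) {
    stop("config must define at least one library")
  }
  ids <- vapply(cfg$libraries, function(l) as.character(l$id), character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate library ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  }
  for (ct in cfg$contrasts) {
    for (end in c(ct$a, ct$b)) {
      if (!end %in% ids) {
        stop("unknown contrast endpoint: '", end,
             "' (known libraries: ", paste(ids, collapse = ", "), ")")
      }
    }
  }
  labels <- vapply(cfg$contrasts, function(ct) as.character(ct$label),
                   character(1))
  for (vn in cfg$venn) {
    for (end in c(vn$t1, vn$t2)) {
      if (!end %in% labels) {
        stop("unknown venn contrast label: '", end, "'")
      }
    }
  }
  needSynthetic <- any(vapply(cfg$libraries,
                              function(l) is.null(l$reads) && is.null(l$counts),
                              logical(1)))
  if (needSynthetic && is.null(cfg$scenario) &&
      is.null(cfg$reference$synthetic)) {
    stop("synthetic libraries require a synthetic reference and scenario")
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full tag-profiling pipeline
#'
#' Executes, from one validated config: reference loading or simulation,
#' virtual tag index construction, per-library cleaning (with filter
#' accounting), mapping, count-matrix assembly, per-contrast
#' differential-expression calling, optional Venn decomposition across time
#' points, optional GO enrichment, and optional saturation curves.  Every
#' stage writes its artifact as TSV under the output directory together
#' with an md5 manifest; the whole run is deterministic for a fixed seed.
#'
#' @param config path to YAML or config list (see [readRunConfig()]).
#' @param outputDir output directory; overrides \code{config$output_dir}.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory stage results:
#'   \code{index}, \code{libraries}, \code{tce}, \code{de} (per contrast),
#'   \code{venn}, \code{enrichment}, \code{saturation}, \code{outputDir}.
#' @export
runPipeline <- function(config, outputDir = NULL, quiet = FALSE) {
  cfg <- readRunConfig(config)
  outDir <- outputDir %||% cfg$output_dir %||% stop("no output directory")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  logLines <- character(0)
  note <- function(...) {
    msg <- sprintf("[%7.2fs] %s", proc.time()[["elapsed"]] - t0,
                   paste0(...))
    logLines <<- c(logLines, msg)
    if (!quiet) message(msg)
  }

  # stage 1: reference
  if (!is.null(cfg$reference$fasta)) {
    transcripts <- Biostrings::readDNAStringSet(cfg$reference$fasta)
    names(transcripts) <- sub("\\s.*$", "", names(transcripts))
  } else {
    rs <- cfg$reference$synthetic
    transcripts <- generateTranscriptome(
      rs$n_genes,
      c(rs$length_min %||% 200L, rs$length_max %||% 1200L),
      seed = childSeed(cfg$seed, 1L))
    Biostrings::writeXStringSet(transcripts,
                                file.path(outDir, "transcripts.fasta"))
  }
  note("reference: ", length(transcripts), " transcripts")

  # stage 2: virtual tag index
  index <- buildTagIndex(transcripts)
  writeTagIndex(index, file.path(outDir, "tag_index.tsv"))
  note("index: ", nrow(siteTable(index)), " sites, ",
       length(tagKeys(index)), " tags (",
       length(ambiguousTags(index)), " ambiguous)")

  # scenario for synthetic libraries
  scenario <- NULL
  if (!is.null(cfg$scenario)) {
    sc <- cfg$scenario
    scenario <- makeDEScenario(transcripts,
                               fracDE = sc$frac_de %||% 0.1,
                               log2fcMagnitude = sc$log2fc_magnitude %||% 2,
                               seed = childSeed(cfg$seed, 2L))
    truth <- data.frame(gene_id = geneIds(scenario),
                        baseline_abundance = unname(baselineAbundance(scenario)),
                        log2fc = unname(plantedLog2fc(scenario)),
                        label = unname(deLabels(scenario)))
    writeTsv(truth, file.path(outDir, "scenario_truth.tsv"))
  }

  # stage 3: per-library reads -> clean libraries
  libs <- list()
  manifests <- list()
  for (i in seq_along(cfg$libraries)) {
    spec <- cfg$libraries[[i]]
    id <- as.character(spec$id)
    if (!is.null(spec$reads)) {
      reads <- as.character(Biostrings::readDNAStringSet(spec$reads))
      lib <- cleanTags(reads, adaptor = cfg$adaptor, libraryId = id)
    } else if (!is.null(spec$counts)) {
      lib <- readTagCounts(spec$counts, adaptor = cfg$adaptor,
                           libraryId = id)
    } else {
      nz <- cfg$noise %||% list()
      noise <- noiseProfile(
        perBaseErrorRate = nz$per_base_error_rate %||% 0.005,
        adaptorFraction = nz$adaptor_fraction %||% 0.02,
        emptyFraction = nz$empty_fraction %||% 0.01,
        lengthAnomalyFraction = nz$length_anomaly_fraction %||% 0.01,
        ambiguousBaseFraction = nz$ambiguous_base_fraction %||% 0.01,
        seed = childSeed(cfg$seed, 100L + i))
      ab <- conditionAbundance(scenario, spec$condition %||% "A")
      sim <- simulateTagLibrary(transcripts, ab, spec$depth %||% 20000L,
                                noise, adaptor = cfg$adaptor,
                                leakySiteRate = nz$leaky_site_rate %||% 0)
      manifests[[id]] <- sim$manifest
      lib <- cleanTags(sim$reads, adaptor = cfg$adaptor, libraryId = id)
    }
    libs[[id]] <- lib
    writeTsv(data.frame(tag = names(cleanCounts(lib)),
                        count = unname(cleanCounts(lib))),
             file.path(outDir, paste0(id, ".clean.tsv")))
    fs <- filterStats(lib)
    writeTsv(data.frame(class = names(fs), reads = unname(fs)),
             file.path(outDir, paste0(id, ".filter_stats.tsv")))
    note("library ", id, ": ", fs[["raw_total"]], " raw -> ",
         totalCleanTags(lib), " clean")
  }

  # stage 4: mapping + count matrix
  mapped <- lapply(libs, mapLibrary, index = index)
  tce <- assembleCountMatrix(mapped)
  counts <- SummarizedExperiment::assay(tce, "counts")
  writeTsv(data.frame(gene_id = rownames(counts), counts,
                      check.names = FALSE),
           file.path(outDir, "count_matrix.tsv"))
  writeTsv(mappingStatsTable(tce), file.path(outDir, "mapping_stats.tsv"))
  note("count matrix: ", nrow(counts), " genes x ", ncol(counts),
       " libraries")

  # optional saturation curves
  satOut <- list()
  if (isTRUE(cfg$saturation)) {
    for (id in names(libs)) {
      sat <- saturationCurve(libs[[id]], index,
                             seed = childSeed(cfg$seed, 200L))
      satOut[[id]] <- sat
      writeTsv(sat, file.path(outDir, paste0(id, ".saturation.tsv")))
    }
    note("saturation curves written")
  }

  # stage 5: differential expression per contrast
  deOut <- list()
  for (ct in cfg$contrasts) {
    de <- callDE(tce, ct$a, ct$b,
                 fdrThreshold = cfg$thresholds$fdr,
                 lfcThreshold = cfg$thresholds$lfc)
    deOut[[as.character(ct$label)]] <- de
    df <- data.frame(gene = rownames(de), as.data.frame(de))
    writeTsv(df, file.path(outDir, paste0("de_", ct$label, ".tsv")))
    note("contrast ", ct$label, ": ", sum(de$call == "up"), " up, ",
         sum(de$call == "down"), " down")
  }

  # stage 6: Venn decomposition across time points
  vennOut <- list()
  for (vn in cfg$venn) {
    v <- vennDecompose(deOut[[vn$t1]], deOut[[vn$t2]])
    lab <- vn$label %||% paste0(vn$t1, "_vs_", vn$t2)
    vennOut[[lab]] <- v
    writeTsv(data.frame(set = names(v), n_genes = unname(vennCounts(v)),
                        genes = vapply(v, paste, character(1),
                                       collapse = ";")),
             file.path(outDir, paste0("venn_", lab, ".tsv")))
    note("venn ", lab, ": ", sum(vennCounts(v)), " genes DE at either point")
  }

  # stage 7: GO enrichment against the tag-mapped background
  enrichOut <- list()
  if (!is.null(cfg$annotation)) {
    ann <- readAnnotation(cfg$annotation)
    universe <- rownames(counts)[rowSums(counts) > 0]
    for (lab in names(deOut)) {
      de <- deOut[[lab]]
      deg <- rownames(de)[de$call != "ns"]
      deg <- intersect(deg, universe)
      if (length(deg) == 0L) next
      er <- goEnrich(deg, ann, universe,
                     pThreshold = cfg$thresholds$go_p,
                     fdrThreshold = cfg$thresholds$go_fdr)
      enrichOut[[lab]] <- er
      writeTsv(er, file.path(outDir, paste0("enrichment_", lab, ".tsv")))
    }
    note("enrichment done for ", length(enrichOut), " contrasts")
  }

  # manifest + summary
  artifacts <- sort(setdiff(list.files(outDir),
                            c("manifest.tsv", "run.log", "run_summary.txt")))
  manifest <- data.frame(
    file = artifacts,
    md5 = unname(tools::md5sum(file.path(outDir, artifacts)))
  )
  writeTsv(manifest, file.path(outDir, "manifest.tsv"))
  summaryLines <- c(
    "DGE tag-profiling run summary",
    sprintf("seed: %d", cfg$seed),
    sprintf("reference genes: %d", length(transcripts)),
    sprintf("libraries: %s", paste(names(libs), collapse = ", ")),
    vapply(names(deOut), function(lab) {
      de <- deOut[[lab]]
      sprintf("contrast %s: %d up / %d down of %d tested", lab,
              sum(de$call == "up"), sum(de$call == "down"),
              sum(!is.na(de$p_value)))
    }, character(1))
  )
  writeLines(summaryLines, file.path(outDir, "run_summary.txt"))
  writeLines(logLines, file.path(outDir, "run.log"))

  invisible(list(index = index, libraries = libs, manifests = manifests,
                 scenario = scenario, tce = tce, de = deOut,
                 venn = vennOut, enrichment = enrichOut,
                 saturation = satOut, outputDir = outDir))
}

#' Demo run configuration
#'
#' A bundled synthetic scenario sized for a laptop: a 200-gene
#' transcriptome, six libraries in the classic two-genotype,
#' control/short-stress/long-stress layout, four stress contrasts and the
#' two per-genotype Venn decompositions.
#'
#' @param seed master seed.
#' @param outputDir output directory for [runPipeline()].
#' @param depth reads per library.
#' @param nGenes reference size.
#' @return a config list suitable for [runPipeline()].
#' @export
demoRunConfig <- function(seed = 7L, outputDir = tempfile("dgetag_demo_"),
                          depth = 20000L, nGenes = 200L) {
  list(
    seed = as.integer(seed),
    output_dir = outputDir,
    reference = list(synthetic = list(n_genes = nGenes,
                                      length_min = 200L,
                                      length_max = 1200L)),
    scenario = list(frac_de = 0.1, log2fc_magnitude = 2),
    noise = list(per_base_error_rate = 0.005, adaptor_fraction = 0.02,
                 empty_fraction = 0.01, length_anomaly_fraction = 0.01,
                 ambiguous_base_fraction = 0.01),
    libraries = list(
      list(id = "A_CK", condition = "A", depth = depth),
      list(id = "A_0.5h", condition = "B", depth = depth),
      list(id = "A_24h", condition = "B", depth = depth),
      list(id = "B_CK", condition = "A", depth = depth),
      list(id = "B_0.5h", condition = "B", depth = depth),
      list(id = "B_24h", condition = "B", depth = depth)
    ),
    contrasts = list(
      list(a = "A_CK", b = "A_0.5h", label = "A_0.5h_vs_CK"),
      list(a = "A_CK", b = "A_24h", label = "A_24h_vs_CK"),
      list(a = "B_CK", b = "B_0.5h", label = "B_0.5h_vs_CK"),
      list(a = "B_CK", b = "B_24h", label = "B_24h_vs_CK")
    ),
    venn = list(
      list(t1 = "A_0.5h_vs_CK", t2 = "A_24h_vs_CK", label = "A"),
      list(t1 = "B_0.5h_vs_CK", t2 = "B_24h_vs_CK", label = "B")
    ),
    saturation = TRUE
  )
}
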