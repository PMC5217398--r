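test_that("the five cleaning filters account for every read exactly once", {
  adaptor <- "TCGTATGCCGTCTTCTGCTTG"
  kmer <- substr(adaptor, 1, 8)
  t1 <- paste0("CATG", strrep("A", 17))
  t2 <- paste0("CATG", strrep("G", 17))
  reads <- c(
    rep(t1, 5),                                        # valid, copy 5
    t2,                                                # valid, copy 1
    paste0(substr(t1, 1, 13), kmer),                   # adaptor after tag
    paste0("GGGGG", kmer, "TTTTTTTT"),                 # adaptor after tag
    paste0(kmer, substr(adaptor, 9, 21)),              # adaptor only
    paste0("CATG", "N", strrep("A", 16)),              # ambiguous base
    substr(t2, 1, 20),                                 # too short
    paste0(t2, "A")                                    # too long
  )
  lib <- cleanTags(reads, adaptor = adaptor, libraryId = "fix")
  expect_identical(cleanCounts(lib), structure(5L, names = t1))
  expect_equal(totalCleanTags(lib), 5L)
  fs <- filterStats(lib)
  expect_equal(fs[["raw_total"]], 12L)
  expect_equal(fs[["adaptor"]], 2L)
  expect_equal(fs[["empty"]], 1L)
  expect_equal(fs[["low_quality"]], 1L)
  expect_equal(fs[["length"]], 2L)
  expect_equal(fs[["singleton"]], 1L)
})

test_that("identical valid reads aggregate before the copy filter", {
  t1 <- paste0("CATG", strrep("T", 17))
  lib <- cleanTags(rep(t1, 4), libraryId = "x")
  expect_identical(cleanCounts(lib), structure(4L, names = t1))
  expect_equal(totalCleanTags(lib), 4L)

  # empty input stream is an empty library, not an error
  lib0 <- cleanTags(character(0), libraryId = "none")
  expect_equal(totalCleanTags(lib0), 0L)
  expect_equal(filterStats(lib0)[["raw_total"]], 0L)
})

test_that("pre-counted tag/count input passes through the same filters", {
  t1 <- paste0("CATG", strrep("A", 17))
  t2 <- paste0("CATG", strrep("C", 17))
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("tag\tcount", paste0(t1, "\t7"), paste0(t2, "\t1"),
               paste0(strrep("G", 20), "\t3")), tsv)
  lib <- readTagCounts(tsv, libraryId = "tsv")
  expect_identical(cleanCounts(lib), structure(7L, names = t1))
  fs <- filterStats(lib)
  expect_equal(fs[["length"]], 3L)
  expect_equal(fs[["singleton"]], 1L)
  expect_equal(fs[["raw_total"]], 11L)
})

test_that("noise-free synthetic cleaning recovers the manifest counts", {
  tx <- generateTranscriptome(50, c(150, 400), seed = 21)
  sc <- makeDEScenario(tx, fracDE = 0, seed = 22)
  sim <- simulateTagLibrary(tx, baselineAbundance(sc), 20000,
                            noiselessProfile(seed = 23))
  lib <- cleanTags(sim$reads, libraryId = "nf")
  truth <- sim$manifest$geneCounts
  nSingleton <- sum(filterStats(lib)[["singleton"]])
  expect_equal(totalCleanTags(lib),
               sim$manifest$nInformative - nSingleton)
  expect_equal(filterStats(lib)[["adaptor"]] + filterStats(lib)[["empty"]] +
                 filterStats(lib)[["low_quality"]] +
                 filterStats(lib)[["length"]], 0L)
  expect_equal(sum(truth), sim$manifest$nInformative)
})

test_that("copy-number classification reports shares of clean tags", {
  t1 <- paste0("CATG", strrep("A", 17))
  lib <- cleanTags(rep(t1, 10), libraryId = "one")
  cn <- copyNumberDistribution(lib, breaks = c(2L, 6L, 11L))
  expect_identical(cn$bin, c("2-5", "6-10", ">10"))
  expect_equal(cn$pct_of_clean_tags, c(0, 100, 0))
  expect_false(attr(cn, "empty"))

  # hand-enumerated fixture: counts 2, 3, 7, 12 -> copy mass 24
  tags <- c(paste0("CATG", strrep("A", 17)), paste0("CATG", strrep("C", 17)),
            paste0("CATG", strrep("G", 17)), paste0("CATG", strrep("T", 17)))
  reads <- rep(tags, c(2, 3, 7, 12))
  lib2 <- cleanTags(reads, libraryId = "mix")
  cn2 <- copyNumberDistribution(lib2, breaks = c(2L, 6L, 11L))
  expect_equal(cn2$n_distinct_tags, c(2L, 1L, 1L))
  expect_equal(cn2$n_tag_copies, c(5L, 7L, 12L))
  expect_equal(cn2$pct_of_clean_tags, 100 * c(5, 7, 12) / 24)
  expect_equal(sum(cn2$pct_of_clean_tags), 100)

  # degenerate empty library: zeros with the empty flag
  lib0 <- cleanTags(character(0), libraryId = "none")
  cn0 <- copyNumberDistribution(lib0)
  expect_true(attr(cn0, "empty"))
  expect_true(all(cn0$pct_of_clean_tags == 0))

  expect_error(copyNumberDistribution(lib, breaks = c(3L, 6L)), "\\[2, Inf\\)")
})

test_that("saturation curves are monotone, nested, and hit the full count", {
  tx <- generateTranscriptome(80, c(150, 400), seed = 31)
  sc <- makeDEScenario(tx, fracDE = 0, seed = 32)
  sim <- simulateTagLibrary(tx, baselineAbundance(sc), 20000,
                            noiselessProfile(seed = 33))
  lib <- cleanTags(sim$reads, libraryId = "sat")
  idx <- buildTagIndex(tx)
  sat <- saturationCurve(lib, idx, seed = 1)

  expect_true(all(diff(sat$genes_detected) >= 0))
  full <- mapLibrary(lib, idx)$stats$genes_detected
  expect_equal(sat$genes_detected[nrow(sat)], full)

  expect_error(saturationCurve(lib, idx, fractions = c(0.5, 0.9)),
               "include 1")
  expect_error(saturationCurve(lib, idx, fractions = c(0, 1)), "\\(0, 1\\]")
})

test_that("subsampling variability at half depth is small on a deep library", {
  tx <- generateTranscriptome(100, c(150, 400), seed = 41)
  sc <- makeDEScenario(tx, fracDE = 0, seed = 42)
  sim <- simulateTagLibrary(tx, baselineAbundance(sc), 1e5,
                            noiselessProfile(seed = 43))
  lib <- cleanTags(sim$reads, libraryId = "deep")
  idx <- buildTagIndex(tx)
  d1 <- saturationCurve(lib, idx, fractions = c(0.5, 1), seed = 1)
  d2 <- saturationCurve(lib, idx, fractions = c(0.5, 1), seed = 2)
  expect_lt(abs(d1$genes_detected[1] - d2$genes_detected[1]),
            0.05 * length(tx))
})

test_that("deeper libraries lose a smaller singleton fraction", {
  tx <- generateTranscriptome(60, c(150, 400), seed = 51)
  sc <- makeDEScenario(tx, fracDE = 0, seed = 52)
  singletonFrac <- function(depth, seed) {
    sim <- simulateTagLibrary(tx, baselineAbundance(sc), depth,
                              noiseProfile(0.002, 0, 0, 0, 0, seed = seed))
    lib <- cleanTags(sim$reads, libraryId = "d")
    filterStats(lib)[["singleton"]] / depth
  }
  shallow <- mean(vapply(1:3, function(s) singletonFrac(2000, s), numeric(1)))
  deep <- mean(vapply(1:3, function(s) singletonFrac(20000, s), numeric(1)))
  expect_lte(deep, shallow)
})
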