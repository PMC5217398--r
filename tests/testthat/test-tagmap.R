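test_that("whole tag counts are credited to unique genes only", {
  t1 <- paste0("CATG", strrep("A", 17))
  shared <- paste0("CATG", strrep("C", 17))
  tx <- c(G = paste0("TT", t1), H1 = paste0("GG", shared),
          H2 = paste0("AA", shared))
  idx <- buildTagIndex(tx)

  # unique tag: all counts to its gene, 100% mapped and unambiguous
  lib <- cleanTags(rep(t1, 5), libraryId = "u")
  m <- mapLibrary(lib, idx)
  expect_equal(unname(m$geneCounts[["G"]]), 5L)
  expect_equal(m$stats$mapped_pct, 100)
  expect_equal(m$stats$unambiguous_pct, 100)
  expect_equal(m$stats$genes_detected, 1L)

  # ambiguous tag: counted as mapped but credited to no gene
  lib2 <- cleanTags(c(rep(t1, 5), rep(shared, 3)), libraryId = "a")
  m2 <- mapLibrary(lib2, idx)
  expect_equal(unname(m2$geneCounts[["G"]]), 5L)
  expect_equal(unname(m2$geneCounts[["H1"]]), 0L)
  expect_equal(m2$stats$mapped, 8)
  expect_equal(m2$stats$unambiguous, 5)
  expect_equal(m2$stats$genes_detected, 1L)
})

test_that("accounting identity holds and noise-free counts match truth", {
  tx <- generateTranscriptome(60, c(150, 400), seed = 61)
  idx <- buildTagIndex(tx)
  sc <- makeDEScenario(tx, fracDE = 0.1, seed = 62)

  # noisy library: identity is exact regardless of noise
  simN <- simulateTagLibrary(tx, baselineAbundance(sc), 20000,
                             noiseProfile(0.01, 0.05, 0.02, 0.02, 0.02,
                                          seed = 63))
  libN <- cleanTags(simN$reads, libraryId = "noisy")
  mN <- mapLibrary(libN, idx)
  expect_equal(mN$stats$unambiguous + mN$stats$ambiguous +
                 mN$stats$unmapped, mN$stats$clean_total)

  # noise-free, leak-free: per-gene counts equal the manifest truth
  # (minus tags the copy >= 2 filter removed)
  sim0 <- simulateTagLibrary(tx, baselineAbundance(sc), 20000,
                             noiselessProfile(seed = 64))
  lib0 <- cleanTags(sim0$reads, libraryId = "clean")
  m0 <- mapLibrary(lib0, idx)
  truth <- sim0$manifest$geneCounts
  surviving <- ifelse(truth >= 2L, truth, 0L)
  expect_identical(m0$geneCounts[names(truth)], surviving)
})

test_that("count matrices assemble with zero fill and carried totals", {
  t1 <- paste0("CATG", strrep("A", 17))
  t2 <- paste0("CATG", strrep("G", 17))
  tx <- c(g1 = paste0("TT", t1), g2 = paste0("CC", t2))
  idx <- buildTagIndex(tx)
  mA <- mapLibrary(cleanTags(rep(t1, 4), libraryId = "A"), idx)
  mB <- mapLibrary(cleanTags(rep(t2, 6), libraryId = "B"), idx)

  one <- assembleCountMatrix(list(A = mA))
  expect_equal(dim(one), c(2L, 1L))
  expect_equal(unname(SummarizedExperiment::assay(one)["g1", "A"]), 4L)

  both <- assembleCountMatrix(list(A = mA, B = mB))
  counts <- SummarizedExperiment::assay(both, "counts")
  expect_equal(unname(counts["g1", ]), c(4L, 0L))
  expect_equal(unname(counts["g2", ]), c(0L, 6L))
  expect_equal(unname(colSums(counts)),
               unname(c(mA$stats$unambiguous, mB$stats$unambiguous)))
  expect_equal(unname(cleanTotals(both)), c(4, 6))

  expect_error(assembleCountMatrix(list(A = mA, A = mB)), "duplicate")
})

test_that("six-library assembly satisfies the column-sum identity", {
  tx <- generateTranscriptome(40, c(150, 300), seed = 71)
  idx <- buildTagIndex(tx)
  sc <- makeDEScenario(tx, fracDE = 0.1, seed = 72)
  ids <- c("A_CK", "A_0.5h", "A_24h", "B_CK", "B_0.5h", "B_24h")
  cond <- c("A", "B", "B", "A", "B", "B")
  mapped <- lapply(seq_along(ids), function(i) {
    ab <- conditionAbundance(sc, cond[i])
    sim <- simulateTagLibrary(tx, ab, 5000,
                              noiseProfile(0.005, 0.02, 0.01, 0.01, 0.01,
                                           seed = 80 + i))
    mapLibrary(cleanTags(sim$reads, libraryId = ids[i]), idx)
  })
  names(mapped) <- ids
  tce <- assembleCountMatrix(mapped)
  counts <- SummarizedExperiment::assay(tce, "counts")
  expect_equal(unname(colSums(counts)),
               vapply(mapped, function(m) m$stats$unambiguous, numeric(1),
                      USE.NAMES = FALSE))
  expect_true(all(colSums(counts) <= cleanTotals(tce)))
  st <- mappingStatsTable(tce)
  expect_equal(names(st), c("statistic", ids))
  expect_equal(nrow(st), 7L)
})

test_that("sequencing errors shift recovery from perfect to one-mismatch", {
  tx <- generateTranscriptome(50, c(150, 400), seed = 91)
  idx <- buildTagIndex(tx)
  sc <- makeDEScenario(tx, fracDE = 0, seed = 92)
  shares <- lapply(c(0, 0.005, 0.02), function(rate) {
    sim <- simulateTagLibrary(tx, baselineAbundance(sc), 20000,
                              noiseProfile(rate, 0, 0, 0, 0, seed = 93))
    m <- mapLibrary(cleanTags(sim$reads, libraryId = "e"), idx)
    res <- m$resolution
    c(perfect = sum(res$count[res$match_class == "perfect" &
                                res$status == "gene"]),
      mm1 = sum(res$count[res$match_class == "mismatch1" &
                            res$status == "gene"]),
      total = m$stats$clean_total)
  })
  perfectFrac <- vapply(shares, function(s) s[["perfect"]] / s[["total"]],
                        numeric(1))
  mm1Frac <- vapply(shares, function(s) s[["mm1"]] / s[["total"]],
                    numeric(1))
  expect_true(all(diff(perfectFrac) < 0))
  expect_true(all(diff(mm1Frac) > 0))
  # recovery never drops below the perfect-only baseline
  recovered <- vapply(shares, function(s) s[["perfect"]] + s[["mm1"]],
                      numeric(1))
  expect_true(all(recovered >= vapply(shares, `[[`, numeric(1), "perfect")))
})
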