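test_that("TPM normalization is tag count per million clean tags", {
  expect_equal(tpmNormalize(100, 1e6), 100)
  expect_equal(tpmNormalize(0, 1e6), 0)
  expect_equal(tpmNormalize(57, 5943058), 57 / 5943058 * 1e6)
  expect_error(tpmNormalize(-1, 1e6))
  expect_error(tpmNormalize(5, 0))
})

test_that("Audic-Claverie boundary cases and symmetry hold", {
  # x = y = 0 with equal totals: point mass 0.5 per count, p = 1 two-sided
  expect_equal(audicClaveriePValue(0, 0, 1e5, 1e5), 1)
  # library-exchange symmetry
  set.seed(5)
  for (i in 1:25) {
    x <- sample(0:200, 1); y <- sample(0:200, 1)
    n1 <- sample(c(1e5, 2e5, 5943058), 1); n2 <- sample(c(1e5, 3e5), 1)
    expect_equal(audicClaveriePValue(x, y, n1, n2),
                 audicClaveriePValue(y, x, n2, n1), tolerance = 1e-12)
  }
  # p-values live in [0, 1]
  p <- audicClaveriePValue(c(0, 3, 500), c(64, 3, 100), 1e5, 2e5)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("Audic-Claverie matches the conditional-binomial oracle", {
  set.seed(8)
  xs <- sample(0:50, 30, replace = TRUE)
  ys <- sample(0:50, 30, replace = TRUE)
  for (i in seq_along(xs)) {
    for (tot in list(c(1e5, 1e5), c(1e5, 2e5))) {
      expect_lt(abs(audicClaveriePValue(xs[i], ys[i], tot[1], tot[2]) -
                      acpOracle(xs[i], ys[i], tot[1], tot[2])), 1e-9)
    }
  }
})

test_that("the conditional distribution is normalized", {
  for (x in c(0, 1, 10, 100)) {
    for (tot in list(c(1e5, 1e5), c(1e5, 2e5), c(5943058, 5712643))) {
      kmax <- ceiling((x + 1) * tot[2] / tot[1]) + 5000L
      total <- sum(exp(dgetag:::.acLogProb(0:kmax, x, tot[1], tot[2])))
      expect_lt(abs(total - 1), 1e-9)
    }
  }
})

test_that("DE calls honour both thresholds and the zero floor", {
  genes <- sprintf("g%02d", 1:20)
  # equal counts, equal totals: nothing called
  cts <- sample(0:50, 20, replace = TRUE)
  de0 <- callDE(makeCountTce(cts, cts, 1e5, 1e5, genes), "A", "B")
  expect_true(all(de0$call == "ns"))
  expect_true(all(de0$log2_ratio[cts > 0] == 0))

  # x = 0 vs y = 64: called up; ratio uses the 0.5-tag floor
  cA <- c(0, rep(10, 19)); cB <- c(64, rep(10, 19))
  de <- callDE(makeCountTce(cA, cB, 1e5, 1e5, genes), "A", "B")
  expect_identical(unname(de["g01", "call"]), "up")
  expect_equal(unname(de["g01", "log2_ratio"]), log2(64 / 0.5))
  expect_lt(de["g01", "p_value"], acpOracle(0, 64, 1e5, 1e5) + 1e-12)

  # genes at zero in both libraries are excluded from testing and BH
  cA2 <- c(0, cA[-1]); cB2 <- c(0, cB[-1])
  de2 <- callDE(makeCountTce(cA2, cB2, 1e5, 1e5, genes), "A", "B")
  expect_true(is.na(de2["g01", "p_value"]))
  expect_identical(unname(de2["g01", "call"]), "ns")
  expect_equal(sum(!is.na(de2$p_value)), 19L)

  expect_error(callDE(de0, "A", "B"))
  expect_error(
    callDE(makeCountTce(cA, cB, 1e5, 1e5, genes), "A", "Z"), "Z")
})

test_that("exchanging the libraries flips calls and preserves p-values", {
  set.seed(13)
  genes <- sprintf("g%03d", 1:200)
  cA <- rpois(200, 30); cB <- rpois(200, 30)
  cB[1:10] <- cB[1:10] * 6 # force some calls
  fwd <- callDE(makeCountTce(cA, cB, 2e5, 25e4, genes), "A", "B")
  rev <- callDE(makeCountTce(cB, cA, 25e4, 2e5, genes), "A", "B")
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)
  expect_equal(fwd$log2_ratio, -rev$log2_ratio, tolerance = 1e-12)
  flip <- c(up = "down", down = "up", ns = "ns")
  expect_identical(unname(flip[fwd$call]), rev$call)
})

test_that("TPM columns sum to the mapped-per-clean ratio exactly", {
  tx <- generateTranscriptome(40, c(150, 300), seed = 101)
  idx <- buildTagIndex(tx)
  sc <- makeDEScenario(tx, fracDE = 0, seed = 102)
  sim <- simulateTagLibrary(tx, baselineAbundance(sc), 10000,
                            noiseProfile(0.005, 0.02, 0.01, 0.01, 0.01,
                                         seed = 103))
  m <- mapLibrary(cleanTags(sim$reads, libraryId = "L"), idx)
  tpm <- tpmNormalize(m$geneCounts, m$stats$clean_total)
  expect_equal(sum(tpm),
               m$stats$unambiguous / m$stats$clean_total * 1e6)
})

test_that("Venn decomposition is the exhaustive per-gene case analysis", {
  # hand cases
  mk <- function(calls, genes) {
    S4Vectors::DataFrame(call = calls, row.names = genes)
  }
  v <- vennDecompose(mk(c("up", "up", "ns"), c("a", "b", "c")),
                     mk(c("ns", "up", "up"), c("a", "b", "c")))
  expect_identical(v$common_up, "b")
  expect_identical(v$only_t1_up, "a")
  expect_identical(v$only_t2_up, "c")

  v2 <- vennDecompose(mk(c("up"), "d"), mk(c("down"), "d"))
  expect_identical(v2$up_then_down, "d")

  # random 200-gene fixture against the per-gene oracle
  set.seed(17)
  genes <- sprintf("g%03d", 1:200)
  c1 <- sample(c("up", "down", "ns"), 200, replace = TRUE,
               prob = c(.2, .2, .6))
  c2 <- sample(c("up", "down", "ns"), 200, replace = TRUE,
               prob = c(.2, .2, .6))
  got <- vennDecompose(mk(c1, genes), mk(c2, genes))
  exp <- vennOracle(structure(c1, names = genes),
                    structure(c2, names = genes))
  for (k in names(exp)) expect_setequal(got[[k]], exp[[k]])

  # disjoint and covering
  all <- unlist(got)
  expect_equal(anyDuplicated(all), 0L)
  expect_setequal(all, genes[c1 != "ns" | c2 != "ns"])
  expect_equal(sum(vennCounts(got)), length(all))

  expect_error(vennDecompose(mk("up", "a"), mk("up", "b")), "universe")
})

test_that("2^-ddCt relative expression follows the closed form", {
  expect_equal(ddctFoldChange(20, 18, 22, 20), 1)
  expect_equal(ddctFoldChange(20, 18, 22, 19), 2)
  expect_equal(ddctFoldChange(21.32, 18, 18, 18), 2^-3.32)
  expect_error(ddctFoldChange(NA, 18, 18, 18))
})
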