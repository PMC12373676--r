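test_that("generators are deterministic and leave the RNG state untouched", {
  p1 <- generateGametologPair(length = 600, seed = 7)
  p2 <- generateGametologPair(length = 600, seed = 7)
  expect_identical(p1, p2)
  p3 <- generateGametologPair(length = 600, seed = 8)
  expect_false(identical(p1$y, p3$y))

  set.seed(99)
  before <- stats::runif(5)
  set.seed(99)
  invisible(generateGametologPair(length = 600, seed = 7))
  invisible(generateCohort(p1, seed = 7))
  invisible(syntheticCsPDS5())
  after <- stats::runif(5)
  expect_identical(before, after)

  c1 <- generateCohort(p1, nMale = 2, nFemale = 2, seed = 5)
  c2 <- generateCohort(p1, nMale = 2, nFemale = 2, seed = 5)
  expect_identical(c1$samples, c2$samples)
  expect_identical(SummarizedExperiment::assay(c1$se),
                   SummarizedExperiment::assay(c2$se))
})

test_that("the planted site and conserved windows honour the stated geometry", {
  for (seed in 1:3) {
    pair <- generateGametologPair(length = 1000, divergence = 0.02,
                                  seed = seed, primerLen = 20,
                                  flankGap = 120)
    tr <- pair$truth
    expect_identical(tr$sitePos, 500L)
    # the recognition sequence sits exactly once in Y, nowhere in X
    expect_identical(matchIUPAC(tr$enzyme@recognition, pair$y),
                     tr$sitePos)
    expect_identical(matchIUPAC(tr$enzyme@recognition, pair$x), integer(0))
    # every site position differs between the alleles
    for (i in seq_len(tr$siteLength) - 1L) {
      expect_false(substr(pair$x, tr$sitePos + i, tr$sitePos + i) ==
                     substr(pair$y, tr$sitePos + i, tr$sitePos + i))
    }
    # conserved windows are mutation-free (identical between alleles)
    for (w in tr$windows) {
      expect_identical(substr(pair$x, w[1], w[2]), substr(pair$y, w[1], w[2]))
      expect_identical(w[2] - w[1] + 1L, 20L)
    }
  }
})

test_that("realised divergence tracks the requested rate", {
  pair <- generateGametologPair(length = 2000, divergence = 0.05, seed = 11)
  xc <- strsplit(pair$x, "")[[1]]
  yc <- strsplit(pair$y, "")[[1]]
  diffs <- sum(xc != yc) - pair$truth$siteLength
  free <- 2000 - pair$truth$siteLength - 2L * 20L
  # binomial interval around 0.05 with wide slack for scrub adjustments
  expect_gt(diffs / free, 0.03)
  expect_lt(diffs / free, 0.07)
})

test_that("zero divergence leaves only the planted site (plus rare scrub edits)", {
  pair <- generateGametologPair(length = 600, divergence = 0, seed = 12)
  xc <- strsplit(pair$x, "")[[1]]
  yc <- strsplit(pair$y, "")[[1]]
  diffPos <- which(xc != yc)
  siteCols <- pair$truth$sitePos:(pair$truth$sitePos +
                                    pair$truth$siteLength - 1L)
  expect_true(all(siteCols %in% diffPos))
  expect_lte(length(diffPos), pair$truth$siteLength + 6L)
})

test_that("generator input validation", {
  expect_error(generateGametologPair(length = 100), ">= 300")
  expect_error(generateGametologPair(length = 600, divergence = 0.5),
               "0.3")
  expect_error(generateCohort(generateGametologPair(length = 600, seed = 1),
                              nMale = 0), "at least one")
})

test_that("cohorts carry the Y transcript in males only, with matching TPM", {
  pair <- generateGametologPair(length = 800, divergence = 0.02, seed = 21)
  coh <- generateCohort(pair, nMale = 3, nFemale = 3, snpRate = 0.001,
                        nDecoys = 10, seed = 21)
  expect_identical(names(coh$samples),
                   c("M1", "M2", "M3", "F1", "F2", "F3"))
  for (sid in names(coh$samples)) {
    hasY <- "Y.t1" %in% names(coh$samples[[sid]])
    expect_identical(hasY, coh$sex[[sid]] == "male", info = sid)
    expect_true("X.t1" %in% names(coh$samples[[sid]]))
    # the planted diagnostic site is exempt from per-sample SNPs
    if (hasY) {
      tr <- pair$truth
      expect_identical(
        substr(coh$samples[[sid]][["Y.t1"]], tr$sitePos,
               tr$sitePos + tr$siteLength - 1L),
        substr(pair$y, tr$sitePos, tr$sitePos + tr$siteLength - 1L))
    }
  }
  tpm <- SummarizedExperiment::assay(coh$se, "tpm")
  expect_true(all(tpm["Y.t1", c("F1", "F2", "F3")] == 0))
  expect_gt(mean(tpm["Y.t1", c("M1", "M2", "M3")]), 10)
  expect_true(all(tpm["X.t1", ] > 0))
  # the biased decoy is male-skewed but not female-absent
  expect_true(all(tpm[coh$truth$biasedDecoy, ] > 0))
  expect_gt(mean(tpm[coh$truth$biasedDecoy, c("M1", "M2", "M3")]),
            mean(tpm[coh$truth$biasedDecoy, c("F1", "F2", "F3")]))
})

test_that("the synthetic assay fixture satisfies its published arithmetic", {
  csp <- syntheticCsPDS5()
  expect_identical(nchar(csp$x), nchar(csp$y))
  # exactly the three engineered differences, all inside the site
  xc <- strsplit(csp$x, "")[[1]]
  yc <- strsplit(csp$y, "")[[1]]
  expect_identical(which(xc != yc), csp$truth$diffColumns)
  expect_identical(sum(columnClasses(csp$alignment) == "substitution"), 3L)
  expect_identical(sum(columnClasses(csp$alignment) == "indel"), 0L)
  # EcoRI present exactly once in Y, absent from X
  expect_identical(matchIUPAC("GAATTC", csp$y, forbidN = TRUE),
                   csp$truth$siteStartGene)
  expect_identical(matchIUPAC("GAATTC", csp$x, forbidN = TRUE), integer(0))
  # the male probe spans the site on Y; the female probe its X counterpart
  expect_gt(length(matchIUPAC(csp$truth$maleProbe, csp$y)), 0L)
  expect_identical(matchIUPAC(csp$truth$maleProbe, csp$x), integer(0))
  expect_gt(length(matchIUPAC(csp$truth$femProbe, csp$x)), 0L)
})

test_that("the cultivar fixture differs from the base rows only at primer SNPs", {
  cult <- syntheticCsPDS5Cultivars()
  base <- syntheticCsPDS5()
  gal <- cult$alignment
  expect_length(gal@extraRows, 4L)
  expect_identical(gal@xRow, base$x)
  expect_identical(gal@yRow, base$y)
  for (nm in names(gal@extraRows)) {
    ref <- if (grepl("chrX$", nm)) base$x else base$y
    rc <- strsplit(ref, "")[[1]]
    ec <- strsplit(gal@extraRows[[nm]], "")[[1]]
    d <- which(rc != ec)
    expect_true(all(d >= cult$truth$fwdWindow[1]), info = nm)
    expect_true(all(d <= cult$truth$revWindow[2]), info = nm)
  }
})

test_that("the supplementary stand-ins have the documented shapes", {
  s1 <- syntheticSupplementS1()
  expect_length(s1, 25L)
  expect_true(all(grepl("^FE\\.chrY\\.t", names(s1))))
  expect_identical(s1[["FE.chrY.t9"]], syntheticCsPDS5()$y)

  s2 <- syntheticSupplementS2()
  expect_length(s2, 6L)
  for (g in names(s2)) {
    rows <- s2[[g]]
    expect_length(rows, 2L)
    expect_identical(nchar(rows[[1]]), nchar(rows[[2]]))
    expect_identical(names(rows), paste0(g, c("_chrX", "_chrY")))
  }
  expect_identical(unname(s2[["FE.chrY.t9"]][2]), syntheticCsPDS5()$y)
})
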