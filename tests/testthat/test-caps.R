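test_that("scanDifferentialSites finds exactly the engineered Y-only EcoRI site", {
  csp <- syntheticCsPDS5()
  sites <- scanDifferentialSites(csp$alignment, list(csp$truth$enzyme))
  expect_length(sites, 1L)
  s <- sites[[1]]
  expect_identical(s@enzyme@name, "EcoRI")
  expect_identical(s@alleleWithSite, "Y")
  expect_identical(s@siteStart, csp$truth$siteStartGene)
  expect_identical(s@strand, "+")
  expect_identical(s@alignmentColumn, csp$truth$siteStartGene)
})

test_that("identical alleles yield no differential sites", {
  s <- paste0(randDna(100), "GAATTC", randDna(100))
  gal <- GametologAlignment(s, s)
  expect_length(scanDifferentialSites(gal, defaultEnzymes()), 0L)
})

test_that("generated pairs carry their planted differential site and no X-side site", {
  for (seed in 1:5) {
    pair <- generateGametologPair(length = 800, divergence = 0.02,
                                  seed = seed)
    gal <- GametologAlignment(pair$x, pair$y)
    sites <- scanDifferentialSites(gal, list(pair$truth$enzyme))
    alleles <- vapply(sites, function(s) s@alleleWithSite, character(1))
    starts <- vapply(sites, function(s) s@siteStart, integer(1))
    expect_true(any(alleles == "Y" & starts == pair$truth$sitePos),
                info = paste("seed", seed))
    # the generator scrubs every recognition match from the X copy
    expect_false(any(alleles == "X"), info = paste("seed", seed))
  }
})

test_that("non-palindromic recognition is detected on the minus strand", {
  enz <- RestrictionEnzyme("BsaI", "GGTCTC", 1)
  expect_false(enz@palindromic)
  set.seed(51)
  repeat {
    backbone <- randDna(200)
    yc <- strsplit(backbone, "")[[1]]
    yc[101:106] <- strsplit(revcomp("GGTCTC"), "")[[1]]
    y <- paste(yc, collapse = "")
    xc <- strsplit(backbone, "")[[1]]
    xc[101:106] <- c("A", "A", "A", "A", "A", "A")
    x <- paste(xc, collapse = "")
    # regenerate until the only recognition match anywhere is the planted one
    if (length(matchIUPAC("GGTCTC", x)) == 0L &&
        length(matchIUPAC("GAGACC", x)) == 0L &&
        length(matchIUPAC("GGTCTC", y)) == 0L &&
        identical(matchIUPAC("GAGACC", y), 101L)) break
  }
  sites <- scanDifferentialSites(GametologAlignment(x, y), list(enz))
  expect_length(sites, 1L)
  expect_identical(sites[[1]]@strand, "-")
  expect_identical(sites[[1]]@alleleWithSite, "Y")
  expect_identical(sites[[1]]@siteStart, 101L)
})

test_that("an indel-shifted site is not reported as differential", {
  # same site in both alleles, but offset by a deletion in X upstream
  set.seed(53)
  repeat {
    left <- randDna(50)
    right <- randDna(50)
    y <- paste0(left, "AAAA", "GAATTC", right)
    x <- paste0(left, "GAATTC", right)
    # exactly one (intended) EcoRI match in each allele
    if (identical(matchIUPAC("GAATTC", x), 51L) &&
        identical(matchIUPAC("GAATTC", y), 55L)) break
  }
  gal <- alignPair(x, y)
  sites <- scanDifferentialSites(gal, list(RestrictionEnzyme("EcoRI",
                                                             "GAATTC", 1)))
  expect_length(sites, 0L)
})

test_that("findConservedFlanks returns the nearest clean windows", {
  csp <- syntheticCsPDS5()
  site <- c(csp$truth$siteStartGene, csp$truth$siteStartGene + 5L)
  fl <- findConservedFlanks(csp$alignment, site)
  # all non-site columns are identical, so the windows abut the site
  expect_identical(fl$left, c(site[1] - 20L, site[1] - 1L))
  expect_identical(fl$right, c(site[2] + 1L, site[2] + 20L))
})

test_that("findConservedFlanks skips indel and hyper-polymorphic columns", {
  base <- randDna(100)
  yc <- strsplit(base, "")[[1]]
  xc <- yc
  # site columns 61..66 differ
  yc[61:66] <- strsplit("GAATTC", "")[[1]]
  xc[61:66] <- strsplit("ACCGGA", "")[[1]]
  # indel: X gapped at columns 55-56
  xc[55:56] <- "-"
  gal <- GametologAlignment(paste(xc, collapse = ""),
                            paste(yc, collapse = ""))
  cfg <- flankConfig(primerLen = 10, maxPoly = 0)
  fl <- findConservedFlanks(gal, c(61L, 66L), cfg)
  expect_identical(fl$left, c(45L, 54L))
  expect_identical(fl$right, c(67L, 76L))
  # a window budget too tight for any clean window returns NULL
  cfgTight <- flankConfig(primerLen = 10, maxPoly = 0, maxDistance = 5)
  expect_null(findConservedFlanks(gal, c(61L, 66L), cfgTight))
})

test_that("consensus design on the multi-cultivar alignment reproduces the published primers", {
  cult <- syntheticCsPDS5Cultivars()
  windows <- list(left = cult$truth$fwdWindow, right = cult$truth$revWindow)
  primers <- designDegeneratePrimers(cult$alignment, windows)
  expect_identical(primers$fwd@seq, "GGAYTATCATCCAGAGAMTG")
  expect_identical(primers$fwd@degeneracy, 4L)
  expect_identical(primers$rev@seq, "TACCATATTCTCATCAGARGC")
  expect_identical(primers$rev@degeneracy, 2L)
  expect_identical(primers$fwd@strand, "+")
  expect_identical(primers$rev@strand, "-")
})

test_that("designed primers bind every row of the alignment", {
  cult <- syntheticCsPDS5Cultivars()
  windows <- list(left = cult$truth$fwdWindow, right = cult$truth$revWindow)
  primers <- designDegeneratePrimers(cult$alignment, windows)
  gal <- cult$alignment
  rows <- c(gsub("-", "", gal@xRow, fixed = TRUE),
            gsub("-", "", gal@yRow, fixed = TRUE),
            gsub("-", "", gal@extraRows, fixed = TRUE))
  for (r in rows) {
    expect_gt(length(matchIUPAC(primers$fwd@seq, r)), 0L)
    expect_gt(length(matchIUPAC(revcomp(primers$rev@seq), r)), 0L)
  }
})

test_that("primer constraints are enforced: 3' anchor, degeneracy, Tm", {
  cult <- syntheticCsPDS5Cultivars()
  windows <- list(left = cult$truth$fwdWindow, right = cult$truth$revWindow)
  cfg <- primerConfig()
  primers <- designDegeneratePrimers(cult$alignment, windows, cfg)
  for (p in primers) {
    expect_true(substr(p@seq, nchar(p@seq), nchar(p@seq)) %in%
                  c("A", "C", "G", "T"))
    expect_lte(p@degeneracy, cfg$maxDegeneracy)
    expect_gte(p@tmEstimate, cfg$tmRange[1])
    expect_lte(p@tmEstimate, cfg$tmRange[2])
    expect_gte(nchar(p@seq), cfg$minLen)
    expect_lte(nchar(p@seq), cfg$maxLen)
  }
  # an impossible degeneracy budget fails loudly
  expect_error(
    designDegeneratePrimers(cult$alignment, windows,
                            primerConfig(maxDegeneracy = 1)),
    "primer design failed")
  expect_error(designDegeneratePrimers(cult$alignment, NULL),
               "no conserved flanks")
})

test_that("allele probes match their own allele and mismatch the other", {
  csp <- syntheticCsPDS5()
  site <- scanDifferentialSites(csp$alignment, list(csp$truth$enzyme))[[1]]
  probes <- designAlleleProbes(csp$alignment, site)
  expect_gt(length(matchIUPAC(probes$cut, csp$y)), 0L)
  expect_identical(matchIUPAC(probes$cut, csp$x), integer(0))
  expect_gt(length(matchIUPAC(probes$uncut, csp$x)), 0L)
  expect_identical(matchIUPAC(probes$uncut, csp$y), integer(0))
  # the probe window covers at least one diagnostic column
  expect_true(any(probes$diagnosticColumns >= probes$windowColumns[1] &
                    probes$diagnosticColumns <= probes$windowColumns[2]))
  expect_setequal(probes$diagnosticColumns, csp$truth$diffColumns)
})

test_that("probe design fails cleanly when the alleles are identical at the site", {
  s <- paste0(randDna(60), "GAATTC", randDna(60))
  gal <- GametologAlignment(s, s)
  site <- new("DifferentialSite",
              enzyme = RestrictionEnzyme("EcoRI", "GAATTC", 1),
              alleleWithSite = "Y", siteStart = 61L, alignmentColumn = 61L,
              strand = "+")
  expect_error(designAlleleProbes(gal, site), "probe design failed")
})

test_that("designCapsCandidates assembles a working assay on the fixture pair", {
  csp <- syntheticCsPDS5()
  cands <- designCapsCandidates(csp$alignment, list(csp$truth$enzyme))
  expect_gte(length(cands), 1L)
  top <- cands[[1]]
  expect_identical(top@site@enzyme@name, "EcoRI")
  expect_identical(top@site@alleleWithSite, "Y")
  expect_identical(top@site@siteStart, csp$truth$siteStartGene)
  expect_identical(bands(top@predictedBands$XX), top@ampliconLenX)
  expect_length(bands(top@predictedBands$XY), 3L)
  expect_identical(genotypeCall(top@predictedBands$XX), "XX")
  expect_identical(genotypeCall(top@predictedBands$XY), "XY")
  # fragments conserve amplicon length for each allele
  expect_identical(sum(setdiff(bands(top@predictedBands$XY),
                               top@ampliconLenX)), top@ampliconLenY)
})

test_that("rankCandidates is deterministic under input permutation", {
  pair <- generateGametologPair(length = 2000, divergence = 0.05, seed = 3)
  gal <- alignPair(pair$x, pair$y)
  cands <- designCapsCandidates(gal, defaultEnzymes())
  expect_gte(length(cands), 2L)
  scores <- vapply(cands, function(cc) cc@score, numeric(1))
  expect_true(all(diff(scores) <= 0))
  set.seed(52)
  perm <- sample(length(cands))
  reranked <- rankCandidates(cands[perm])
  key <- function(cc) paste(cc@site@enzyme@name, cc@site@alleleWithSite,
                            cc@site@siteStart)
  expect_identical(vapply(reranked, key, character(1)),
                   vapply(cands, key, character(1)))
})
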