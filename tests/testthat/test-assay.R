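test_that("the fixture assay gives one 419 bp amplicon per allele", {
  csp <- syntheticCsPDS5()
  ampX <- insilicoPCR(csp$x, csp$truth$fwdPrimer, csp$truth$revPrimer)
  ampY <- insilicoPCR(csp$y, csp$truth$fwdPrimer, csp$truth$revPrimer)
  expect_identical(nrow(ampX), 1L)
  expect_identical(nrow(ampY), 1L)
  expect_identical(ampX$length, 419L)
  expect_identical(ampY$length, 419L)
  expect_identical(ampX$start, csp$truth$ampliconStart)
  expect_identical(ampX$end - ampX$start + 1L, 419L)
})

test_that("EcoRI digestion: Y amplicon 157 + 262, X amplicon uncut 419", {
  csp <- syntheticCsPDS5()
  ampX <- insilicoPCR(csp$x, csp$truth$fwdPrimer, csp$truth$revPrimer)$seq
  ampY <- insilicoPCR(csp$y, csp$truth$fwdPrimer, csp$truth$revPrimer)$seq
  eco <- csp$truth$enzyme
  expect_identical(bands(digest(ampY, eco)), c(157L, 262L))
  expect_identical(bands(digest(ampX, eco)), 419L)
  pb <- predictGenotypeBands(ampX, ampY, eco)
  expect_identical(bands(pb$XX), 419L)
  expect_identical(bands(pb$XY), c(157L, 262L, 419L))
  expect_true(pb$diagnostic)
})

test_that("the allelic-discrimination primers give a 200 bp site-spanning product", {
  csp <- syntheticCsPDS5()
  ampX <- insilicoPCR(csp$x, csp$truth$taqFwd, csp$truth$taqRev)
  ampY <- insilicoPCR(csp$y, csp$truth$taqFwd, csp$truth$taqRev)
  expect_identical(ampX$length, 200L)
  expect_identical(ampY$length, 200L)
  # the product spans the differential site
  expect_lte(ampY$start, csp$truth$siteStartGene)
  expect_gte(ampY$end, csp$truth$siteStartGene + 5L)
})

test_that("insilicoPCR handles non-binding primers and multiple products", {
  set.seed(60)
  expect_identical(nrow(insilicoPCR(randDna(100), "GGGGGGGGGG",
                                    "CCCCCCCCCC")), 0L)
  # two forward sites -> two products with one reverse site
  repeat {
    tpl <- paste0("AAACCCGGGTTT", randDna(30), "AAACCCGGGTTT", randDna(30),
                  "CATCATCATCAT")
    if (length(matchIUPAC("AAACCCGGGTTT", tpl)) == 2L &&
        length(matchIUPAC("CATCATCATCAT", tpl)) == 1L) break
  }
  amps <- insilicoPCR(tpl, "AAACCCGGGTTT", revcomp("CATCATCATCAT"))
  expect_identical(nrow(amps), 2L)
  expect_true(all(amps$length == nchar(amps$seq)))
  # maxAmplicon drops long products
  expect_identical(nrow(insilicoPCR(tpl, "AAACCCGGGTTT",
                                    revcomp("CATCATCATCAT"),
                                    maxAmplicon = 50)), 0L)
})

test_that("digestion fragments always sum to the amplicon length and match the oracle", {
  set.seed(61)
  enzymes <- defaultEnzymes()
  for (rep in 1:300) {
    n <- sample(50:400, 1)
    s <- randDna(n)
    enz <- enzymes[[sample(length(enzymes), 1)]]
    bp <- bands(digest(s, enz))
    expect_identical(sum(bp), n, info = paste(enz@name, s))
    expect_identical(sort(bp),
                     as.integer(oracleDigestBands(s, enz@recognition,
                                                  enz@cutOffset)),
                     info = paste(enz@name, s))
  }
})

test_that("digestion of a non-palindromic enzyme cuts both strands", {
  enz <- RestrictionEnzyme("BsaI", "GGTCTC", 1)
  s <- paste0(strrep("A", 20), "GGTCTC", strrep("A", 20),
              revcomp("GGTCTC"), strrep("A", 20))
  # plus-strand cut after 20 + 1 = 21; bottom-strand site at 47..52 cuts
  # after 46 + (6 - 1) = 51
  expect_identical(bands(digest(s, enz)), c(21L, 21L, 30L))
  expect_identical(sum(bands(digest(s, enz))), nchar(s))
})

test_that("blunt symmetric cutters digest a sequence and its reverse complement alike", {
  set.seed(62)
  for (enzName in c("EcoRV", "DraI")) {
    enz <- defaultEnzymes()[[enzName]]
    for (rep in 1:30) {
      s <- randDna(sample(100:300, 1))
      expect_identical(bands(digest(s, enz)),
                       bands(digest(revcomp(s), enz)),
                       info = paste(enzName, s))
    }
  }
})

test_that("an N in the template never creates or hides a phantom cut", {
  s <- paste0(strrep("C", 20), "GANTTC", strrep("C", 20))
  expect_identical(bands(digest(s, RestrictionEnzyme("EcoRI", "GAATTC", 1))),
                   46L)
})

test_that("predictGenotypeBands enforces the common-primer contract", {
  expect_error(predictGenotypeBands(NULL, "ACGT",
                                    RestrictionEnzyme("EcoRI", "GAATTC", 1)),
               "common-primer contract")
})

test_that("non-diagnostic assays are flagged", {
  s <- paste0(randDna(50), randDna(50))
  pb <- predictGenotypeBands(s, s, RestrictionEnzyme("EcoRI", "GAATTC", 1))
  expect_false(pb$diagnostic)
})

test_that("callGenotype round-trips predicted patterns at tolerance 0", {
  csp <- syntheticCsPDS5()
  ampX <- insilicoPCR(csp$x, csp$truth$fwdPrimer, csp$truth$revPrimer)$seq
  ampY <- insilicoPCR(csp$y, csp$truth$fwdPrimer, csp$truth$revPrimer)$seq
  pb <- predictGenotypeBands(ampX, ampY, csp$truth$enzyme)
  expect_identical(callGenotype(bands(pb$XY), pb, toleranceBp = 0), "XY")
  expect_identical(callGenotype(bands(pb$XX), pb, toleranceBp = 0), "XX")
})

test_that("callGenotype applies gel tolerance and reports ambiguity", {
  pats <- list(XX = BandPattern(419), XY = BandPattern(c(157, 262, 419)))
  expect_identical(callGenotype(c(160, 258, 422), pats, toleranceBp = 10),
                   "XY")
  expect_identical(callGenotype(c(160, 258, 422), pats, toleranceBp = 1),
                   "ambiguous")
  expect_identical(callGenotype(300, pats), "ambiguous")
  expect_identical(callGenotype(c(419, 419), pats), "XX")
  expect_error(callGenotype(numeric(0), pats), "no observed bands")
  # a non-diagnostic candidate can never be called
  same <- list(XX = BandPattern(100), XY = BandPattern(100))
  expect_identical(callGenotype(100, same), "ambiguous")
})

test_that("simulateTaqman reports VIC for XX, VIC+FAM for XY, nothing for NTC", {
  csp <- syntheticCsPDS5()
  site <- scanDifferentialSites(csp$alignment, list(csp$truth$enzyme))[[1]]
  probes <- designAlleleProbes(csp$alignment, site)
  expect_identical(simulateTaqman("XX", probes, csp$x, csp$y), "VIC")
  expect_setequal(simulateTaqman("XY", probes, csp$x, csp$y),
                  c("VIC", "FAM"))
  expect_identical(simulateTaqman("NTC", probes, csp$x, csp$y),
                   character(0))
})

test_that("simulateTaqman works with the published probe pair on the fixture", {
  csp <- syntheticCsPDS5()
  probes <- list(cut = csp$truth$maleProbe, uncut = csp$truth$femProbe)
  expect_identical(simulateTaqman("XX", probes, csp$x, csp$y), "VIC")
  expect_setequal(simulateTaqman("XY", probes, csp$x, csp$y),
                  c("VIC", "FAM"))
})

test_that("simulateTaqman rejects probes that match neither allele", {
  csp <- syntheticCsPDS5()
  probes <- list(cut = strrep("G", 25), uncut = csp$truth$femProbe)
  expect_error(simulateTaqman("XX", probes, csp$x, csp$y),
               "matches neither allele")
})
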