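# Synthetic stand-in for the CsPDS5 X/Y gametolog region and for the
# supplementary candidate-gene data. The real CsPDS5 sequences are not
# redistributed here; these generators build sequences engineered so that
# the published assay arithmetic holds exactly: the published degenerate
# primer pair amplifies a 419 bp product from both alleles, the Y allele
# carries a single EcoRI site whose digestion yields 157 + 262 bp, the X
# allele is uncut, and the published TaqMan primers amplify a 200 bp
# site-spanning product. Everything labelled "synthetic" in file names and
# docs derives from these functions.

# published assay oligos (used as design inputs and planted footprints)
.CSPDS5_OLIGOS <- list(
  fwdPrimer = "GGAYTATCATCCAGAGAMTG",
  revPrimer = "TACCATATTCTCATCAGARGC",
  taqFwd    = "TATTYCAWTGGAGCTTCTCACC",
  taqRev    = "AACCTTMGKAGCACAKRTTTC",
  maleProbe = "AGTTACAGTTTGGAATTCCTTT"
)

#' Synthetic CsPDS5-like X/Y gametolog pair
#'
#' Deterministic construction of a synthetic gene pair reproducing the
#' published CsPDS5-CAPS geometry: a 419 bp amplicon region (primer
#' footprints included) flanked by 100/80 bp of genomic context, a Y-only
#' EcoRI site placed so the top-strand cut falls 157 bp into the amplicon,
#' the male-probe sequence spanning the site, and planted footprints for the
#' published CAPS and TaqMan primer pairs. The X copy differs from the Y
#' copy at exactly three site positions, ablating the EcoRI site; everywhere
#' else the copies are identical, mirroring the highly conserved assay
#' region.
#'
#' This is a synthetic stand-in for the real supplementary alignment data,
#' not the CsPDS5 sequence itself.
#'
#' @return `list(x, y, alignment, truth)`: the two ungapped gene sequences,
#'   their (gap-free) [GametologAlignment-class], and a truth record with
#'   the published oligos, planted coordinates (1-based; `siteStartGene`,
#'   `siteStartAmplicon`, `ampliconStart`, `ampliconLen`) and the expected
#'   band sizes.
#' @export
syntheticCsPDS5 <- function() {
  ol <- .CSPDS5_OLIGOS
  # one concrete instantiation of each degenerate oligo, planted identically
  # in both alleles (the degenerate positions model cross-cultivar SNPs, not
  # X/Y differences)
  fwdFoot <- "GGATTATCATCCAGAGAATG"
  revFoot <- revcomp("TACCATATTCTCATCAGAAGC")
  taqFwdFoot <- "TATTTCATTGGAGCTTCTCACC"
  taqRevFoot <- revcomp("AACCTTAGGAGCACAGATTTC")
  leftFlank <- 100L; ampLen <- 419L; rightFlank <- 80L
  geneLen <- leftFlank + ampLen + rightFlank
  # amplicon-local feature starts (1-based)
  feats <- list(fwd = c(1L, fwdFoot), taqFwd = c(41L, taqFwdFoot),
                probe = c(145L, ol$maleProbe), taqRev = c(220L, taqRevFoot),
                rev = c(399L, revFoot))
  siteAmp <- 157L                       # GAATTC at amplicon 157..162
  diffAmp <- c(158L, 160L, 162L)        # X-allele substitutions
  diffBases <- c("C", "G", "A")         # GAATTC -> GCAGTA

  .withSeed(424243L, {
    gene <- sample(.BASES, geneLen, replace = TRUE)
    for (f in feats) {
      s <- leftFlank + as.integer(f[[1]])
      ch <- .seqChars(f[[2]])
      gene[s:(s + length(ch) - 1L)] <- ch
    }
    planted <- unlist(lapply(feats, function(f) {
      s <- leftFlank + as.integer(f[[1]])
      s:(s + nchar(f[[2]]) - 1L)
    }))
    diffGene <- leftFlank + diffAmp

    buildAlleles <- function(g) {
      y <- paste(g, collapse = "")
      gx <- g; gx[diffGene] <- diffBases
      list(x = paste(gx, collapse = ""), y = y)
    }
    # scrub: each planted pattern must occur exactly once (at its planted
    # start) in both alleles, and EcoRI only at the planted Y site.
    # Mutations are applied to the shared backbone so the alleles keep
    # exactly the three planted differences.
    pats <- list(
      list(pat = ol$fwdPrimer, keep = leftFlank + 1L),
      list(pat = revcomp(ol$revPrimer), keep = leftFlank + 399L),
      list(pat = ol$taqFwd, keep = leftFlank + 41L),
      list(pat = revcomp(ol$taqRev), keep = leftFlank + 220L),
      list(pat = "GAATTC", keep = leftFlank + siteAmp)
    )
    for (iter in 1:100) {
      al <- buildAlleles(gene)
      bad <- integer(0)
      for (pp in pats) {
        for (s in c(al$x, al$y)) {
          extra <- setdiff(matchIUPAC(pp$pat, s), pp$keep)
          for (st in extra) bad <- c(bad, st:(st + nchar(pp$pat) - 1L))
        }
      }
      bad <- setdiff(unique(bad), c(planted, diffGene))
      if (length(bad) == 0L) break
      q <- bad[1]
      gene[q] <- .mutateBase(gene[q])
    }
    al <- buildAlleles(gene)
    # construction must satisfy the published arithmetic
    ampX <- insilicoPCR(al$x, ol$fwdPrimer, ol$revPrimer)
    ampY <- insilicoPCR(al$y, ol$fwdPrimer, ol$revPrimer)
    stopifnot(nrow(ampX) == 1L, nrow(ampY) == 1L,
              ampX$length == ampLen, ampY$length == ampLen)
    probeCols <- (leftFlank + 145L):(leftFlank + 166L)
    femProbe <- substr(al$x, probeCols[1], probeCols[length(probeCols)])
    list(x = al$x, y = al$y,
         alignment = GametologAlignment(al$x, al$y),
         truth = c(ol, list(
           femProbe = femProbe,
           ampliconStart = leftFlank + 1L, ampliconLen = ampLen,
           siteStartAmplicon = siteAmp,
           siteStartGene = leftFlank + siteAmp,
           diffColumns = diffGene,
           enzyme = RestrictionEnzyme("EcoRI", "GAATTC", 1),
           expectedBands = list(X = 419L, Y = c(157L, 262L)))))
  })
}

#' Synthetic multi-cultivar CsPDS5-like alignment
#'
#' Extends [syntheticCsPDS5()] with four cultivar rows that differ from the
#' base X/Y rows only at the three primer-footprint positions corresponding
#' to the degenerate bases of the published primers (two SNP columns in the
#' forward window, one in the reverse). Consensus primer design over this
#' alignment therefore reproduces the published degenerate primer pair
#' exactly.
#'
#' @return `list(alignment, truth)`: a [GametologAlignment-class] whose extra
#'   rows are the cultivar variants, and the [syntheticCsPDS5()] truth
#'   augmented with `fwdWindow`/`revWindow` (1-based closed column ranges of
#'   the planted primer footprints).
#' @export
syntheticCsPDS5Cultivars <- function() {
  base <- syntheticCsPDS5()
  leftFlank <- base$truth$ampliconStart - 1L
  # degenerate positions (gene columns): fwd primer pos 4 (Y) and 18 (M),
  # rev footprint pos 3 (Y, i.e. primer R)
  snpCols <- leftFlank + c(4L, 18L, 399L + 2L)
  altBases <- c("C", "C", "C")  # base rows carry T, A, T at these columns
  variant <- function(row, which) {
    v <- .seqChars(row)
    v[snpCols[which]] <- altBases[which]
    paste(v, collapse = "")
  }
  extras <- c(
    GRM_chrX  = variant(base$x, 1:3),
    BCM_chrX  = variant(base$x, 2:3),
    AH3M_chrY = variant(base$y, 1L),
    KOMP_chrY = base$y
  )
  gal <- GametologAlignment(base$x, base$y, extraRows = extras)
  truth <- base$truth
  truth$fwdWindow <- c(leftFlank + 1L, leftFlank + 20L)
  truth$revWindow <- c(leftFlank + 399L, leftFlank + 419L)
  list(alignment = gal, truth = truth)
}

#' Synthetic stand-in for the supplementary Y-transcript set
#'
#' 25 transcript records named in the published style (`FE.chrY.t9` is the
#' synthetic CsPDS5-like Y copy; the rest are random decoy transcripts of
#' 300-600 bp). Synthetic data, not the published transcripts.
#'
#' @return Named character vector of 25 sequences.
#' @export
syntheticSupplementS1 <- function() {
  csp <- syntheticCsPDS5()
  ids <- paste0("FE.chrY.t",
                c(5, 9, 122, 25, 42, 47, 50:68))
  .withSeed(77001L, {
    seqs <- vapply(ids, function(id) .randSeq(sample(300:600, 1L)),
                   character(1))
    seqs[["FE.chrY.t9"]] <- csp$y
    seqs
  })
}

#' Synthetic stand-in for the supplementary candidate-gene alignments
#'
#' Six two-row X/Y alignments named after the published candidate
#' transcripts; `FE.chrY.t9` is the synthetic CsPDS5-like pair, the other
#' five are generated gametolog pairs at assorted divergences. Synthetic
#' data, not the published alignments.
#'
#' @return Named list of six named character vectors (rows `<gene>_chrX`,
#'   `<gene>_chrY`, equal gapped lengths).
#' @export
syntheticSupplementS2 <- function() {
  csp <- syntheticCsPDS5()
  genes <- c("FE.chrY.t5", "FE.chrY.t9", "FE.chrY.t122",
             "FE.chrY.t25", "FE.chrY.t42", "FE.chrY.t47")
  divs <- c(0.01, NA, 0.02, 0.03, 0.05, 0.08)
  out <- lapply(seq_along(genes), function(i) {
    if (genes[i] == "FE.chrY.t9") {
      rows <- c(csp$x, csp$y)
    } else {
      pr <- generateGametologPair(length = 800, divergence = divs[i],
                                  seed = 9000L + i)
      rows <- c(pr$x, pr$y)
    }
    stats::setNames(rows, paste0(genes[i], c("_chrX", "_chrY")))
  })
  stats::setNames(out, genes)
}
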