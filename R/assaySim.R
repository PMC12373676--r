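# In-silico validation of a designed assay: PCR amplification, restriction
# digestion, gel band prediction, genotype calling, and TaqMan-style
# allele-signal simulation.

.primerSeq <- function(p) {
  if (is(p, "DegeneratePrimer")) p@seq else toupper(as.character(p))
}

#' In-silico PCR
#'
#' Reports every template interval where the forward primer matches the plus
#' strand and the reverse primer matches the minus strand downstream, with
#' zero mismatches under IUPAC expansion (degenerate primers carry all their
#' variants, so binding is exact by construction). Amplicons include both
#' primer footprints and are reported 5'->3' on the plus strand.
#'
#' @param template Template sequence (character or `DNAString`).
#' @param fwd,rev Primers, as [DegeneratePrimer-class] or IUPAC strings
#'   (both written 5'->3').
#' @param maxAmplicon Maximum product length considered (bp).
#' @return `data.frame` with columns `start`, `end` (1-based, closed),
#'   `length`, `seq`; zero rows when the primers do not bind.
#' @export
insilicoPCR <- function(template, fwd, rev, maxAmplicon = 3000) {
  t <- unname(.asSeqChar(template)[1])
  f <- .primerSeq(fwd); r <- .primerSeq(rev)
  fl <- nchar(f); rl <- nchar(r)
  fStarts <- matchIUPAC(f, t)
  rStarts <- matchIUPAC(revcomp(r), t)
  rows <- list()
  for (fs in fStarts) {
    for (rs in rStarts) {
      if (rs < fs + fl) next  # reverse footprint must lie downstream
      len <- rs + rl - fs
      if (len > maxAmplicon) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = fs, end = rs + rl - 1L, length = len,
        seq = substr(t, fs, rs + rl - 1L), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), seq = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Digest an amplicon with a restriction enzyme
#'
#' Cuts at every recognition match on either strand (palindromic sites once);
#' the cut coordinate is the top-strand cut position (`siteStart - 1 +
#' cutOffset` for plus-strand sites), since gel bands are double-stranded
#' lengths and overhang asymmetry is invisible on a gel. Overlapping matches
#' produce a cut at every distinct coordinate. Template `N` never satisfies a
#' recognition match.
#'
#' @param amplicon Ungapped sequence (character or `DNAString`).
#' @param enzyme A [RestrictionEnzyme-class].
#' @return A [BandPattern-class]; an uncut amplicon gives a single
#'   full-length band. Fragments always sum to the amplicon length.
#' @export
digest <- function(amplicon, enzyme) {
  a <- unname(.asSeqChar(amplicon)[1])
  n <- nchar(a)
  L <- nchar(enzyme@recognition)
  off <- enzyme@cutOffset
  cuts <- matchIUPAC(enzyme@recognition, a, forbidN = TRUE) - 1L + off
  if (!enzyme@palindromic) {
    # recognition on the bottom strand: its cut, projected to top coordinates
    cuts <- c(cuts,
              matchIUPAC(revcomp(enzyme@recognition), a, forbidN = TRUE) -
                1L + (L - off))
  }
  cuts <- sort(unique(cuts[cuts > 0L & cuts < n]))
  BandPattern(diff(c(0L, cuts, n)))
}

#' Predict per-genotype band patterns for a CAPS assay
#'
#' XX samples carry only the X amplicon; XY samples carry both, so their
#' lane is the multiset union of both digests. Monoecious individuals are XX
#' and are treated as such. An assay with no X amplicon is invalid — the
#' common-primer contract (one primer pair amplifying both alleles) is
#' broken.
#'
#' @param xAmplicon X-allele amplicon sequence (required).
#' @param yAmplicon Y-allele amplicon sequence, or `NULL` if the genotype
#'   lacks a Y copy.
#' @param enzyme A [RestrictionEnzyme-class].
#' @return `list(XX, XY, diagnostic)`: two [BandPattern-class] objects with
#'   genotype calls filled in, and a flag that is `FALSE` when the two
#'   patterns are indistinguishable on a gel (same set of band sizes).
#' @export
predictGenotypeBands <- function(xAmplicon, yAmplicon, enzyme) {
  if (is.null(xAmplicon) || !nzchar(.asSeqChar(xAmplicon)[1]))
    stop("assay invalid: no X amplicon (common-primer contract broken)")
  dx <- digest(xAmplicon, enzyme)
  xy <- if (is.null(yAmplicon)) bands(dx)
        else c(bands(dx), bands(digest(yAmplicon, enzyme)))
  XX <- BandPattern(bands(dx), "XX")
  XY <- BandPattern(xy, "XY")
  list(XX = XX, XY = XY,
       diagnostic = !setequal(unique(bands(XX)), unique(bands(XY))))
}

.bandsMatch <- function(observed, expected, tol) {
  # gel semantics: multiplicities collapse; mutual coverage within tolerance
  obs <- unique(observed); exp <- unique(expected)
  all(vapply(exp, function(b) any(abs(obs - b) <= tol), logical(1))) &&
    all(vapply(obs, function(b) any(abs(exp - b) <= tol), logical(1)))
}

#' Call a genotype from an observed band pattern
#'
#' Formalises gel reading: a lane is called XY when it shows the full
#' predicted XY pattern (digestion products plus the uncut full-length band)
#' within `toleranceBp`, XX when it shows only the full-length pattern, and
#' ambiguous otherwise (including when the candidate is non-diagnostic).
#'
#' @param observed Numeric vector of observed band sizes (bp).
#' @param candidate A [CapsCandidate-class], or a list with `XX`/`XY`
#'   [BandPattern-class] entries as from [predictGenotypeBands()].
#' @param toleranceBp Band-size matching tolerance; default 10 bp, the
#'   practical resolution of a standard agarose gel.
#' @return `"XX"`, `"XY"` or `"ambiguous"`.
#' @export
callGenotype <- function(observed, candidate, toleranceBp = 10) {
  if (length(observed) == 0L) stop("no observed bands")
  pats <- if (is(candidate, "CapsCandidate")) candidate@predictedBands
          else candidate
  mXX <- .bandsMatch(observed, bands(pats$XX), toleranceBp)
  mXY <- .bandsMatch(observed, bands(pats$XY), toleranceBp)
  if (mXY && !mXX) "XY" else if (mXX && !mXY) "XX" else "ambiguous"
}

#' Simulate a TaqMan allelic-discrimination read-out
#'
#' Endpoint logic only: a dye fires iff its probe matches an allele present
#' in the genotype with zero mismatches (either strand). The probe for the
#' site-carrying (Y) allele reports FAM, the other (X) probe reports VIC, so
#' XX samples give only VIC, XY samples give VIC and FAM, and no-template
#' controls give nothing.
#'
#' @param genotype `"XX"`, `"XY"` or `"NTC"` (no template).
#' @param probes Named character vector or list with `cut` (FAM, Y allele)
#'   and `uncut` (VIC, X allele), as from [designAlleleProbes()].
#' @param xSeq,ySeq The allele sequences (amplicon or gene region).
#' @return Character vector: subset of `c("VIC", "FAM")`.
#' @export
simulateTaqman <- function(genotype, probes, xSeq, ySeq) {
  genotype <- match.arg(genotype, c("XX", "XY", "NTC"))
  x <- unname(.asSeqChar(xSeq)[1]); y <- unname(.asSeqChar(ySeq)[1])
  binds <- function(probe, s) {
    length(matchIUPAC(probe, s)) > 0L ||
      length(matchIUPAC(revcomp(probe), s)) > 0L
  }
  cut <- probes[["cut"]]; uncut <- probes[["uncut"]]
  if (!binds(cut, x) && !binds(cut, y))
    stop("design invariant violation: 'cut' probe matches neither allele")
  if (!binds(uncut, x) && !binds(uncut, y))
    stop("design invariant violation: 'uncut' probe matches neither allele")
  present <- switch(genotype, XX = list(x), XY = list(x, y), NTC = list())
  fires <- function(probe) any(vapply(present, function(s) binds(probe, s),
                                      logical(1)))
  out <- character(0)
  if (length(present) && fires(uncut)) out <- c(out, "VIC")
  if (length(present) && fires(cut)) out <- c(out, "FAM")
  out
}
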