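# CAPS marker design: scan a gametolog alignment for allele-differential
# restriction sites, find conserved primer windows around them, build
# degenerate common primers and allele-specific probes, and rank the
# resulting candidates.

.alignmentRows <- function(gal) {
  rows <- c(X = gal@xRow, Y = gal@yRow, gal@extraRows)
  do.call(rbind, strsplit(rows, "", fixed = TRUE))
}

# column index for each ungapped position of a row
.colOfPos <- function(map) which(!is.na(map))

#' Scan a gametolog alignment for allele-differential restriction sites
#'
#' For every enzyme (both strands; palindromic recognitions are scanned once)
#' and both alleles, reports each recognition match present in one allele
#' whose homologous context in the other allele is match-free. The context is
#' the other allele's ungapped sequence spanning the site's alignment columns
#' extended by `|recognition| - 1` columns on each side, so a site merely
#' shifted by an indel cannot masquerade as differential. Template `N` never
#' satisfies a recognition match.
#'
#' @param gal A [GametologAlignment-class].
#' @param enzymes List of [RestrictionEnzyme-class] (e.g. [defaultEnzymes()]).
#' @return List of [DifferentialSite-class], ordered by enzyme, allele,
#'   position.
#' @export
scanDifferentialSites <- function(gal, enzymes) {
  if (length(enzymes) == 0L) stop("empty enzyme table")
  if (is(enzymes, "RestrictionEnzyme")) enzymes <- list(enzymes)
  ncols <- alignmentLength(gal)
  seqs <- c(X = xSeq(gal), Y = ySeq(gal))
  maps <- list(X = gal@xMap, Y = gal@yMap)
  colOf <- lapply(maps, .colOfPos)

  out <- list()
  for (enz in enzymes) {
    L <- nchar(enz@recognition)
    pats <- list("+" = enz@recognition)
    if (!enz@palindromic) pats[["-"]] <- revcomp(enz@recognition)
    for (allele in c("X", "Y")) {
      other <- if (allele == "X") "Y" else "X"
      for (strand in names(pats)) {
        starts <- matchIUPAC(pats[[strand]], seqs[[allele]], forbidN = TRUE)
        for (p in starts) {
          cols <- colOf[[allele]][p:(p + L - 1L)]
          c1 <- max(1L, min(cols) - (L - 1L))
          c2 <- min(ncols, max(cols) + (L - 1L))
          posOther <- maps[[other]][c1:c2]
          posOther <- posOther[!is.na(posOther)]
          ctx <- if (length(posOther))
            substr(seqs[[other]], min(posOther), max(posOther)) else ""
          hasMatch <- any(vapply(pats, function(pp) {
            length(matchIUPAC(pp, ctx, forbidN = TRUE)) > 0L
          }, logical(1)))
          if (!hasMatch) {
            out[[length(out) + 1L]] <- new("DifferentialSite",
              enzyme = enz, alleleWithSite = allele,
              siteStart = as.integer(p), alignmentColumn = as.integer(cols[1]),
              strand = strand)
          }
        }
      }
    }
  }
  out
}

#' Default conserved-flank search parameters
#'
#' @param primerLen Window length searched for on each side (nt).
#' @param maxPoly Maximum substitution (polymorphic) columns tolerated per
#'   window; such columns become degenerate bases in the primer.
#' @param maxDistance Maximum distance (columns) between the site and a
#'   window, keeping amplicons gel-friendly.
#' @return Named list.
#' @export
flankConfig <- function(primerLen = 20, maxPoly = 3, maxDistance = 400) {
  list(primerLen = as.integer(primerLen), maxPoly = as.integer(maxPoly),
       maxDistance = as.integer(maxDistance))
}

#' Find conserved windows flanking an alignment column range
#'
#' Searches outward from the site for the nearest window of `primerLen`
#' columns on each side containing no indel columns and at most `maxPoly`
#' polymorphic columns (over all alignment rows, extra cultivars included).
#'
#' @param gal A [GametologAlignment-class].
#' @param columns Integer: the site's alignment column(s); a scalar or
#'   `c(start, end)`.
#' @param flankCfg See [flankConfig()].
#' @return `list(left = c(start, end), right = c(start, end))` of alignment
#'   columns, or `NULL` when no pair of windows exists.
#' @export
findConservedFlanks <- function(gal, columns, flankCfg = flankConfig()) {
  n <- alignmentLength(gal)
  colStart <- min(columns); colEnd <- max(columns)
  if (colStart < 1L || colEnd > n) stop("site columns outside alignment")
  rows <- .alignmentRows(gal)
  isIndel <- apply(rows == "-", 2L, any)
  nDistinct <- apply(rows, 2L, function(col) length(unique(col)))
  isPoly <- !isIndel & nDistinct > 1L
  Lw <- flankCfg$primerLen

  windowOk <- function(s, e) {
    !any(isIndel[s:e]) && sum(isPoly[s:e]) <= flankCfg$maxPoly
  }
  left <- NULL
  lo <- max(Lw, colStart - flankCfg$maxDistance)
  if (colStart - 1L >= lo) {
    for (e in seq(colStart - 1L, lo, by = -1L)) {
      s <- e - Lw + 1L
      if (windowOk(s, e)) { left <- c(s, e); break }
    }
  }
  right <- NULL
  if (colEnd + 1L <= n - Lw + 1L) {
    for (s in seq(colEnd + 1L, min(n - Lw + 1L, colEnd + flankCfg$maxDistance))) {
      e <- s + Lw - 1L
      if (windowOk(s, e)) { right <- c(s, e); break }
    }
  }
  if (is.null(left) || is.null(right)) return(NULL)
  list(left = as.integer(left), right = as.integer(right))
}

#' Default primer design parameters
#'
#' @param minLen,maxLen Primer length bounds (nt).
#' @param maxDegeneracy Cap on the product of per-base IUPAC set sizes.
#' @param tmRange Acceptable Wallace-rule Tm window (deg C); deliberately wide
#'   — degeneracy and 3' anchoring are the binding constraints, annealing
#'   temperature is tuned at the bench.
#' @return Named list.
#' @export
primerConfig <- function(minLen = 18, maxLen = 25, maxDegeneracy = 16,
                         tmRange = c(45, 72)) {
  list(minLen = as.integer(minLen), maxLen = as.integer(maxLen),
       maxDegeneracy = as.integer(maxDegeneracy), tmRange = tmRange)
}

.windowConsensus <- function(rows, cols) {
  vapply(cols, function(j) consensusIUPAC(rows[, j]), character(1))
}

.makePrimer <- function(consChars, colsAbs, strand, cfg) {
  # consChars: consensus IUPAC letters of the window; colsAbs: their columns.
  # The 3' end faces the site: window right edge for "+", left edge for "-".
  n <- length(consChars)
  ends <- if (strand == "+") seq(n, cfg$minLen) else seq(1L, n - cfg$minLen + 1L)
  for (anchor in ends) {
    if (!consChars[anchor] %in% c("A", "C", "G", "T")) next
    avail <- if (strand == "+") anchor else n - anchor + 1L
    for (len in seq(min(cfg$maxLen, avail), cfg$minLen)) {
      idx <- if (strand == "+") (anchor - len + 1L):anchor
             else anchor:(anchor + len - 1L)
      foot <- paste(consChars[idx], collapse = "")
      primer <- if (strand == "+") foot else revcomp(foot)
      dg <- degeneracy(primer)
      tm <- .wallaceTm(primer)
      if (dg <= cfg$maxDegeneracy &&
          tm >= cfg$tmRange[1] && tm <= cfg$tmRange[2]) {
        return(new("DegeneratePrimer", seq = primer, strand = strand,
                   bindingColumns = as.integer(range(colsAbs[idx])),
                   degeneracy = dg, tmEstimate = tm))
      }
    }
  }
  NULL
}

#' Design a degenerate common primer pair from conserved windows
#'
#' Each primer is the per-column consensus over all alignment rows, with
#' polymorphic columns encoded as the minimal covering IUPAC code, so one
#' primer pair binds every allele and cultivar in the alignment. The reverse
#' primer is reverse-complemented. Within each window the longest sub-window
#' (between `minLen` and `maxLen`) satisfying the degeneracy cap and Tm range
#' is chosen, with the 3'-terminal base (the site-facing end) forced
#' non-degenerate by shifting when needed.
#'
#' @param gal A [GametologAlignment-class].
#' @param windows From [findConservedFlanks()].
#' @param cfg See [primerConfig()].
#' @return `list(fwd, rev)` of [DegeneratePrimer-class].
#' @export
designDegeneratePrimers <- function(gal, windows, cfg = primerConfig()) {
  if (is.null(windows)) stop("primer design failed: no conserved flanks")
  rows <- .alignmentRows(gal)
  lcols <- windows$left[1]:windows$left[2]
  rcols <- windows$right[1]:windows$right[2]
  fwd <- .makePrimer(.windowConsensus(rows, lcols), lcols, "+", cfg)
  if (is.null(fwd))
    stop("primer design failed: no forward sub-window satisfies ",
         "degeneracy/Tm/3' constraints")
  rev <- .makePrimer(.windowConsensus(rows, rcols), rcols, "-", cfg)
  if (is.null(rev))
    stop("primer design failed: no reverse sub-window satisfies ",
         "degeneracy/Tm/3' constraints")
  list(fwd = fwd, rev = rev)
}

#' Default allele-probe design parameters
#' @param probeLen Target probe length (nt).
#' @param minLen,maxLen Length bounds.
#' @param maxShift How far the window may be shifted off-centre to avoid
#'   indel columns.
#' @return Named list.
#' @export
probeConfig <- function(probeLen = 22, minLen = 15, maxLen = 25,
                        maxShift = 10) {
  list(probeLen = as.integer(probeLen), minLen = as.integer(minLen),
       maxLen = as.integer(maxLen), maxShift = as.integer(maxShift))
}

#' Design allele-specific probes over a differential site
#'
#' Two short oligos centred on the diagnostic columns (the alignment columns
#' where the recognition match differs between alleles): one matching the
#' site-carrying allele exactly, one matching the other allele exactly; each
#' mismatches the opposite allele at one or more diagnostic columns. In the
#' TaqMan adaptation the site-carrying (Y) probe is FAM-labelled and the
#' other (X) probe VIC-labelled.
#'
#' @param gal A [GametologAlignment-class].
#' @param site A [DifferentialSite-class] from [scanDifferentialSites()].
#' @param cfg See [probeConfig()].
#' @return `list(cut, uncut, windowColumns, diagnosticColumns)`: `cut` is the
#'   probe for the site-carrying allele.
#' @export
designAlleleProbes <- function(gal, site, cfg = probeConfig()) {
  n <- alignmentLength(gal)
  L <- nchar(site@enzyme@recognition)
  map <- if (site@alleleWithSite == "X") gal@xMap else gal@yMap
  colOf <- .colOfPos(map)
  cols <- colOf[site@siteStart:(site@siteStart + L - 1L)]
  diagCols <- cols[columnClasses(gal)[cols] != "identical"]
  diagCols <- diagCols[columnClasses(gal)[diagCols] == "substitution"]
  if (length(diagCols) == 0L)
    stop("probe design failed: no substitution column inside the site")
  xc <- .seqChars(gal@xRow); yc <- .seqChars(gal@yRow)
  isIndel <- xc == "-" | yc == "-"
  centre <- as.integer(round(mean(diagCols)))
  half <- cfg$probeLen %/% 2L

  for (shift in c(0L, as.vector(rbind(seq_len(cfg$maxShift),
                                      -seq_len(cfg$maxShift))))) {
    s <- centre - half + shift
    e <- s + cfg$probeLen - 1L
    if (s < 1L || e > n) next
    if (any(isIndel[s:e])) next
    if (!any(diagCols >= s & diagCols <= e)) next
    win <- s:e
    cut <- paste((if (site@alleleWithSite == "X") xc else yc)[win],
                 collapse = "")
    uncut <- paste((if (site@alleleWithSite == "X") yc else xc)[win],
                   collapse = "")
    if (identical(cut, uncut)) next
    return(list(cut = cut, uncut = uncut,
                windowColumns = c(s, e), diagnosticColumns = diagCols))
  }
  stop("probe design failed: alleles identical (or gapped) over all ",
       "feasible probe windows")
}

#' Rank CAPS candidates by assay practicality
#'
#' Score favours gel resolvability (larger minimum gap between distinct
#' predicted band sizes), lower total primer degeneracy, and shorter
#' amplicons. Deterministic: ties broken by enzyme name, allele and site
#' position.
#'
#' @param candidates List of [CapsCandidate-class].
#' @param weights Named numeric: `band_gap`, `degeneracy`, `amplicon`.
#' @return The list sorted best-first, with scores filled in.
#' @export
rankCandidates <- function(candidates,
                           weights = c(band_gap = 1, degeneracy = 2,
                                       amplicon = 0.01)) {
  if (length(candidates) == 0L) return(candidates)
  scored <- lapply(candidates, function(cc) {
    xy <- unique(bands(cc@predictedBands$XY))
    gap <- if (length(xy) > 1L) min(diff(sort(xy))) else 0
    cc@score <- weights[["band_gap"]] * gap -
      weights[["degeneracy"]] * (log2(cc@fwd@degeneracy) +
                                 log2(cc@rev@degeneracy)) -
      weights[["amplicon"]] * max(cc@ampliconLenX, cc@ampliconLenY)
    cc
  })
  ids <- vapply(scored, function(cc) {
    sprintf("%s_%s_%06d", cc@site@enzyme@name, cc@site@alleleWithSite,
            cc@site@siteStart)
  }, character(1))
  scores <- vapply(scored, function(cc) cc@score, numeric(1))
  scored[order(-scores, ids, method = "radix")]
}

#' Full CAPS design over a gametolog alignment
#'
#' Runs [scanDifferentialSites()], and for every differential site attempts
#' conserved flanks, degenerate primers, in-silico amplification of both
#' alleles, band prediction and allele probes; candidates whose predicted XX
#' and XY patterns are indistinguishable are dropped as non-diagnostic.
#'
#' @param gal A [GametologAlignment-class].
#' @param enzymes List of [RestrictionEnzyme-class].
#' @param flankCfg,primerCfg,probeCfg See the respective config constructors.
#' @param maxAmplicon Largest amplicon considered (bp).
#' @return List of [CapsCandidate-class], ranked best-first.
#' @export
designCapsCandidates <- function(gal, enzymes = defaultEnzymes(),
                                 flankCfg = flankConfig(),
                                 primerCfg = primerConfig(),
                                 probeCfg = probeConfig(),
                                 maxAmplicon = 2000) {
  sites <- scanDifferentialSites(gal, enzymes)
  xU <- xSeq(gal); yU <- ySeq(gal)
  out <- list()
  for (site in sites) {
    L <- nchar(site@enzyme@recognition)
    map <- if (site@alleleWithSite == "X") gal@xMap else gal@yMap
    cols <- .colOfPos(map)[site@siteStart:(site@siteStart + L - 1L)]
    windows <- findConservedFlanks(gal, range(cols), flankCfg)
    if (is.null(windows)) next
    primers <- tryCatch(designDegeneratePrimers(gal, windows, primerCfg),
                        error = function(e) NULL)
    if (is.null(primers)) next
    ampX <- insilicoPCR(xU, primers$fwd, primers$rev, maxAmplicon)
    ampY <- insilicoPCR(yU, primers$fwd, primers$rev, maxAmplicon)
    if (nrow(ampX) != 1L || nrow(ampY) != 1L) next
    # the differential site must sit inside the amplicon of its allele
    siteAmp <- if (site@alleleWithSite == "X") ampX else ampY
    if (site@siteStart < siteAmp$start[1] ||
        site@siteStart + L - 1L > siteAmp$end[1]) next
    pb <- predictGenotypeBands(ampX$seq[1], ampY$seq[1], site@enzyme)
    if (!pb$diagnostic) next
    probes <- tryCatch(designAlleleProbes(gal, site, probeCfg),
                       error = function(e) NULL)
    if (is.null(probes)) next
    out[[length(out) + 1L]] <- new("CapsCandidate", site = site,
      fwd = primers$fwd, rev = primers$rev,
      probes = c(cut = probes$cut, uncut = probes$uncut),
      ampliconLenX = nchar(ampX$seq[1]), ampliconLenY = nchar(ampY$seq[1]),
      predictedBands = list(XX = pb$XX, XY = pb$XY), score = NA_real_)
  }
  rankCandidates(out)
}
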