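# IUPAC nucleotide algebra: the shared primitive behind degenerate-primer
# design, restriction-site scanning and probe matching.

#' IUPAC nucleotide code expansions
#'
#' Named list mapping each one-letter IUPAC nucleotide code to the set of
#' unambiguous bases it stands for (e.g. `Y` = C/T, `M` = A/C, `N` = any).
#'
#' @format Named list of character vectors.
#' @export
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# bitmask encoding A=1 C=2 G=4 T=8; two codes are compatible iff masks overlap
.iupacMask <- vapply(IUPAC_SETS, function(b) {
  sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[b])
}, integer(1))

.maskToCode <- local({
  v <- character(15L)
  for (nm in names(.iupacMask)) v[.iupacMask[[nm]]] <- nm
  v
})

.checkIupac <- function(chars, allowGap = FALSE) {
  ok <- chars %in% names(.iupacMask)
  if (allowGap) ok <- ok | chars == "-"
  if (!all(ok)) {
    stop("non-IUPAC character(s): ",
         paste(unique(chars[!ok]), collapse = ", "), call. = FALSE)
  }
  invisible(chars)
}

.seqChars <- function(x) strsplit(toupper(as.character(x)), "", fixed = TRUE)[[1L]]

# coerce XString/XStringSet/character to a named character vector of sequences
.asSeqChar <- function(x) {
  if (is(x, "XStringSet") || is(x, "XString")) {
    x <- as.character(x)
  }
  if (!is.character(x)) stop("expected sequences as character or XStringSet")
  toupper(x)
}

#' Test whether two IUPAC codes are compatible
#'
#' Two codes match iff the base sets they stand for intersect; the relation is
#' symmetric. This is the matching notion used for degenerate primer and probe
#' binding.
#'
#' @param patternChar,baseChar Character vectors of single IUPAC codes
#'   (recycled to common length).
#' @return Logical vector.
#' @examples
#' iupacMatch("Y", "C")  # TRUE:  Y = {C,T}
#' iupacMatch("M", "G")  # FALSE: M = {A,C}
#' @export
iupacMatch <- function(patternChar, baseChar) {
  p <- toupper(patternChar); b <- toupper(baseChar)
  .checkIupac(p); .checkIupac(b)
  bitwAnd(.iupacMask[p], .iupacMask[b]) > 0L
}

#' Reverse complement of IUPAC strings
#'
#' IUPAC-aware reverse complement (`Y` <-> `R`, `M` <-> `K`, `W` -> `W`, ...).
#' Gap characters (`-`) are preserved, so gapped alignment rows can be
#' reverse-complemented in place.
#'
#' @param x Character vector of IUPAC strings (or an `XStringSet`).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("GAATTC")    # palindromic EcoRI site
#' revcomp("GGAYTATC")  # "GATARTCC"
#' @export
revcomp <- function(x) {
  x <- .asSeqChar(x)
  lapply(strsplit(x, "", fixed = TRUE), .checkIupac, allowGap = TRUE)
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Degeneracy of an IUPAC string
#'
#' Product over positions of the number of bases each code stands for; the
#' number of distinct plain-DNA oligos a degenerate primer mixes.
#'
#' @param x Character scalar (IUPAC string).
#' @return Integer degeneracy.
#' @examples
#' degeneracy("GGAYTATCATCCAGAGAMTG")  # 4
#' @export
degeneracy <- function(x) {
  chars <- .seqChars(x)
  .checkIupac(chars)
  as.integer(prod(lengths(IUPAC_SETS[chars])))
}

#' Minimal IUPAC code covering a set of bases
#'
#' @param bases Character vector of IUPAC codes observed in an alignment
#'   column; the result is the smallest code whose base set covers their union.
#' @return Single IUPAC letter.
#' @examples
#' consensusIUPAC(c("C", "T"))  # "Y"
#' @export
consensusIUPAC <- function(bases) {
  b <- toupper(bases)
  .checkIupac(b)
  .maskToCode[Reduce(bitwOr, .iupacMask[b])]
}

#' Expand a degenerate IUPAC string to all plain-DNA variants
#' @param x Character scalar.
#' @return Character vector of length `degeneracy(x)`.
#' @export
expandIUPAC <- function(x) {
  chars <- .seqChars(x)
  .checkIupac(chars)
  apply(expand.grid(IUPAC_SETS[chars], stringsAsFactors = FALSE), 1L,
        paste, collapse = "")
}

#' Find IUPAC-compatible matches of a pattern in a subject
#'
#' Slides `pattern` along `subject` and reports every start where all positions
#' are IUPAC-compatible. With `forbidN = TRUE` (the convention for restriction
#' site scanning) a subject window containing `N` never matches, so missing
#' template data cannot produce phantom sites.
#'
#' @param pattern,subject IUPAC strings.
#' @param forbidN Disallow `N` in the matched subject window.
#' @return Integer vector of 1-based start positions.
#' @export
matchIUPAC <- function(pattern, subject, forbidN = FALSE) {
  p <- .seqChars(pattern)
  s <- .seqChars(subject)
  .checkIupac(p); .checkIupac(s)
  np <- length(p); ns <- length(s)
  if (np == 0L || ns < np) return(integer(0))
  pm <- .iupacMask[p]
  sm <- .iupacMask[s]
  if (forbidN) sm[s == "N"] <- 0L
  ok <- rep(TRUE, ns - np + 1L)
  for (j in seq_len(np)) {
    ok <- ok & bitwAnd(sm[seq.int(j, ns - np + j)], pm[j]) > 0L
  }
  which(ok)
}

# Wallace-rule melting temperature, averaged over degenerate expansions:
# each position contributes the mean of 2 (A/T) or 4 (G/C) over its base set.
.wallaceTm <- function(x) {
  chars <- .seqChars(x)
  .checkIupac(chars)
  sum(vapply(IUPAC_SETS[chars], function(b) {
    mean(ifelse(b %in% c("G", "C"), 4, 2))
  }, numeric(1)))
}
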