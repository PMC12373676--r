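# Pairing candidate Y transcripts with their X-chromosome counterparts:
# local-alignment search with identity/coverage/ambiguity gates, global
# affine-gap alignment of accepted pairs, divergence ranking.

#' Default alignment scoring
#'
#' Match +2, mismatch -3, gap opening 10, gap extension 2 (a gap of length L
#' costs `open + L * ext`). The opening penalty is deliberately high relative
#' to the mismatch cost (as in classic Needleman-Wunsch defaults): gametolog
#' copies diverge mostly by substitution, and a cheap opening lets the
#' aligner rewrite short runs of substitutions — such as a diverged
#' restriction site — as an insertion/deletion pair, corrupting the
#' column-wise homology that site scanning and probe design rely on.
#' Deterministic for fixed inputs.
#'
#' @return Named list of scoring parameters.
#' @export
defaultScoring <- function() {
  list(match = 2, mismatch = -3, gapOpen = 10, gapExt = 2)
}

.submat <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                           mismatch = scoring$mismatch,
                                           baseOnly = FALSE)
}

#' Globally align an X/Y gametolog pair
#'
#' Needleman-Wunsch with affine gaps (Gotoh), via
#' `Biostrings::pairwiseAlignment`.
#'
#' @param xSeq,ySeq Ungapped IUPAC strings (or `DNAString`s).
#' @param scoring See [defaultScoring()].
#' @return A [GametologAlignment-class].
#' @export
alignPair <- function(xSeq, ySeq, scoring = defaultScoring()) {
  xchr <- unname(.asSeqChar(xSeq)[1]); ychr <- unname(.asSeqChar(ySeq)[1])
  if (!nzchar(xchr) || !nzchar(ychr)) stop("empty input sequence")
  aln <- Biostrings::pairwiseAlignment(xchr, ychr,
    substitutionMatrix = .submat(scoring),
    gapOpening = scoring$gapOpen, gapExtension = scoring$gapExt,
    type = "global")
  gal <- GametologAlignment(as.character(Biostrings::alignedPattern(aln)),
                            as.character(Biostrings::alignedSubject(aln)))
  # ungapping the rows must reproduce the inputs exactly
  stopifnot(identical(gsub("-", "", gal@xRow, fixed = TRUE), xchr),
            identical(gsub("-", "", gal@yRow, fixed = TRUE), ychr))
  gal
}

#' Global alignment score (used by the oracle tests)
#' @param a,b Ungapped strings.
#' @param scoring See [defaultScoring()].
#' @return Numeric optimal global alignment score.
#' @export
alignScore <- function(a, b, scoring = defaultScoring()) {
  BiocGenerics::score(Biostrings::pairwiseAlignment(.asSeqChar(a), .asSeqChar(b),
    substitutionMatrix = .submat(scoring),
    gapOpening = scoring$gapOpen, gapExtension = scoring$gapExt,
    type = "global"))
}

#' Find the X-chromosome counterpart of a candidate Y transcript
#'
#' Local-alignment search of the query against every candidate X locus.
#' The best hit is accepted only when it is near-identical
#' (`identity >= minIdentity`, `coverage >= minCoverage`) and unambiguous
#' (no secondary hit scoring within `maxSecondaryRatio` of the best).
#' A perfect full-coverage hit is rejected as `rejected_female_identical`:
#' a sequence identical to a female-genome locus carries no X/Y divergence
#' and cannot be Y-specific.
#'
#' @param ySeq Candidate Y sequence (named character scalar, or use `yId`).
#' @param xCandidates Candidate X loci (`DNAStringSet` or named character).
#' @param policy A [PairingPolicy-class].
#' @param scoring See [defaultScoring()].
#' @param yId Identifier of the query (defaults to the name of `ySeq`).
#' @return A [GametologPair-class]; accepted pairs carry the global alignment
#'   and its divergence.
#' @export
findCounterpart <- function(ySeq, xCandidates, policy = PairingPolicy(),
                            scoring = defaultScoring(), yId = NULL) {
  y <- .asSeqChar(ySeq)
  if (is.null(yId)) yId <- if (!is.null(names(y))) names(y)[1] else "query"
  y <- unname(y[1])
  if (!nzchar(y)) stop("empty query sequence")
  xs <- .asSeqChar(xCandidates)
  if (length(xs) == 0L) stop("no candidate X sequences")
  if (is.null(names(xs))) names(xs) <- paste0("x", seq_along(xs))

  mat <- .submat(scoring)
  hits <- lapply(xs, function(x) {
    aln <- Biostrings::pairwiseAlignment(y, x, substitutionMatrix = mat,
      gapOpening = scoring$gapOpen, gapExtension = scoring$gapExt,
      type = "local")
    pat <- as.character(Biostrings::alignedPattern(aln))
    sub <- as.character(Biostrings::alignedSubject(aln))
    pc <- .seqChars(pat); sc <- .seqChars(sub)
    ident <- if (length(pc)) sum(pc == sc & pc != "-") / length(pc) else 0
    ystart <- BiocGenerics::start(Biostrings::pattern(aln))
    yend <- BiocGenerics::end(Biostrings::pattern(aln))
    list(score = BiocGenerics::score(aln), identity = ident,
         coverage = (yend - ystart + 1) / nchar(y))
  })
  scores <- vapply(hits, `[[`, numeric(1), "score")
  bestIdx <- which.max(scores)
  best <- hits[[bestIdx]]
  bestId <- names(xs)[bestIdx]

  fail <- function(status) {
    new("GametologPair", yId = yId, xId = NA_character_, alignment = NULL,
        divergence = NA_real_, status = status)
  }
  if (best$score <= 0) return(fail("no_hit"))
  if (best$identity >= 1 - 1e-9 && best$coverage >= 1 - 1e-9)
    return(fail("rejected_female_identical"))
  if (length(scores) > 1L &&
      max(scores[-bestIdx]) >= policy@maxSecondaryRatio * best$score)
    return(fail("ambiguous_multi_hit"))
  if (best$identity < policy@minIdentity || best$coverage < policy@minCoverage)
    return(fail("no_hit"))

  gal <- alignPair(xs[[bestIdx]], y, scoring)
  new("GametologPair", yId = yId, xId = bestId, alignment = gal,
      divergence = divergence(gal), status = "accepted")
}

#' Rank accepted gametolog pairs by X/Y divergence
#'
#' The most diverged pairs are the most informative marker candidates:
#' divergence is what creates allele-differential restriction sites.
#' Descending by divergence; ties broken by `yId` lexicographically (C
#' collation) for determinism.
#'
#' @param pairs List of accepted [GametologPair-class] objects.
#' @return The list reordered.
#' @export
divergenceRank <- function(pairs) {
  if (length(pairs) == 0L) return(pairs)
  status <- vapply(pairs, function(p) p@status, character(1))
  if (any(status != "accepted"))
    stop("divergenceRank expects accepted pairs only")
  divs <- vapply(pairs, function(p) p@divergence, numeric(1))
  ids <- vapply(pairs, function(p) p@yId, character(1))
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  pairs[order(-divs, ids)]
}
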