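#' Fraction of diverged columns in a gametolog alignment
#'
#' Divergence is the number of non-identical alignment columns (substitutions
#' plus indel columns; each column counts once) divided by the alignment
#' length. `divergence(align(s, s)) == 0` and the measure is symmetric in the
#' two rows.
#'
#' @param x A [GametologAlignment-class] or [GametologPair-class].
#' @param indelWeight `"column"` (default: every indel column counts) or
#'   `"event"` (each gap run counts once).
#' @return Numeric fraction in `[0, 1]`.
#' @export
setGeneric("divergence", function(x, indelWeight = c("column", "event")) {
  standardGeneric("divergence")
})

#' @rdname divergence
#' @export
setMethod("divergence", "GametologAlignment", function(x, indelWeight = c("column", "event")) {
  indelWeight <- match.arg(indelWeight)
  cls <- x@columnClasses
  n <- length(cls)
  if (n == 0L) return(0)
  nsub <- sum(cls == "substitution")
  if (indelWeight == "column") {
    nindel <- sum(cls == "indel")
  } else {
    runs <- rle(cls == "indel")
    nindel <- sum(runs$values)
  }
  (nsub + nindel) / n
})

#' @rdname divergence
#' @export
setMethod("divergence", "GametologPair", function(x, indelWeight = c("column", "event")) {
  if (is.null(x@alignment)) return(NA_real_)
  divergence(x@alignment, indelWeight)
})

#' Pairing status of a GametologPair
#' @param x A [GametologPair-class].
#' @return Character status.
#' @export
pairStatus <- function(x) x@status
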