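# S4 classes for the marker-discovery pipeline. Sequences themselves live in
# Biostrings containers (DNAStringSet); these classes hold the assay-specific
# structure built on top of them.
#
# Coordinate convention: all positions and intervals are 1-based and closed
# (R / Biostrings style); restriction cut positions are expressed as the
# number of bases preceding the cut (EcoRI G^AATTC has cutOffset 1).

#' @import methods
NULL

# ---------------------------------------------------------------------------
# RestrictionEnzyme

#' Restriction enzyme with IUPAC recognition sequence
#'
#' @slot name Enzyme name, e.g. `"EcoRI"`.
#' @slot recognition IUPAC recognition sequence (length >= 4).
#' @slot cutOffset Top-strand cut position: number of bases between the start
#'   of the recognition sequence and the cut (0 to `nchar(recognition)`).
#' @slot palindromic Cached flag: recognition equals its own IUPAC reverse
#'   complement.
#' @export
setClass("RestrictionEnzyme",
  representation(name = "character", recognition = "character",
                 cutOffset = "integer", palindromic = "logical"))

setValidity("RestrictionEnzyme", function(object) {
  rec <- object@recognition
  msgs <- character(0)
  if (length(rec) != 1L || nchar(rec) < 4L)
    msgs <- c(msgs, "recognition sequence must be a single string of length >= 4")
  chars <- .seqChars(rec)
  if (!all(chars %in% names(.iupacMask)))
    msgs <- c(msgs, "recognition contains non-IUPAC characters")
  off <- object@cutOffset
  if (length(off) != 1L || is.na(off) || off < 0L || off > nchar(rec))
    msgs <- c(msgs, "cutOffset must lie in [0, nchar(recognition)]")
  if (length(msgs) == 0L &&
      !identical(object@palindromic, identical(rec, revcomp(rec))))
    msgs <- c(msgs, "palindromic flag inconsistent with recognition sequence")
  if (length(msgs)) msgs else TRUE
})

#' Construct a RestrictionEnzyme
#'
#' @param name Enzyme name.
#' @param recognition IUPAC recognition sequence.
#' @param cutOffset Top-strand cut offset from the recognition start
#'   (`G^AATTC` -> 1).
#' @return A [RestrictionEnzyme-class] object; the palindromy flag is derived.
#' @examples
#' RestrictionEnzyme("EcoRI", "GAATTC", 1)
#' @export
RestrictionEnzyme <- function(name, recognition, cutOffset) {
  recognition <- toupper(recognition)
  new("RestrictionEnzyme", name = as.character(name),
      recognition = recognition, cutOffset = as.integer(cutOffset),
      palindromic = identical(recognition, revcomp(recognition)))
}

setMethod("show", "RestrictionEnzyme", function(object) {
  rec <- object@recognition
  off <- object@cutOffset
  cut <- paste0(substr(rec, 1, off), "^", substr(rec, off + 1L, nchar(rec)))
  cat("RestrictionEnzyme ", object@name, ": 5'-", cut, "-3'",
      if (object@palindromic) " (palindromic)" else "", "\n", sep = "")
})

# ---------------------------------------------------------------------------
# FilterConfig / PairingPolicy

#' Thresholds for the k-mer sieve and expression filters
#'
#' @slot k k-mer length used by the comparative sieve.
#' @slot minMaleMeanTpm Minimum mean TPM over male samples (strict filter
#'   retains transcripts with mean strictly above this).
#' @slot maxFemaleTpm Maximum TPM allowed in any female sample (0 demands
#'   exact zeros).
#' @slot minLog2fc Minimum log2 fold change (male vs female) for the
#'   male-bias test.
#' @slot maxFdr Maximum Benjamini-Hochberg FDR for the male-bias test.
#' @slot pseudocount Added to both means before the log2 ratio so
#'   female-absent transcripts have a finite fold change.
#' @export
setClass("FilterConfig",
  representation(k = "integer", minMaleMeanTpm = "numeric",
                 maxFemaleTpm = "numeric", minLog2fc = "numeric",
                 maxFdr = "numeric", pseudocount = "numeric"))

setValidity("FilterConfig", function(object) {
  if (object@k < 4L) return("k must be >= 4")
  vals <- c(object@minMaleMeanTpm, object@maxFemaleTpm, object@minLog2fc,
            object@maxFdr, object@pseudocount)
  if (any(vals < 0)) return("thresholds must be non-negative")
  TRUE
})

#' @param k,minMaleMeanTpm,maxFemaleTpm,minLog2fc,maxFdr,pseudocount See slot
#'   documentation; defaults follow the published pipeline (16-mers, mean male
#'   TPM > 10, female TPM = 0, log2FC >= 1, FDR <= 0.05).
#' @return A [FilterConfig-class] object.
#' @rdname FilterConfig-class
#' @export
FilterConfig <- function(k = 16, minMaleMeanTpm = 10, maxFemaleTpm = 0,
                         minLog2fc = 1, maxFdr = 0.05, pseudocount = 1) {
  new("FilterConfig", k = as.integer(k), minMaleMeanTpm = minMaleMeanTpm,
      maxFemaleTpm = maxFemaleTpm, minLog2fc = minLog2fc, maxFdr = maxFdr,
      pseudocount = pseudocount)
}

#' Acceptance thresholds for X-counterpart search
#'
#' Quantifies "near-identical, single unambiguous hit": the best local hit
#' must reach `minIdentity` and `minCoverage`, and no secondary hit may score
#' within `maxSecondaryRatio` of the best.
#'
#' @slot minIdentity Minimum fractional identity of the best hit.
#' @slot minCoverage Minimum fraction of the query covered by the best hit.
#' @slot maxSecondaryRatio A secondary hit scoring above this fraction of the
#'   best score marks the query ambiguous.
#' @export
setClass("PairingPolicy",
  representation(minIdentity = "numeric", minCoverage = "numeric",
                 maxSecondaryRatio = "numeric"))

setValidity("PairingPolicy", function(object) {
  v <- c(object@minIdentity, object@minCoverage, object@maxSecondaryRatio)
  if (any(v <= 0 | v > 1)) return("policy fractions must lie in (0, 1]")
  TRUE
})

#' @param minIdentity,minCoverage,maxSecondaryRatio See slot documentation.
#' @return A [PairingPolicy-class] object.
#' @rdname PairingPolicy-class
#' @export
PairingPolicy <- function(minIdentity = 0.95, minCoverage = 0.90,
                          maxSecondaryRatio = 0.90) {
  new("PairingPolicy", minIdentity = minIdentity, minCoverage = minCoverage,
      maxSecondaryRatio = maxSecondaryRatio)
}

# ---------------------------------------------------------------------------
# GametologAlignment

#' Alignment of X and Y gametolog copies
#'
#' Holds the gapped X and Y rows (plus optional extra cultivar rows), a
#' per-column classification, and column-to-ungapped-position maps.
#'
#' @slot xRow,yRow Equal-length gapped IUPAC strings.
#' @slot extraRows Named character vector of additional aligned rows
#'   (e.g. other cultivars), all the same gapped length.
#' @slot columnClasses Per column one of `"identical"`, `"substitution"`,
#'   `"indel"` (X vs Y only).
#' @slot xMap,yMap Integer vectors: for each alignment column, the 1-based
#'   ungapped position in that row, or `NA` at gaps.
#' @export
setClass("GametologAlignment",
  representation(xRow = "character", yRow = "character",
                 extraRows = "character", columnClasses = "character",
                 xMap = "integer", yMap = "integer"))

setValidity("GametologAlignment", function(object) {
  n <- nchar(object@xRow)
  if (nchar(object@yRow) != n) return("rows differ in gapped length")
  if (length(object@extraRows) && any(nchar(object@extraRows) != n))
    return("extra rows differ in gapped length")
  if (length(object@columnClasses) != n ||
      length(object@xMap) != n || length(object@yMap) != n)
    return("column annotations must have one entry per alignment column")
  if (!all(object@columnClasses %in% c("identical", "substitution", "indel")))
    return("invalid column class")
  TRUE
})

.classifyColumns <- function(xc, yc) {
  cls <- rep("substitution", length(xc))
  cls[xc == "-" | yc == "-"] <- "indel"
  cls[xc == yc & xc != "-"] <- "identical"
  cls
}

.gapMap <- function(chars) {
  m <- rep(NA_integer_, length(chars))
  ng <- chars != "-"
  m[ng] <- seq_len(sum(ng))
  m
}

#' Construct a GametologAlignment from gapped rows
#'
#' @param xRow,yRow Gapped, equal-length IUPAC strings (X and Y copies).
#' @param extraRows Optional named character vector of further aligned rows.
#' @return A [GametologAlignment-class] object with derived column classes and
#'   coordinate maps.
#' @export
GametologAlignment <- function(xRow, yRow, extraRows = character(0)) {
  xRow <- toupper(as.character(xRow)); yRow <- toupper(as.character(yRow))
  extraRows <- vapply(extraRows, function(s) toupper(as.character(s)),
                      character(1))
  xc <- .seqChars(xRow); yc <- .seqChars(yRow)
  .checkIupac(xc, allowGap = TRUE); .checkIupac(yc, allowGap = TRUE)
  if (length(xc) != length(yc)) stop("alignment rows differ in length")
  if (any(xc == "-" & yc == "-")) stop("all-gap column in X/Y alignment")
  new("GametologAlignment", xRow = xRow, yRow = yRow, extraRows = extraRows,
      columnClasses = .classifyColumns(xc, yc),
      xMap = .gapMap(xc), yMap = .gapMap(yc))
}

#' @describeIn GametologAlignment-class Number of alignment columns.
#' @param x,object A `GametologAlignment`.
#' @export
alignmentLength <- function(x) nchar(x@xRow)

#' @describeIn GametologAlignment-class Ungapped X sequence.
#' @export
xSeq <- function(x) gsub("-", "", x@xRow, fixed = TRUE)

#' @describeIn GametologAlignment-class Ungapped Y sequence.
#' @export
ySeq <- function(x) gsub("-", "", x@yRow, fixed = TRUE)

#' @describeIn GametologAlignment-class Per-column classes (X vs Y).
#' @export
columnClasses <- function(x) x@columnClasses

setMethod("show", "GametologAlignment", function(object) {
  tab <- table(factor(object@columnClasses,
                      levels = c("identical", "substitution", "indel")))
  cat("GametologAlignment: ", alignmentLength(object), " columns (",
      tab[["identical"]], " identical, ", tab[["substitution"]],
      " substitution, ", tab[["indel"]], " indel)",
      if (length(object@extraRows))
        paste0("; ", length(object@extraRows), " extra row(s)") else "",
      "\n  divergence: ", format(divergence(object), digits = 4), "\n",
      sep = "")
})

# ---------------------------------------------------------------------------
# BandPattern

#' Gel band pattern
#'
#' Multiset of restriction-fragment lengths with an optional genotype call.
#'
#' @slot bands Sorted integer fragment lengths (bp).
#' @slot genotypeCall `"XX"`, `"XY"`, `"ambiguous"` or `NA`.
#' @export
setClass("BandPattern",
  representation(bands = "integer", genotypeCall = "character"))

setValidity("BandPattern", function(object) {
  if (any(object@bands < 1L)) return("band lengths must be >= 1 bp")
  if (is.unsorted(object@bands)) return("bands must be sorted ascending")
  gc <- object@genotypeCall
  if (length(gc) != 1L || !(is.na(gc) || gc %in% c("XX", "XY", "ambiguous")))
    return("genotypeCall must be XX, XY, ambiguous or NA")
  TRUE
})

#' Construct a BandPattern
#' @param bands Numeric fragment lengths in bp (sorted internally).
#' @param genotypeCall Optional genotype call.
#' @return A [BandPattern-class] object.
#' @export
BandPattern <- function(bands, genotypeCall = NA_character_) {
  new("BandPattern", bands = sort(as.integer(bands)),
      genotypeCall = as.character(genotypeCall))
}

#' @describeIn BandPattern-class Fragment lengths (sorted, bp).
#' @param x A `BandPattern`.
#' @export
bands <- function(x) x@bands

#' @describeIn BandPattern-class Genotype call stored with the pattern.
#' @export
genotypeCall <- function(x) x@genotypeCall

setMethod("show", "BandPattern", function(object) {
  cat("BandPattern: {", paste(object@bands, collapse = ", "), "} bp",
      if (!is.na(object@genotypeCall))
        paste0(" [", object@genotypeCall, "]") else "", "\n", sep = "")
})

# ---------------------------------------------------------------------------
# GametologPair

setClassUnion("GametologAlignmentOrNULL", c("GametologAlignment", "NULL"))

#' A candidate Y transcript paired with its X counterpart
#'
#' @slot yId,xId Sequence identifiers (`xId` is `NA` when no hit was accepted).
#' @slot alignment Global [GametologAlignment-class] of the pair, or `NULL`.
#' @slot divergence Fraction of non-identical alignment columns, or `NA`.
#' @slot status One of `"accepted"`, `"ambiguous_multi_hit"`,
#'   `"rejected_female_identical"`, `"no_hit"`.
#' @export
setClass("GametologPair",
  representation(yId = "character", xId = "character",
                 alignment = "GametologAlignmentOrNULL",
                 divergence = "numeric", status = "character"))

setValidity("GametologPair", function(object) {
  if (!object@status %in% c("accepted", "ambiguous_multi_hit",
                            "rejected_female_identical", "no_hit"))
    return("invalid pairing status")
  if (object@status == "accepted" && is.null(object@alignment))
    return("accepted pair must carry an alignment")
  TRUE
})

setMethod("show", "GametologPair", function(object) {
  cat("GametologPair: ", object@yId, " ~ ",
      ifelse(is.na(object@xId), "<none>", object@xId),
      " [", object@status, "]",
      if (!is.na(object@divergence))
        paste0(", divergence ", format(object@divergence, digits = 4)) else "",
      "\n", sep = "")
})

# ---------------------------------------------------------------------------
# SampleKmerProfile

#' Per-sample k-mer presence profile
#'
#' @slot sampleId Sample identifier.
#' @slot sex `"male"` or `"female"`.
#' @slot k k-mer length.
#' @slot kmers Character vector (set) of distinct A/C/G/T k-mers.
#' @export
setClass("SampleKmerProfile",
  representation(sampleId = "character", sex = "character", k = "integer",
                 kmers = "character"))

setValidity("SampleKmerProfile", function(object) {
  if (!object@sex %in% c("male", "female"))
    return("sex must be 'male' or 'female'")
  if (length(object@kmers) && any(nchar(object@kmers) != object@k))
    return("k-mer lengths inconsistent with k")
  if (length(object@kmers) && any(grepl("[^ACGT]", object@kmers)))
    return("k-mers must be over {A,C,G,T}")
  TRUE
})

setMethod("show", "SampleKmerProfile", function(object) {
  cat("SampleKmerProfile ", object@sampleId, " (", object@sex, "): ",
      length(object@kmers), " distinct ", object@k, "-mers\n", sep = "")
})

# ---------------------------------------------------------------------------
# DifferentialSite / DegeneratePrimer / CapsCandidate

#' Allele-differential restriction site
#'
#' A recognition-site match present in exactly one of the two gametolog
#' copies, absent from the homologous context of the other.
#'
#' @slot enzyme The [RestrictionEnzyme-class].
#' @slot alleleWithSite `"X"` or `"Y"`.
#' @slot siteStart 1-based ungapped start of the match in the carrying allele.
#' @slot alignmentColumn 1-based alignment column of the match start.
#' @slot strand `"+"` or `"-"` (palindromic sites are reported on `"+"`).
#' @export
setClass("DifferentialSite",
  representation(enzyme = "RestrictionEnzyme", alleleWithSite = "character",
                 siteStart = "integer", alignmentColumn = "integer",
                 strand = "character"))

setMethod("show", "DifferentialSite", function(object) {
  cat("DifferentialSite: ", object@enzyme@name, " on ", object@alleleWithSite,
      " allele at ", object@siteStart, " (column ", object@alignmentColumn,
      ", strand ", object@strand, ")\n", sep = "")
})

#' Degenerate common primer
#'
#' @slot seq IUPAC primer sequence, written 5'->3'.
#' @slot strand `"+"` (forward) or `"-"` (reverse).
#' @slot bindingColumns Integer `c(start, end)` alignment columns of the
#'   plus-strand footprint (1-based, closed).
#' @slot degeneracy Product of per-base IUPAC set sizes.
#' @slot tmEstimate Wallace-rule melting temperature averaged over degenerate
#'   expansions (deg C).
#' @export
setClass("DegeneratePrimer",
  representation(seq = "character", strand = "character",
                 bindingColumns = "integer", degeneracy = "integer",
                 tmEstimate = "numeric"))

setMethod("show", "DegeneratePrimer", function(object) {
  cat("DegeneratePrimer (", object@strand, "): 5'-", object@seq,
      "-3' | degeneracy ", object@degeneracy, ", Tm ~",
      round(object@tmEstimate, 1), " C, columns ",
      object@bindingColumns[1], "-", object@bindingColumns[2], "\n", sep = "")
})

#' A complete CAPS marker candidate
#'
#' Differential restriction site plus common primer pair, allele-specific
#' probes and the band patterns each genotype is predicted to show on a gel.
#'
#' @slot site The [DifferentialSite-class].
#' @slot fwd,rev [DegeneratePrimer-class] pair.
#' @slot probes Named character vector with elements `cut` (probe matching the
#'   site-carrying allele) and `uncut`.
#' @slot ampliconLenX,ampliconLenY Predicted amplicon lengths (bp).
#' @slot predictedBands Named list of [BandPattern-class] for genotypes
#'   `XX` and `XY`.
#' @slot score Ranking score (higher is better).
#' @export
setClass("CapsCandidate",
  representation(site = "DifferentialSite", fwd = "DegeneratePrimer",
                 rev = "DegeneratePrimer", probes = "character",
                 ampliconLenX = "integer", ampliconLenY = "integer",
                 predictedBands = "list", score = "numeric"))

setValidity("CapsCandidate", function(object) {
  pb <- object@predictedBands
  if (!all(c("XX", "XY") %in% names(pb)))
    return("predictedBands must contain XX and XY patterns")
  if (!is(pb$XX, "BandPattern") || !is(pb$XY, "BandPattern"))
    return("predictedBands entries must be BandPattern objects")
  TRUE
})

setMethod("show", "CapsCandidate", function(object) {
  cat("CapsCandidate: ", object@site@enzyme@name, " site on ",
      object@site@alleleWithSite, " allele (position ",
      object@site@siteStart, ")\n", sep = "")
  cat("  fwd 5'-", object@fwd@seq, "-3'  rev 5'-", object@rev@seq, "-3'\n",
      sep = "")
  cat("  amplicons: X ", object@ampliconLenX, " bp, Y ", object@ampliconLenY,
      " bp\n", sep = "")
  cat("  predicted XX {", paste(bands(object@predictedBands$XX),
                                collapse = ", "),
      "}  XY {", paste(bands(object@predictedBands$XY), collapse = ", "),
      "}\n", sep = "")
})
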