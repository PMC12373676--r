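# Seeded synthetic-data generators with planted ground truth. These emulate
# the pipeline's study conditions — gametolog pairs with a planted
# allele-differential restriction site flanked by conserved primer windows,
# male/female sample cohorts differing by the presence of the Y allele, and
# TPM tables where Y transcripts are male-only — so every stage is testable
# without external data. All generators are pure functions of their
# arguments, seed included.

.BASES <- c("A", "C", "G", "T")

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

.randSeq <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

.mutateBase <- function(base) sample(setdiff(.BASES, base), 1L)

# substitute characters at given positions of a string
.substitute <- function(s, pos, chars) {
  v <- .seqChars(s)
  v[pos] <- chars
  paste(v, collapse = "")
}

# remove every accidental recognition match (either strand) outside `keep`
# by mutating the middle base of the offending window
.scrubSites <- function(s, enzyme, keep = integer(0)) {
  L <- nchar(enzyme@recognition)
  pats <- unique(c(enzyme@recognition, revcomp(enzyme@recognition)))
  for (iter in 1:50) {
    starts <- sort(unique(unlist(lapply(pats, matchIUPAC, subject = s))))
    starts <- setdiff(starts, keep)
    if (length(starts) == 0L) return(s)
    p <- starts[1] + L %/% 2L
    s <- .substitute(s, p, .mutateBase(substr(s, p, p)))
  }
  stop("could not scrub accidental recognition sites")
}

#' Generate a synthetic gametolog pair with a planted differential site
#'
#' A random ancestor is diverged into X and Y copies by substitutions at the
#' stated rate; one concrete instance of the enzyme's recognition sequence is
#' planted in the Y copy and ablated base-by-base in the X copy at the
#' homologous position (so every site column differs between alleles), and
#' two mutation-free windows of `primerLen` bases are reserved on each side
#' of the site at `flankGap` bases distance. Accidental recognition matches
#' elsewhere are scrubbed. Substitution-only by default so coordinates are
#' shared between the copies; `indelRate > 0` additionally deletes short
#' stretches from one copy for alignment stress-testing.
#'
#' @param length Total sequence length (>= 300).
#' @param divergence Per-column substitution probability between the copies
#'   (0 to 0.3); default 0.02, typical of gametologs in an old stratum that
#'   still share a conserved assay region.
#' @param enzyme A [RestrictionEnzyme-class]; default EcoRI.
#' @param seed Integer seed; same seed, same output, bit for bit.
#' @param primerLen,flankGap Conserved-window geometry (nt).
#' @param indelRate Per-column probability of opening a short deletion in one
#'   copy (default 0, keeping the pair gap-free).
#' @return `list(x, y, truth)`: two ungapped sequences and a truth record
#'   with `sitePos` (1-based start of the planted site in the Y copy),
#'   `siteLength`, `windows` (`left`/`right`, 1-based closed), `enzyme` and
#'   the requested `divergence`.
#' @export
generateGametologPair <- function(length = 2000, divergence = 0.02,
                                  enzyme = RestrictionEnzyme("EcoRI", "GAATTC", 1),
                                  seed = 1, primerLen = 20, flankGap = 120,
                                  indelRate = 0) {
  if (length < 300) stop("length must be >= 300")
  if (divergence < 0 || divergence > 0.3)
    stop("divergence must lie in [0, 0.3]")
  length <- as.integer(length)
  primerLen <- as.integer(primerLen)
  flankGap <- as.integer(flankGap)
  L <- nchar(enzyme@recognition)
  p <- length %/% 2L
  left <- c(p - flankGap - primerLen, p - flankGap - 1L)
  right <- c(p + L + flankGap, p + L + flankGap + primerLen - 1L)
  if (left[1] < 1L || right[2] > length)
    stop("site plus conserved windows exceed the sequence length")
  protected <- c(p:(p + L - 1L), left[1]:left[2], right[1]:right[2])

  .withSeed(seed, {
    anc <- .randSeq(length)
    x <- y <- .seqChars(anc)
    recChars <- .seqChars(enzyme@recognition)
    for (i in seq_len(L)) {
      ySet <- IUPAC_SETS[[recChars[i]]]
      yBase <- if (length(ySet) == 1L) ySet else sample(ySet, 1L)
      avoid <- setdiff(.BASES, union(ySet, yBase))
      if (length(avoid) == 0L) avoid <- setdiff(.BASES, yBase)
      xBase <- if (length(avoid) == 1L) avoid else sample(avoid, 1L)
      y[p + i - 1L] <- yBase
      x[p + i - 1L] <- xBase
    }
    free <- setdiff(seq_len(length), protected)
    hit <- free[stats::runif(base::length(free)) < divergence]
    for (q in hit) {
      if (stats::runif(1) < 0.5) x[q] <- .mutateBase(x[q])
      else y[q] <- .mutateBase(y[q])
    }
    if (indelRate > 0) {
      nDel <- stats::rbinom(1L, base::length(free), indelRate)
      delStarts <- sample(free, nDel)
      for (q in delStarts) {
        span <- q:min(q + sample(1:3, 1L) - 1L, length)
        span <- setdiff(span, protected)
        if (stats::runif(1) < 0.5) x[span] <- "" else y[span] <- ""
      }
    }
    xs <- paste(x, collapse = ""); ys <- paste(y, collapse = "")
    ys <- .scrubSites(ys, enzyme, keep = p)
    xs <- .scrubSites(xs, enzyme)
    stopifnot(identical(matchIUPAC(enzyme@recognition, ys), as.integer(p)))
    list(x = xs, y = ys,
         truth = list(sitePos = p, siteLength = L,
                      windows = list(left = left, right = right),
                      enzyme = enzyme, divergence = divergence,
                      mutatedPositions = hit))
  })
}

.addSnps <- function(s, rate, protect = integer(0)) {
  v <- .seqChars(s)
  hit <- setdiff(which(stats::runif(length(v)) < rate), protect)
  for (q in hit) v[q] <- .mutateBase(v[q])
  paste(v, collapse = "")
}

#' Generate a male/female sample cohort with known truth
#'
#' Female samples carry the X-derived transcript and the autosomal decoys;
#' male samples additionally carry the Y-derived transcript. Each sample's
#' copies acquire private SNPs at `snpRate` (the planted diagnostic site is
#' exempt: a usable marker is by definition fixed within each sex). The TPM
#' table expresses the Y transcript only in males (mean well above 10, exact
#' zeros in females); decoys are expressed in both sexes, one of them
#' male-biased but female-nonzero — detectable by a fold-change filter but
#' correctly rejected by the strict presence/absence filter.
#'
#' @param pair Output of [generateGametologPair()].
#' @param nMale,nFemale Samples per sex (>= 1); defaults 3 and 3.
#' @param snpRate Per-base per-sample SNP probability; default 0.001.
#' @param nDecoys Autosomal decoy transcripts; default 20.
#' @param seed Integer seed.
#' @return `list(samples, sex, se, truth)`: named list of per-sample
#'   transcript sets (named character vectors), sample sex labels, the
#'   expression `SummarizedExperiment`, and the ground truth (`yTranscript`,
#'   `xTranscript`, `biasedDecoy`, plus the pair's planted truth).
#' @export
generateCohort <- function(pair, nMale = 3, nFemale = 3, snpRate = 0.001,
                           nDecoys = 20, seed = 1) {
  if (nMale < 1 || nFemale < 1) stop("need at least one sample per sex")
  tr <- pair$truth
  protect <- tr$sitePos:(tr$sitePos + tr$siteLength - 1L)
  .withSeed(seed + 1000L, {
    decoys <- vapply(seq_len(nDecoys), function(i) .randSeq(500L),
                     character(1))
    names(decoys) <- paste0("AUTO.t", seq_len(nDecoys))
    ids <- c(M = paste0("M", seq_len(nMale)), F = paste0("F", seq_len(nFemale)))
    sex <- stats::setNames(rep(c("male", "female"), c(nMale, nFemale)),
                           unname(ids))
    samples <- lapply(unname(ids), function(sid) {
      isMale <- sex[[sid]] == "male"
      base <- c(stats::setNames(pair$x, "X.t1"),
                if (isMale) stats::setNames(pair$y, "Y.t1"), decoys)
      vapply(names(base), function(nm) {
        .addSnps(base[[nm]], snpRate,
                 protect = if (nm %in% c("X.t1", "Y.t1")) protect
                           else integer(0))
      }, character(1))
    })
    names(samples) <- unname(ids)

    transcripts <- c("Y.t1", "X.t1", names(decoys))
    tpm <- matrix(0, nrow = length(transcripts), ncol = length(ids),
                  dimnames = list(transcripts, unname(ids)))
    male <- names(sex)[sex == "male"]; female <- names(sex)[sex == "female"]
    tpm["Y.t1", male] <- stats::rlnorm(nMale, log(50), 0.3)
    tpm["X.t1", ] <- stats::rlnorm(length(ids), log(30), 0.3)
    for (d in names(decoys))
      tpm[d, ] <- stats::rlnorm(length(ids), log(20), 0.5)
    tpm["AUTO.t1", male] <- stats::rlnorm(nMale, log(40), 0.3)
    tpm["AUTO.t1", female] <- stats::rlnorm(nFemale, log(5), 0.3)

    list(samples = samples, sex = sex, se = ExpressionTable(tpm, sex),
         truth = list(yTranscript = "Y.t1", xTranscript = "X.t1",
                      biasedDecoy = "AUTO.t1", pairTruth = tr))
  })
}
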