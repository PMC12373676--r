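# Independent brute-force oracles used to validate the package primitives.
# Each is written from the definition, not from the package implementation.

.ORACLE_BASES <- c("A", "C", "G", "T")

randDna <- function(n) {
  paste(sample(.ORACLE_BASES, n, replace = TRUE), collapse = "")
}

randIupac <- function(n, codes = names(IUPAC_SETS)) {
  paste(sample(codes, n, replace = TRUE), collapse = "")
}

# IUPAC compatibility straight from the set definition
oracleIupacMatch <- function(p, b) {
  length(intersect(IUPAC_SETS[[p]], IUPAC_SETS[[b]])) > 0L
}

# sliding-window IUPAC pattern match by per-position set intersection
oracleMatchStarts <- function(pattern, subject, forbidN = FALSE) {
  pc <- strsplit(pattern, "")[[1]]
  sc <- strsplit(subject, "")[[1]]
  np <- length(pc); ns <- length(sc)
  if (np == 0L || ns < np) return(integer(0))
  hits <- integer(0)
  for (s in seq_len(ns - np + 1L)) {
    win <- sc[s:(s + np - 1L)]
    if (forbidN && any(win == "N")) next
    ok <- all(vapply(seq_len(np), function(i) {
      oracleIupacMatch(pc[i], win[i])
    }, logical(1)))
    if (ok) hits <- c(hits, s)
  }
  hits
}

# all k-length substrings over {A,C,G,T} of a sequence, as a set
oracleKmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  km <- unique(vapply(seq_len(n - k + 1L), function(i) {
    substr(s, i, i + k - 1L)
  }, character(1)))
  km[!grepl("[^ACGT]", km)]
}

# independent affine-gap global alignment score (Gotoh), with the
# convention that a gap of length L costs open + L * ext.
# Row-vectorised dynamic programme; three-state recursion from first
# principles, no shared code with the package.
oracleGotoh <- function(a, b, match = 2, mismatch = -3, open = 10, ext = 2) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  NEG <- -1e15
  # rows indexed 0..m over b
  Mprev <- c(0, rep(NEG, m))
  Ixprev <- rep(NEG, m + 1L)
  Iyprev <- c(NEG, -(open + seq_len(m) * ext))
  for (i in seq_len(n)) {
    subScore <- ifelse(bc == ac[i], match, mismatch)
    diagBest <- pmax(Mprev, Ixprev, Iyprev)[seq_len(m)]
    Mcur <- c(NEG, diagBest + subScore)
    Ixcur <- pmax(Mprev - open - ext, Ixprev - ext)
    Ixcur[1] <- -(open + i * ext)
    # Iy[i, j] = max_{k < j} (M[i, k] - open - (j - k) * ext)
    jj <- 0:m
    t <- Mcur + jj * ext
    Iycur <- c(NEG, -open - jj[-1] * ext + cummax(t[seq_len(m)]))
    Mprev <- Mcur; Ixprev <- Ixcur; Iyprev <- Iycur
  }
  max(Mprev[m + 1L], Ixprev[m + 1L], Iyprev[m + 1L])
}

# digestion bands from the definition: cut after siteStart - 1 + offset for
# plus-strand matches; bottom-strand matches of non-palindromic enzymes cut
# after siteStart - 1 + (L - offset) in top-strand coordinates
oracleDigestBands <- function(s, recognition, cutOffset) {
  n <- nchar(s)
  L <- nchar(recognition)
  cuts <- oracleMatchStarts(recognition, s, forbidN = TRUE) - 1L + cutOffset
  rc <- revcomp(recognition)
  if (!identical(recognition, rc)) {
    cuts <- c(cuts,
              oracleMatchStarts(rc, s, forbidN = TRUE) - 1L + (L - cutOffset))
  }
  cuts <- sort(unique(cuts[cuts > 0L & cuts < n]))
  sort(diff(c(0L, cuts, n)))
}

# exact two-sided rank-sum p-value by full enumeration of group assignments
oracleRankSumP <- function(x, y) {
  all <- c(x, y)
  r <- rank(all)
  W <- sum(r[seq_along(x)])
  EW <- length(x) * (length(all) + 1) / 2
  combs <- utils::combn(length(all), length(x))
  Ws <- apply(combs, 2L, function(idx) sum(r[idx]))
  mean(abs(Ws - EW) >= abs(W - EW) - 1e-9)
}
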