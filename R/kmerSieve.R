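# Comparative k-mer sieve: keep transcripts carrying k-mers present in every
# male sample and absent from every female sample. Profiles are exact
# in-memory sets — the all-male/no-female predicate needs exactness, and the
# per-cohort scale (transcript sets, not raw reads) keeps them small.

.kmersOfSeq <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  km <- unique(substring(s, 1:(n - k + 1L), k:n))
  km[!grepl("[^ACGT]", km)]
}

#' Build a per-sample k-mer presence profile
#'
#' Collects every length-`k` substring of every record (and of its reverse
#' complement when `canonical = TRUE`, for unstranded input such as raw
#' reads). k-mers containing `N` or other ambiguity codes are dropped:
#' ambiguous positions are missing data, not evidence.
#'
#' @param records Sequences (`DNAStringSet` or named character vector).
#' @param k k-mer length (>= 4); default 16.
#' @param sex `"male"` or `"female"`.
#' @param sampleId Sample identifier.
#' @param canonical Also include k-mers of the reverse complements
#'   (default `FALSE`: transcripts are stranded).
#' @return A [SampleKmerProfile-class].
#' @export
buildKmerProfile <- function(records, k = 16, sex, sampleId,
                             canonical = FALSE) {
  k <- as.integer(k)
  if (k < 4L) stop("k must be >= 4")
  seqs <- .asSeqChar(records)
  if (length(seqs) == 0L) stop("no input records")
  if (canonical) seqs <- c(seqs, revcomp(seqs))
  km <- unique(unlist(lapply(seqs, .kmersOfSeq, k = k), use.names = FALSE))
  if (length(km) == 0L)
    warning("all records shorter than k = ", k, "; profile is empty")
  new("SampleKmerProfile", sampleId = as.character(sampleId),
      sex = match.arg(sex, c("male", "female")), k = k,
      kmers = as.character(km))
}

#' k-mers present in every male and absent from every female sample
#'
#' The defining sieve predicate: intersection over male profiles minus the
#' union over female profiles.
#'
#' @param profiles List of [SampleKmerProfile-class] (>= 1 per sex, same `k`).
#' @return Character vector of sex-specific k-mers.
#' @export
maleSpecificKmers <- function(profiles) {
  sexes <- vapply(profiles, function(p) p@sex, character(1))
  if (!any(sexes == "male") || !any(sexes == "female"))
    stop("need at least one male and one female profile")
  ks <- vapply(profiles, function(p) p@k, integer(1))
  if (length(unique(ks)) != 1L)
    stop("profiles built with different k: ", paste(unique(ks), collapse = ", "))
  maleSets <- lapply(profiles[sexes == "male"], function(p) p@kmers)
  femaleSets <- lapply(profiles[sexes == "female"], function(p) p@kmers)
  setdiff(Reduce(intersect, maleSets),
          unique(unlist(femaleSets, use.names = FALSE)))
}

#' Select transcripts carrying sex-specific k-mers
#'
#' A transcript is retained iff at least one of its k-mers belongs to
#' `specificSet`. Input order is preserved and the per-transcript count of
#' matching k-mers is reported.
#'
#' @param transcripts Candidate transcripts (`DNAStringSet` or named
#'   character vector).
#' @param specificSet Character vector of k-mers (e.g. from
#'   [maleSpecificKmers()]).
#' @param k k-mer length matching `specificSet`.
#' @param canonical Count k-mers of both strands (must match the flag used to
#'   build the profiles).
#' @return `data.frame` with columns `transcript_id`, `n_specific_kmers` for
#'   the retained transcripts, in input order.
#' @export
sieveTranscripts <- function(transcripts, specificSet, k = 16,
                             canonical = FALSE) {
  k <- as.integer(k)
  if (length(specificSet) && any(nchar(specificSet) != k))
    stop("specificSet k-mers do not have length k = ", k)
  seqs <- .asSeqChar(transcripts)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  counts <- vapply(seqs, function(s) {
    km <- .kmersOfSeq(s, k)
    if (canonical) km <- unique(c(km, .kmersOfSeq(revcomp(s), k)))
    sum(km %in% specificSet)
  }, integer(1))
  out <- data.frame(transcript_id = names(seqs),
                    n_specific_kmers = unname(counts),
                    stringsAsFactors = FALSE)
  out[out$n_specific_kmers > 0L, , drop = FALSE]
}
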