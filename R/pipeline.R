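# End-to-end marker discovery: k-mer sieve -> expression filter -> gametolog
# pairing -> CAPS design -> cohort validation and in-silico genotyping, with
# per-stage reports.

.loadSeqSet <- function(x, what = "sequences") {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(.asSeqChar(readFastaRecords(x)))
  s <- .asSeqChar(x)
  if (is.null(names(s))) stop(what, " must be named or a FASTA path")
  s
}

# Thread an ungapped sequence into the gap pattern of a gapped row; NULL if
# the ungapped lengths do not agree (the copy has indels vs the row).
.gapLike <- function(row, seq) {
  rc <- .seqChars(row)
  sc <- .seqChars(seq)
  if (length(sc) != sum(rc != "-")) return(NULL)
  rc[rc != "-"] <- sc
  paste(rc, collapse = "")
}

# Attach each sample's copy of the paired transcripts as extra alignment
# rows, so downstream primer design sees cross-sample SNPs and folds them
# into degenerate bases rather than failing to bind those samples.
.attachSampleRows <- function(p, sampleSets) {
  gal <- p@alignment
  extras <- character(0)
  for (sid in names(sampleSets)) {
    set <- sampleSets[[sid]]
    for (id in c(p@xId, p@yId)) {
      if (!id %in% names(set)) next
      row <- if (identical(id, p@xId)) gal@xRow else gal@yRow
      threaded <- .gapLike(row, set[[id]])
      if (is.null(threaded)) next
      if (identical(threaded, gal@xRow) || identical(threaded, gal@yRow))
        next
      extras[paste0(sid, ".", id)] <- threaded
    }
  }
  extras <- extras[!duplicated(extras)]
  if (length(extras))
    p@alignment <- GametologAlignment(gal@xRow, gal@yRow,
                                      extraRows = c(gal@extraRows, extras))
  p
}

#' Run the full sex-marker discovery pipeline
#'
#' Executes the stages in order — comparative k-mer sieve, expression
#' filters, X-counterpart pairing, CAPS design, cohort validation with
#' in-silico genotyping of the input samples — and returns per-stage results
#' plus a summary of survivor counts. Stages whose inputs are absent are
#' skipped (e.g. no expression table: the sieve output goes to pairing
#' unfiltered).
#'
#' The final stage genotypes every input sample with every designed
#' candidate and reports the calls from the best-ranked candidate whose
#' calls agree most with the known sample sexes. Chance differential sites
#' created by background X/Y divergence are genuine CAPS sites, but unlike
#' a fixed difference they can be toggled by a private SNP in an individual;
#' validation against the known-sex cohort separates fixed markers from
#' such sites, mirroring how wet-lab markers are validated on individuals
#' of known sex before use.
#'
#' The expression gate applied to candidates is the strict presence/absence
#' TPM filter; the male-bias test table is always reported, but its FDR gate
#' is only enforced when `useBiasGate = TRUE` — rank tests are powerless at
#' the smallest cohort sizes (two-sided Wilcoxon cannot reach p < 0.1 at
#' 3 vs 3), and the strict zero-in-females criterion subsumes the bias
#' requirement for Y-linked genes.
#'
#' @param config Named list:
#'   \describe{
#'     \item{males, females}{Named lists of per-sample transcript sets
#'       (named character vectors / `DNAStringSet`s, or FASTA paths).}
#'     \item{transcripts}{Candidate transcripts; default: first male
#'       sample's set.}
#'     \item{expression}{A `SummarizedExperiment` from [ExpressionTable()],
#'       or `list(tpm =, sexes =)` TSV paths; optional.}
#'     \item{xCandidates}{Candidate X loci for pairing; default: first
#'       female sample's set.}
#'     \item{enzymes}{Enzyme list or TSV path; default [defaultEnzymes()].}
#'     \item{filterConfig, pairingPolicy, scoring, flankCfg, primerCfg,
#'       probeCfg}{Stage parameter objects (all optional).}
#'     \item{toleranceBp}{Band-matching tolerance for genotyping calls.}
#'     \item{useBiasGate}{Enforce the log2FC/FDR gate (default `FALSE`).}
#'     \item{outDir}{If set, per-stage TSV/JSON reports are written there.}
#'   }
#' @return List with elements `summary`, `sieve`, `biasTable`, `survivors`,
#'   `pairs`, `candidates`, `candidateOwner`, `validation` (per-candidate
#'   concordance with the known sexes, and which candidate was selected) and
#'   `genotypes` (calls from the selected candidate).
#' @export
runPipeline <- function(config) {
  cfg <- config$filterConfig
  if (is.null(cfg)) cfg <- FilterConfig()
  policy <- config$pairingPolicy
  if (is.null(policy)) policy <- PairingPolicy()
  scoring <- config$scoring
  if (is.null(scoring)) scoring <- defaultScoring()
  tol <- if (is.null(config$toleranceBp)) 10 else config$toleranceBp

  if (is.null(config$males) || length(config$males) == 0L)
    stop("configuration error: no male samples")
  if (is.null(config$females) || length(config$females) == 0L)
    stop("configuration error: no female samples")
  males <- lapply(config$males, .loadSeqSet)
  females <- lapply(config$females, .loadSeqSet)
  if (is.null(names(males))) names(males) <- paste0("M", seq_along(males))
  if (is.null(names(females))) names(females) <- paste0("F", seq_along(females))

  transcripts <- if (!is.null(config$transcripts))
    .loadSeqSet(config$transcripts, "transcripts") else males[[1]]
  xCandidates <- if (!is.null(config$xCandidates))
    .loadSeqSet(config$xCandidates, "xCandidates") else females[[1]]
  enzymes <- config$enzymes
  if (is.null(enzymes)) enzymes <- defaultEnzymes()
  if (is.character(enzymes)) enzymes <- readEnzymeTable(enzymes)

  t0 <- proc.time()[["elapsed"]]
  stageMsg <- function(stage, n) {
    message(sprintf("[%s] %s: %d survivor(s) (%.2fs elapsed)", "sexCAPS",
                    stage, n, proc.time()[["elapsed"]] - t0))
  }

  # stage 1: comparative k-mer sieve
  profiles <- c(
    lapply(names(males), function(id)
      buildKmerProfile(males[[id]], k = cfg@k, sex = "male", sampleId = id)),
    lapply(names(females), function(id)
      buildKmerProfile(females[[id]], k = cfg@k, sex = "female",
                       sampleId = id)))
  specific <- maleSpecificKmers(profiles)
  sieve <- sieveTranscripts(transcripts, specific, k = cfg@k)
  stageMsg("kmer_sieve", nrow(sieve))

  # stage 2: expression filters
  se <- config$expression
  if (is.list(se) && !is(se, "SummarizedExperiment"))
    se <- readExpressionTable(se$tpm, se$sexes)
  biasTable <- NULL
  survivors <- sieve$transcript_id
  if (!is.null(se)) {
    missing <- setdiff(survivors, rownames(se))
    if (length(missing))
      stop("configuration error: transcripts absent from expression table: ",
           paste(missing, collapse = ", "))
    strict <- strictTpmFilter(se, cfg)
    biasTable <- maleBiasTest(se, cfg)
    survivors <- intersect(survivors, strict)
    if (isTRUE(config$useBiasGate)) {
      passing <- biasTable$transcript[biasTable$pass %in% TRUE]
      survivors <- intersect(survivors, passing)
    }
  }
  stageMsg("expression_filter", length(survivors))

  # stage 3: X-counterpart pairing
  pairs <- lapply(survivors, function(id) {
    findCounterpart(transcripts[[id]], xCandidates, policy, scoring, yId = id)
  })
  accepted <- Filter(function(p) p@status == "accepted", pairs)
  if (length(accepted)) accepted <- divergenceRank(accepted)
  stageMsg("gametolog_pairing", length(accepted))

  # stage 4: CAPS design on each accepted pair, best-ranked pair first.
  # Homologous copies from every sample are attached as extra alignment
  # rows (when they thread into the pair alignment without new gaps), so
  # cross-sample SNPs in the flanks become degenerate primer bases instead
  # of primer-binding failures.
  candidates <- list()
  candidateOwner <- character(0)
  allSampleSets <- c(males, females)
  for (p in accepted) {
    p <- .attachSampleRows(p, allSampleSets)
    cands <- designCapsCandidates(p@alignment, enzymes,
      flankCfg = if (is.null(config$flankCfg)) flankConfig() else config$flankCfg,
      primerCfg = if (is.null(config$primerCfg)) primerConfig() else config$primerCfg,
      probeCfg = if (is.null(config$probeCfg)) probeConfig() else config$probeCfg)
    candidates <- c(candidates, cands)
    candidateOwner <- c(candidateOwner, rep(p@yId, length(cands)))
  }
  stageMsg("caps_design", length(candidates))

  # stage 5: cohort validation. Every candidate genotypes every input
  # sample in silico; the reported calls come from the best-ranked
  # candidate most concordant with the known sample sexes (see roxygen).
  genotypes <- NULL
  validation <- NULL
  if (length(candidates)) {
    allSamples <- c(males, females)
    truthSex <- rep(c("male", "female"), c(length(males), length(females)))
    wantCall <- ifelse(truthSex == "male", "XY", "XX")
    callsFor <- function(cc) {
      vapply(seq_along(allSamples), function(i) {
        obs <- integer(0)
        for (s in allSamples[[i]]) {
          amps <- insilicoPCR(s, cc@fwd, cc@rev)
          for (a in amps$seq) obs <- c(obs, bands(digest(a, cc@site@enzyme)))
        }
        if (length(obs) == 0L) return("ambiguous")
        callGenotype(obs, cc, toleranceBp = tol)
      }, character(1))
    }
    callsList <- lapply(candidates, callsFor)
    concordance <- vapply(callsList, function(cl) mean(cl == wantCall),
                          numeric(1))
    best <- which.max(concordance)  # rank order breaks ties
    validation <- data.frame(
      transcript = candidateOwner,
      candidate = vapply(candidates, function(cc) {
        paste(cc@site@enzyme@name, cc@site@alleleWithSite,
              cc@site@siteStart, sep = "_")
      }, character(1)),
      concordance = concordance,
      selected = seq_along(candidates) == best,
      stringsAsFactors = FALSE)
    genotypes <- data.frame(sample_id = names(allSamples), sex = truthSex,
                            call = callsList[[best]],
                            stringsAsFactors = FALSE)
    stageMsg("cohort_validation", sum(concordance == 1))
  }

  summary <- list(
    n_input_transcripts = length(transcripts),
    n_sieved = nrow(sieve),
    n_after_expression = length(survivors),
    n_pairs_accepted = length(accepted),
    n_candidates = length(candidates),
    parameters = list(
      k = cfg@k, min_male_mean_tpm = cfg@minMaleMeanTpm,
      max_female_tpm = cfg@maxFemaleTpm, min_log2fc = cfg@minLog2fc,
      max_fdr = cfg@maxFdr, pseudocount = cfg@pseudocount,
      min_identity = policy@minIdentity, min_coverage = policy@minCoverage,
      max_secondary_ratio = policy@maxSecondaryRatio,
      tolerance_bp = tol, use_bias_gate = isTRUE(config$useBiasGate)))

  report <- list(summary = summary, sieve = sieve, biasTable = biasTable,
                 survivors = survivors, pairs = pairs,
                 candidates = candidates, candidateOwner = candidateOwner,
                 validation = validation, genotypes = genotypes)
  if (!is.null(config$outDir)) writePipelineReport(report, config$outDir)
  report
}

.candidateRecord <- function(cc, owner = NA_character_) {
  list(transcript = owner, enzyme = cc@site@enzyme@name,
       recognition = cc@site@enzyme@recognition,
       allele_with_site = cc@site@alleleWithSite,
       site_start = cc@site@siteStart, strand = cc@site@strand,
       fwd_primer = cc@fwd@seq, rev_primer = cc@rev@seq,
       fwd_degeneracy = cc@fwd@degeneracy, rev_degeneracy = cc@rev@degeneracy,
       probe_cut = unname(cc@probes[["cut"]]),
       probe_uncut = unname(cc@probes[["uncut"]]),
       amplicon_len_x = cc@ampliconLenX, amplicon_len_y = cc@ampliconLenY,
       bands_xx = bands(cc@predictedBands$XX),
       bands_xy = bands(cc@predictedBands$XY),
       score = cc@score)
}

#' Write pipeline reports to a directory
#'
#' Emits `sieve.tsv`, `filter.tsv`, `pairs.tsv`, `candidates.json`,
#' `validation.tsv`, `genotypes.tsv` and `summary.json`. Deterministic:
#' identical reports for identical inputs.
#'
#' @param report Output of [runPipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writePipelineReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  w(report$sieve, "sieve.tsv")
  if (!is.null(report$biasTable)) w(report$biasTable, "filter.tsv")
  pairsDf <- do.call(rbind, lapply(report$pairs, function(p) {
    data.frame(y_id = p@yId, x_id = p@xId, status = p@status,
               divergence = p@divergence, stringsAsFactors = FALSE)
  }))
  if (!is.null(pairsDf)) w(pairsDf, "pairs.tsv")
  recs <- lapply(seq_along(report$candidates), function(i) {
    .candidateRecord(report$candidates[[i]], report$candidateOwner[i])
  })
  jsonlite::write_json(recs, file.path(dir, "candidates.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(report$validation)) w(report$validation, "validation.tsv")
  if (!is.null(report$genotypes)) w(report$genotypes, "genotypes.tsv")
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
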