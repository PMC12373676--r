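# Expression-based refinement of candidate Y transcripts: a strict
# presence/absence TPM filter and a male-bias differential test.

.splitSexColumns <- function(se) {
  sex <- .sampleSex(se)
  if (!any(sex == "male") || !any(sex == "female"))
    stop("need at least one male and one female sample")
  list(male = names(sex)[sex == "male"], female = names(sex)[sex == "female"])
}

#' Strict presence/absence TPM filter
#'
#' Retains transcripts expressed in males (mean TPM strictly above
#' `minMaleMeanTpm`) and absent from every female sample (TPM at most
#' `maxFemaleTpm`; with the default 0 this demands exact zeros). This is the
#' expected signature of Y-chromosome genes, which generate no reads in XX
#' samples.
#'
#' @param se Expression table from [ExpressionTable()].
#' @param cfg A [FilterConfig-class].
#' @return Character vector of retained transcript ids, in table order.
#' @export
strictTpmFilter <- function(se, cfg = FilterConfig()) {
  tpm <- .tpmMatrix(se)
  grp <- .splitSexColumns(se)
  maleMean <- rowMeans(tpm[, grp$male, drop = FALSE])
  femaleMax <- apply(tpm[, grp$female, drop = FALSE], 1L, max)
  rownames(tpm)[maleMean > cfg@minMaleMeanTpm & femaleMax <= cfg@maxFemaleTpm]
}

#' Male-bias differential expression test
#'
#' Per transcript: `log2FC = log2((mean_male + pseudocount) /
#' (mean_female + pseudocount))`; a two-sided Wilcoxon rank-sum test on the
#' per-sample TPMs (distribution-free, suited to the small cohorts typical of
#' these designs); Benjamini-Hochberg FDR over all tested transcripts. A
#' transcript passes when `log2FC >= minLog2fc` and `FDR <= maxFdr`.
#'
#' With fewer than two samples in either sex the test branch is skipped:
#' p, FDR and pass are `NA` and only log2FC is reported.
#'
#' @param se Expression table from [ExpressionTable()].
#' @param cfg A [FilterConfig-class].
#' @param test `"wilcoxon"` (default) or `"t"` (Welch) — strategy hook.
#' @return `data.frame` with columns `transcript`, `log2FC`, `p`, `FDR`,
#'   `pass`.
#' @export
maleBiasTest <- function(se, cfg = FilterConfig(),
                         test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  tpm <- .tpmMatrix(se)
  grp <- .splitSexColumns(se)
  m <- tpm[, grp$male, drop = FALSE]
  f <- tpm[, grp$female, drop = FALSE]
  log2fc <- log2((rowMeans(m) + cfg@pseudocount) /
                 (rowMeans(f) + cfg@pseudocount))
  canTest <- length(grp$male) >= 2L && length(grp$female) >= 2L
  p <- rep(NA_real_, nrow(tpm))
  if (canTest) {
    p <- vapply(seq_len(nrow(tpm)), function(i) {
      mi <- m[i, ]; fi <- f[i, ]
      if (all(mi == fi[1]) && all(fi == fi[1])) return(1)
      suppressWarnings(stats::wilcox.test(mi, fi,
        alternative = "two.sided",
        exact = (test == "wilcoxon" && !anyDuplicated(c(mi, fi))))$p.value)
    }, numeric(1))
    if (test == "t") {
      p <- vapply(seq_len(nrow(tpm)), function(i) {
        mi <- m[i, ]; fi <- f[i, ]
        if (stats::sd(c(mi, fi)) == 0) return(1)
        tryCatch(stats::t.test(mi, fi)$p.value, error = function(e) 1)
      }, numeric(1))
    }
  }
  fdr <- if (canTest) stats::p.adjust(p, method = "BH") else p
  pass <- if (canTest) (log2fc >= cfg@minLog2fc & fdr <= cfg@maxFdr)
          else rep(NA, nrow(tpm))
  data.frame(transcript = rownames(tpm), log2FC = unname(log2fc),
             p = unname(p), FDR = unname(fdr), pass = unname(pass),
             stringsAsFactors = FALSE)
}
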