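# Sequence, enzyme-table and expression-table I/O. FASTA handling is
# delegated to Biostrings; tables are plain TSV.

#' Read a FASTA file of sequences or alignment rows
#'
#' @param path FASTA file (plain or gapped/aligned).
#' @param gapped Keep gap characters (`-`) — use when reading alignments.
#'   With `gapped = FALSE` any gap characters are an error.
#' @return A [Biostrings::DNAStringSet] in file order.
#' @export
readFastaRecords <- function(path, gapped = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) {
                    stop("malformed FASTA in ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  # Biostrings keeps the full header line; use the first token as the id
  names(set) <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  w <- BiocGenerics::width(set)
  if (any(w == 0L))
    stop("empty sequence for record '", names(set)[which(w == 0L)[1]],
         "' in ", path)
  if (anyDuplicated(names(set)))
    stop("duplicate record id '", names(set)[duplicated(names(set))][1],
         "' in ", path)
  if (!gapped) {
    hasGap <- vapply(as.character(set), function(s) grepl("-", s, fixed = TRUE),
                     logical(1))
    if (any(hasGap))
      stop("record '", names(set)[hasGap][1], "' in ", path,
           " contains gap characters; read with gapped = TRUE")
  }
  set
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeFastaRecords <- function(seqs, path) {
  if (!is(seqs, "XStringSet")) {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("sequences must be named")
    seqs <- Biostrings::DNAStringSet(unlist(lapply(seqs, as.character)))
  }
  Biostrings::writeXStringSet(seqs, filepath = path, format = "fasta")
  invisible(path)
}

#' Read a restriction-enzyme table
#'
#' TSV with columns `name`, `recognition`, `cut_offset`.
#'
#' @param path TSV file.
#' @return Named list of [RestrictionEnzyme-class] objects.
#' @export
readEnzymeTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "recognition", "cut_offset")
  if (!all(need %in% names(tab)))
    stop("enzyme table must have columns: ", paste(need, collapse = ", "))
  enz <- lapply(seq_len(nrow(tab)), function(i) {
    RestrictionEnzyme(tab$name[i], tab$recognition[i], tab$cut_offset[i])
  })
  names(enz) <- tab$name
  enz
}

#' The restriction enzymes shipped with the package
#'
#' EcoRI plus a panel of common six-cutters, read from the packaged
#' enzyme TSV.
#'
#' @return Named list of [RestrictionEnzyme-class] objects.
#' @export
defaultEnzymes <- function() {
  readEnzymeTable(system.file("extdata", "enzymes.tsv", package = "sexCAPS",
                              mustWork = TRUE))
}

#' Build an expression table as a SummarizedExperiment
#'
#' @param tpm Numeric matrix, transcripts x samples, non-negative; rownames
#'   are transcript ids, colnames sample ids.
#' @param sex Named character vector (or factor) mapping every sample id to
#'   `"male"` or `"female"`.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay `tpm`
#'   and `colData` column `sex`.
#' @export
ExpressionTable <- function(tpm, sex) {
  tpm <- as.matrix(tpm)
  if (any(tpm < 0)) stop("TPM matrix has negative entries")
  if (is.null(rownames(tpm)) || is.null(colnames(tpm)))
    stop("TPM matrix must carry transcript and sample names")
  sexNames <- names(sex)
  sex <- stats::setNames(as.character(sex), sexNames)
  if (is.null(names(sex))) stop("sex labels must be named by sample id")
  missing <- setdiff(colnames(tpm), names(sex))
  if (length(missing))
    stop("no sex label for sample(s): ", paste(missing, collapse = ", "))
  sex <- sex[colnames(tpm)]
  if (!all(sex %in% c("male", "female")))
    stop("sex labels must be 'male' or 'female'")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = tpm),
    colData = S4Vectors::DataFrame(sex = sex, row.names = colnames(tpm)))
}

#' Read an expression table and sex labels from TSV
#'
#' @param tpmPath TSV: first column transcript id, remaining columns one per
#'   sample (header row gives sample ids).
#' @param sexPath Two-column TSV `sample_id`, `sex`.
#' @return A `SummarizedExperiment`, see [ExpressionTable()].
#' @export
readExpressionTable <- function(tpmPath, sexPath) {
  tab <- utils::read.delim(tpmPath, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs >= 1 sample column")
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  storage.mode(mat) <- "double"
  sx <- utils::read.delim(sexPath, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "sex") %in% names(sx)))
    stop("sex table must have columns sample_id, sex")
  ExpressionTable(mat, stats::setNames(sx$sex, sx$sample_id))
}

.tpmMatrix <- function(se) SummarizedExperiment::assay(se, "tpm")

.sampleSex <- function(se) {
  cd <- SummarizedExperiment::colData(se)
  if (!"sex" %in% names(cd)) stop("expression table has no 'sex' column")
  stats::setNames(as.character(cd$sex), rownames(cd))
}
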