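#' Read cleaning: adapters, N content, low quality
#'
#' Applies the three removal rules, in a fixed order with first-match-wins
#' attribution:
#' 1. reads containing the adapter sequence are removed;
#' 2. reads whose fraction of unknown nucleotides (N) is strictly greater
#'    than 5 percent are removed;
#' 3. reads with strictly more than 20 percent of bases at Phred quality
#'    below 10 are removed.
#'
#' Both thresholds are strict inequalities: at 49 bp, 2 Ns (4.1%) survive
#' and 3 Ns (6.1%) do not; 9 low-quality bases (18.4%) survive and 10
#' (20.4%) do not.
#'
#' @param reads A `read_set` (see [fragments_to_reads()] / [read_fastq()]).
#' @param adapter Adapter sequence to screen for (exact substring match).
#' @param max_n_fraction N-content threshold (default 0.05).
#' @param min_quality Phred threshold defining a low-quality base
#'   (default 10).
#' @param max_lowq_fraction Low-quality-base fraction threshold
#'   (default 0.20).
#' @return A list of class `qc_result` with `clean` (surviving `read_set`)
#'   and `report` (named counts: `total`, `adapter`, `n_content`,
#'   `low_quality`, `clean`).
#' @export
qc_filter <- function(reads, adapter = "AGATCGGAAGAGC",
                      max_n_fraction = 0.05, min_quality = 10L,
                      max_lowq_fraction = 0.20) {
  stopifnot(is.data.frame(reads))
  if (nrow(reads) > 0 && any(nchar(reads$seq) != nchar(reads$qual)))
    stop_spec("malformed read record: sequence/quality length mismatch (%s)",
              reads$id[which(nchar(reads$seq) != nchar(reads$qual))[1]])
  n <- nrow(reads)
  len <- nchar(reads$seq)
  has_adapter <- if (n > 0) grepl(adapter, reads$seq, fixed = TRUE)
                 else logical(0)
  n_count <- len - nchar(gsub("N", "", reads$seq, fixed = TRUE))
  n_fail <- !has_adapter & (n_count / len > max_n_fraction)
  lowq_count <- lowq_bases(reads$qual, min_quality)
  q_fail <- !has_adapter & !n_fail & (lowq_count / len > max_lowq_fraction)
  keep <- !has_adapter & !n_fail & !q_fail
  report <- c(total = n, adapter = sum(has_adapter), n_content = sum(n_fail),
              low_quality = sum(q_fail), clean = sum(keep))
  clean <- reads[keep, , drop = FALSE]
  class(clean) <- c("read_set", "data.frame")
  structure(list(clean = clean, report = report), class = "qc_result")
}

# number of bases with Phred quality < min_quality (Phred+33 encoding);
# counted by deleting the character range below the threshold
lowq_bases <- function(qual, min_quality) {
  if (length(qual) == 0L) return(integer(0))
  pat <- sprintf("[\\x21-\\x%x]", 32L + min_quality)
  nchar(qual) - nchar(gsub(pat, "", qual, perl = TRUE))
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat("QC:", r["total"], "reads in;",
      r["adapter"], "adapter,", r["n_content"], "N-content,",
      r["low_quality"], "low-quality removed;",
      r["clean"], "clean\n")
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param qc A `qc_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(qc, path) {
  df <- data.frame(rule = names(qc$report), count = as.integer(qc$report))
  write_tsv(df, path)
  invisible(path)
}
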