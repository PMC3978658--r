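#' Derive a stage-specific sub-seed from a global seed
#'
#' Stochastic pipeline stages must be reproducible independently of one
#' another, so each stage draws its own seed from the global run seed and the
#' stage name via a small polynomial hash. Re-running a single stage with the
#' same global seed then reproduces its output exactly, regardless of which
#' other stages ran before it.
#'
#' @param seed Global integer seed (non-negative).
#' @param stage Character stage label, e.g. `"chip_reads"`.
#' @return An integer in `[0, 2^31)` suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(1L, "chip_reads")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0,
            is.character(stage), length(stage) == 1L)
  p <- 2147480009 # prime below 2^31; doubles stay exact throughout
  h <- as.numeric(seed) %% p
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% p
  }
  as.integer(h)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 0-based half-open intervals are used internally and in BED output;
# GRanges conversion adds the +1 at this boundary only.
granges_from_bed0 <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
}

#' @noRd
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @noRd
read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, ...)
}

stop_spec <- function(...) stop(sprintf(...), call. = FALSE)
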