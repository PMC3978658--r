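#' Percent identity between two repeat units
#'
#' Equal-length sequences are compared position-wise (Hamming identity),
#' which is exact for the substitution-only divergence model used by the
#' genome generator. Unequal lengths fall back to a global
#' (Needleman-Wunsch) alignment and report matches over alignment columns.
#'
#' @param a,b DNA strings.
#' @return Percent identity in `[0, 100]`.
#' @export
unit_similarity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop_spec("empty sequence")
  if (nchar(a) == nchar(b)) return(hamming_identity(a, b))
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       type = "global")
  Biostrings::pid(aln, type = "PID1")
}

#' Pairwise similarity matrix for a set of sequences
#'
#' @param seqs Named character vector of sequences (e.g. repeat units or
#'   arrays).
#' @return Symmetric numeric matrix of percent identities with 100 on the
#'   diagonal.
#' @export
similarity_matrix <- function(seqs) {
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- unit_similarity(seqs[[i]], seqs[[j]])
      }
    }
  }
  m
}

#' Cross-mapping rate between two genomic features
#'
#' Enumerates the read-length k-mers of feature A (all of them when A has at
#' most `max_enumerate` k-mers, otherwise a seeded sample of `n_sample`) and
#' reports the fraction whose best-stratum placements under the mapper
#' include a position overlapping feature B. Identical features give rate 1:
#' every read from A also fits B, which is why near-identical repeat arrays
#' cannot be distinguished at a 2-mismatch/49 bp envelope.
#'
#' @param genome A `genome_build` or named character vector.
#' @param feature_a,feature_b Lists (or one-row data.frames) with `chrom`,
#'   `start`, `end` (0-based half-open).
#' @param config A [mapping_config()].
#' @param max_enumerate Enumerate exhaustively up to this many k-mers
#'   (default 5000).
#' @param n_sample Sample size beyond that (default 10000).
#' @param rng_seed Seed for sampling.
#' @return Fraction in `[0, 1]`.
#' @export
cross_map_rate <- function(genome, feature_a, feature_b,
                           config = mapping_config(), max_enumerate = 5000L,
                           n_sample = 10000L, rng_seed = 1L) {
  seqs <- genome_seqs_of(genome)
  L <- config$read_length
  a_len <- feature_a$end - feature_a$start
  if (a_len < L) stop_spec("feature A is shorter than the read length")
  starts <- feature_a$start:(feature_a$end - L)
  if (length(starts) > max_enumerate) {
    set.seed(rng_seed)
    starts <- sort(sample(starts, n_sample, replace = FALSE))
  }
  kmers <- cpp_extract_reads(seqs[[feature_a$chrom]], as.integer(starts),
                             integer(length(starts)), L)
  hits <- find_best_hits(kmers, seqs, config)
  in_b <- vapply(hits, function(h) {
    any(h$chrom == feature_b$chrom &
          h$start < feature_b$end &
          h$start + L > feature_b$start)
  }, logical(1))
  mean(in_b)
}

#' Annotate peaks that are explainable as cross-mapping artifacts
#'
#' Every peak that does not overlap a truth centromere is screened against
#' each truth centromere: the peak's sequence is scored in window-sized
#' chunks (150 bp, the resolution of the enrichment statistic) and the best
#' ungapped identity of any chunk against centromeric sequence is taken.
#' If it reaches `similarity_bound` percent the peak is flagged
#' `likely_artifact` (reads from the centromeric copy map equally well to
#' the counterpart and random multi-mapper assignment puts a share of them
#' there); otherwise `independent`. Chunk scoring matters because called
#' peak intervals snap to the window grid and include flanking sequence
#' that would dilute a whole-peak identity. Candidate alignments are found
#' by exact 16-mer seeding, which by the pigeonhole principle cannot miss a
#' chunk counterpart at or above the bound; `matched_identity` is `NA` when
#' no seeded alignment exists at all. Peaks overlapping a truth centromere
#' are always `centromeric`.
#'
#' @param peaks A `peak_calls` data.frame.
#' @param truth Truth data.frame from a `genome_build`.
#' @param genome A `genome_build` or named character vector.
#' @param similarity_bound Indistinguishability bound in percent
#'   (default 96, the regime above which repeat arrays cannot be told
#'   apart; arrays below 93 percent identity are distinguishable).
#' @param window_size Chunk size for identity scoring (default 150).
#' @return `peaks` with added columns `verdict`, `matched_centromere`
#'   and `matched_identity`.
#' @export
annotate_false_positive_peaks <- function(peaks, truth, genome,
                                          similarity_bound = 96,
                                          window_size = 150L) {
  seqs <- genome_seqs_of(genome)
  cen <- truth[truth$label == "centromere", , drop = FALSE]
  peaks <- flag_peaks_truth(peaks, truth)
  verdict <- character(nrow(peaks))
  matched <- rep(NA_character_, nrow(peaks))
  ident <- rep(NA_real_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (peaks$overlaps_truth_centromere[i]) {
      verdict[i] <- "centromeric"
      next
    }
    pseq <- substr(seqs[[peaks$chrom[i]]], peaks$start[i] + 1L,
                   peaks$end[i])
    best <- -1
    best_cen <- NA_character_
    for (j in seq_len(nrow(cen))) {
      cseq <- substr(seqs[[cen$chrom[j]]], cen$start[j] + 1L, cen$end[j])
      id <- cpp_seeded_window_identity(pseq, cseq, window_size, 16L)
      if (id > best) {
        best <- id
        best_cen <- sprintf("%s:%d-%d", cen$chrom[j], cen$start[j],
                            cen$end[j])
      }
    }
    if (best >= 0) {
      matched[i] <- best_cen
      ident[i] <- best
    }
    verdict[i] <- if (best >= similarity_bound) "likely_artifact"
                  else "independent"
  }
  peaks$verdict <- verdict
  peaks$matched_centromere <- matched
  peaks$matched_identity <- ident
  peaks
}
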