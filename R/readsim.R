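#' Occupancy profile for immunoprecipitation simulation
#'
#' A piecewise-constant fold-enrichment track: fragment start positions are
#' sampled with probability proportional to the local fold times a uniform
#' base rate. Fold 1 everywhere gives an input-like (no enrichment) library.
#'
#' @param features data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `fold` (>= 0, finite). May be empty.
#' @return An `occupancy_profile` object.
#' @export
occupancy_profile <- function(features = NULL) {
  if (is.null(features))
    features <- data.frame(chrom = character(0), start = integer(0),
                           end = integer(0), fold = numeric(0))
  stopifnot(all(c("chrom", "start", "end", "fold") %in% names(features)))
  if (any(!is.finite(features$fold)) || any(features$fold < 0))
    stop_spec("folds must be finite and >= 0")
  structure(list(features = features), class = "occupancy_profile")
}

#' Occupancy profile from genome truth features
#'
#' @param truth Truth data.frame from a `genome_build`.
#' @param fold_by_label Named numeric vector mapping truth labels (e.g.
#'   `centromere`) to fold enrichment; unmentioned labels stay at baseline.
#' @return An `occupancy_profile`.
#' @export
profile_from_truth <- function(truth, fold_by_label) {
  keep <- truth$label %in% names(fold_by_label)
  f <- truth[keep, c("chrom", "start", "end"), drop = FALSE]
  f$fold <- unname(fold_by_label[truth$label[keep]])
  occupancy_profile(f)
}

#' Sequencing library configuration
#'
#' @param n_fragments Number of fragments to sample.
#' @param read_length Read length in bp (default 49, single-end tags).
#' @param fragment_length_mean,fragment_length_sd Fragment length
#'   distribution (normal, rounded; default 200 +/- 50 bp, a typical
#'   sonication profile scale — only fragment-scale locality matters for
#'   150 bp windows).
#' @param error_rate Per-base substitution error rate (default 0.005).
#' @param adapter_rate,n_rate,lowq_rate Fractions of reads receiving,
#'   respectively, an adapter prefix, N injections pushing N content above
#'   5 percent, and quality downgrades pushing more than 20 percent of bases
#'   below Q10.
#' @param adapter Adapter sequence used for contamination and detection.
#' @return A `library_config` list.
#' @export
library_config <- function(n_fragments, read_length = 49L,
                           fragment_length_mean = 200,
                           fragment_length_sd = 50,
                           error_rate = 0.005,
                           adapter_rate = 0, n_rate = 0, lowq_rate = 0,
                           adapter = "AGATCGGAAGAGC") {
  rates <- c(error_rate, adapter_rate, n_rate, lowq_rate)
  if (any(rates < 0) || any(rates > 1))
    stop_spec("rates must be in [0, 1]")
  if (read_length < 1) stop_spec("read_length must be >= 1")
  if (n_fragments < 0) stop_spec("n_fragments must be >= 0")
  structure(list(n_fragments = as.integer(n_fragments),
                 read_length = as.integer(read_length),
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd,
                 error_rate = error_rate, adapter_rate = adapter_rate,
                 n_rate = n_rate, lowq_rate = lowq_rate, adapter = adapter),
            class = "library_config")
}

# piecewise-constant segments (chrom, start, end, fold) covering the genome,
# baseline fold 1 outside profile features
profile_segments <- function(genome_seqs, profile) {
  segs <- NULL
  for (chrom in names(genome_seqs)) {
    len <- nchar(genome_seqs[[chrom]])
    f <- profile$features[profile$features$chrom == chrom, , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    cuts <- sort(unique(c(0L, len, f$start, f$end)))
    cuts <- cuts[cuts >= 0L & cuts <= len]
    s <- data.frame(chrom = chrom, start = head(cuts, -1L),
                    end = cuts[-1L], fold = 1, stringsAsFactors = FALSE)
    if (nrow(f) > 0) {
      for (i in seq_len(nrow(f))) {
        inside <- s$start >= f$start[i] & s$end <= f$end[i]
        s$fold[inside] <- f$fold[i]
      }
    }
    segs <- rbind(segs, s)
  }
  segs[segs$end > segs$start, , drop = FALSE]
}

#' Sample chromatin fragments under an occupancy profile
#'
#' Fragment start positions are sampled with probability proportional to
#' `fold x length` of each constant-fold segment (uniform within a segment);
#' fragment lengths are drawn from the configured normal distribution,
#' rounded, floored at 1 bp and truncated at the chromosome end.
#'
#' @param genome A `genome_build` or named character vector of sequences.
#' @param profile An [occupancy_profile()].
#' @param config A [library_config()].
#' @param rng_seed Integer seed.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
sample_fragments <- function(genome, profile, config, rng_seed) {
  seqs <- genome_seqs_of(genome)
  if (length(seqs) == 0 || sum(nchar(seqs)) == 0)
    stop_spec("empty genome")
  set.seed(rng_seed)
  n <- config$n_fragments
  if (n == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  segs <- profile_segments(seqs, profile)
  w <- segs$fold * (segs$end - segs$start)
  if (sum(w) <= 0) stop_spec("occupancy profile gives zero total weight")
  seg_idx <- sample.int(nrow(segs), n, replace = TRUE, prob = w)
  start <- segs$start[seg_idx] +
    floor(runif(n) * (segs$end[seg_idx] - segs$start[seg_idx]))
  chrom <- segs$chrom[seg_idx]
  flen <- pmax(1L, as.integer(round(rnorm(n, config$fragment_length_mean,
                                          config$fragment_length_sd))))
  chrom_len <- nchar(seqs)[chrom]
  end <- pmin(start + flen, chrom_len)
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

genome_seqs_of <- function(genome) {
  if (inherits(genome, "genome_build")) genome$seqs else genome
}

#' Convert fragments to single-end reads
#'
#' One read per fragment, taken from the 5' end of a uniformly chosen
#' strand: plus-strand reads start at the fragment start, minus-strand reads
#' end at the fragment end and are reverse-complemented. Substitution errors
#' are applied at the configured per-base rate; every base gets the Phred
#' quality implied by that rate (capped at Q40). Fragments shorter than the
#' read length are skipped and counted.
#'
#' @param fragments data.frame from [sample_fragments()].
#' @param genome A `genome_build` or named character vector.
#' @param config A [library_config()].
#' @param rng_seed Integer seed.
#' @param id_prefix Prefix for read ids.
#' @return A `read_set`: data.frame with `id`, `seq`, `qual`,
#'   `origin_chrom`, `origin_start` (0-based leftmost aligned base),
#'   `origin_strand`, `artifact`; attribute `n_skipped` counts fragments
#'   shorter than the read length.
#' @export
fragments_to_reads <- function(fragments, genome, config, rng_seed,
                               id_prefix = "read") {
  seqs <- genome_seqs_of(genome)
  set.seed(rng_seed)
  L <- config$read_length
  keep <- (fragments$end - fragments$start) >= L
  n_skipped <- sum(!keep)
  fr <- fragments[keep, , drop = FALSE]
  n <- nrow(fr)
  if (n == 0L) {
    rs <- empty_read_set()
    attr(rs, "n_skipped") <- n_skipped
    return(rs)
  }
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  start0 <- ifelse(strand == "+", fr$start, fr$end - L)
  seq <- character(n)
  for (chrom in unique(fr$chrom)) {
    i <- which(fr$chrom == chrom)
    seq[i] <- cpp_extract_reads(seqs[[chrom]], as.integer(start0[i]),
                                as.integer(strand[i] == "-"), L)
  }
  if (config$error_rate > 0) {
    seq <- cpp_inject_errors(seq, config$error_rate)$seq
  }
  q <- if (config$error_rate > 0) {
    min(40L, as.integer(round(-10 * log10(config$error_rate))))
  } else 40L
  qual <- strrep(intToUtf8(q + 33L), L)
  rs <- data.frame(id = sprintf("%s%07d", id_prefix, seq_len(n)),
                   seq = seq, qual = qual,
                   origin_chrom = fr$chrom,
                   origin_start = as.integer(start0),
                   origin_strand = strand,
                   artifact = "none", stringsAsFactors = FALSE)
  class(rs) <- c("read_set", "data.frame")
  attr(rs, "n_skipped") <- n_skipped
  rs
}

empty_read_set <- function() {
  rs <- data.frame(id = character(0), seq = character(0),
                   qual = character(0), origin_chrom = character(0),
                   origin_start = integer(0), origin_strand = character(0),
                   artifact = character(0), stringsAsFactors = FALSE)
  class(rs) <- c("read_set", "data.frame")
  rs
}

#' Inject library artifacts into reads
#'
#' Disjoint random subsets of reads receive, respectively: an adapter
#' prefix (read length preserved); enough N substitutions to push N content
#' strictly above 5 percent (3 Ns at 49 bp); quality downgrades to Q2 on
#' enough bases to push strictly more than 20 percent of bases below Q10
#' (10 bases at 49 bp). Artifact labels are retained for testing.
#'
#' @param reads A `read_set`.
#' @param config A [library_config()] supplying the rates and adapter.
#' @param rng_seed Integer seed.
#' @return The modified `read_set`.
#' @export
inject_artifacts <- function(reads, config, rng_seed) {
  set.seed(rng_seed)
  n <- nrow(reads)
  if (n == 0L) return(reads)
  L <- config$read_length
  n_adapter <- rbinom(1L, n, config$adapter_rate)
  n_ns <- rbinom(1L, n, config$n_rate)
  n_lowq <- rbinom(1L, n, config$lowq_rate)
  picks <- sample.int(n, min(n, n_adapter + n_ns + n_lowq))
  i_adapter <- head(picks, n_adapter)
  i_ns <- head(tail(picks, -length(i_adapter)), n_ns)
  i_lowq <- tail(picks, max(0L, length(picks) - n_adapter - n_ns))
  seqv <- reads$seq
  qualv <- reads$qual
  artv <- reads$artifact
  # replace characters of x at k random positions each
  scatter <- function(x, k, ch) {
    vapply(x, function(s) {
      at <- sample.int(nchar(s), k)
      for (p in at) substr(s, p, p) <- ch
      s
    }, "", USE.NAMES = FALSE)
  }
  if (length(i_adapter) > 0) {
    ad <- substr(config$adapter, 1L, L)
    seqv[i_adapter] <- paste0(ad, substr(seqv[i_adapter], nchar(ad) + 1L, L))
    artv[i_adapter] <- "adapter"
  }
  if (length(i_ns) > 0) {
    k <- floor(0.05 * L) + 1L # smallest count strictly above 5%
    seqv[i_ns] <- scatter(seqv[i_ns], k, "N")
    artv[i_ns] <- "n_content"
  }
  if (length(i_lowq) > 0) {
    k <- floor(0.20 * L) + 1L # smallest count strictly above 20%
    qualv[i_lowq] <- scatter(qualv[i_lowq], k, intToUtf8(2L + 33L)) # Q2
    artv[i_lowq] <- "low_quality"
  }
  reads$seq <- seqv
  reads$qual <- qualv
  reads$artifact <- artv
  reads
}

#' Simulate a complete library (fragments, reads, artifacts)
#'
#' @inheritParams sample_fragments
#' @param id_prefix Prefix for read ids.
#' @return A `read_set` (see [fragments_to_reads()]).
#' @export
simulate_library <- function(genome, profile, config, rng_seed,
                             id_prefix = "read") {
  fr <- sample_fragments(genome, profile, config,
                         derive_seed(rng_seed, "fragments"))
  rs <- fragments_to_reads(fr, genome, config,
                           derive_seed(rng_seed, "reads"), id_prefix)
  inject_artifacts(rs, config, derive_seed(rng_seed, "artifacts"))
}

#' Write a read set as FASTQ (Phred+33)
#'
#' @param reads A `read_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0) {
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual),
               con)
  }
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' Origin fields (unknown for external data) are set to NA.
#'
#' @param path FASTQ path.
#' @return A `read_set`.
#' @export
read_fastq <- function(path) {
  qs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  n <- length(qs)
  if (n == 0L) return(empty_read_set())
  rs <- data.frame(id = sub("\\s.*$", "", names(qs)),
                   seq = as.character(qs),
                   qual = as.character(S4Vectors::mcols(qs)$qualities),
                   origin_chrom = NA_character_,
                   origin_start = NA_integer_,
                   origin_strand = NA_character_,
                   artifact = NA_character_, stringsAsFactors = FALSE)
  class(rs) <- c("read_set", "data.frame")
  rs
}
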