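#' Mapping configuration
#'
#' Reads are placed ungapped on both strands, allowing up to
#' `max_mismatches` substitutions. Completeness is guaranteed by the
#' pigeonhole principle: the read is cut into `max_mismatches + 1`
#' non-overlapping seed partitions (17/16/16 bp for a 49 bp read at two
#' mismatches), so every valid placement leaves at least one partition
#' error-free and discoverable by exact lookup.
#'
#' @param max_mismatches Maximum mismatches (default 2). N bases in a read
#'   mismatch every reference base.
#' @param read_length Read length (default 49).
#' @return A `mapping_config` list; `partitions` gives the seed lengths.
#' @export
mapping_config <- function(max_mismatches = 2L, read_length = 49L) {
  if (max_mismatches < 0) stop_spec("max_mismatches must be >= 0")
  if (read_length < max_mismatches + 1)
    stop_spec("read_length too short for %d partitions", max_mismatches + 1)
  p <- max_mismatches + 1L
  lens <- rep(read_length %/% p, p)
  extra <- read_length %% p
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  structure(list(max_mismatches = as.integer(max_mismatches),
                 read_length = as.integer(read_length),
                 partitions = as.integer(lens)),
            class = "mapping_config")
}

check_genome_for_mapping <- function(seqs, read_length) {
  if (length(seqs) == 0 || sum(nchar(seqs)) == 0) stop_spec("empty genome")
  short <- nchar(seqs) < read_length
  if (any(short)) {
    warning(sprintf("excluding %d sequence(s) shorter than the read length",
                    sum(short)))
    seqs <- seqs[!short]
    if (length(seqs) == 0) stop_spec("no sequence as long as a read")
  }
  seqs
}

#' All best-stratum hits for each read
#'
#' Returns, for every read, all placements (both strands) achieving the
#' minimum mismatch count, provided that minimum is within the allowance;
#' sub-optimal strata are suppressed (a 0-mismatch hit hides 1-2 mismatch
#' hits).
#'
#' @param reads Character vector of read sequences (equal lengths).
#' @param genome A `genome_build` or named character vector of sequences.
#' @param config A [mapping_config()].
#' @return A list (one element per read) of data.frames with columns
#'   `chrom`, `start` (0-based), `strand`, `mismatches`; zero rows when the
#'   read does not place within the allowance.
#' @export
find_best_hits <- function(reads, genome, config = mapping_config()) {
  seqs <- check_genome_for_mapping(genome_seqs_of(genome),
                                   config$read_length)
  res <- cpp_map_reads(unname(toupper(seqs)), toupper(reads),
                       config$read_length, config$max_mismatches,
                       collect_hits = TRUE)
  chrom_names <- names(seqs)
  lapply(res$hits, function(hm) {
    data.frame(chrom = chrom_names[hm[, 1]], start = hm[, 2],
               strand = c("+", "-")[hm[, 3] + 1L],
               mismatches = hm[, 4], stringsAsFactors = FALSE)
  })
}

#' Map a read library
#'
#' Each read is placed at a uniformly random choice among its best-stratum
#' hits (the multi-mapping resolution used for reads from identical repeat
#' copies); reads with no placement within the mismatch allowance are
#' unmapped. Deterministic given `rng_seed`.
#'
#' @param reads A `read_set` or character vector of sequences.
#' @param genome A `genome_build` or named character vector.
#' @param config A [mapping_config()].
#' @param rng_seed Integer seed for multi-mapper resolution.
#' @return An `alignment_set`: list with `alignments` (data.frame:
#'   `read_id`, `chrom`, `start` 0-based, `strand`, `mismatches`,
#'   `multiplicity`) and `stats` (named counts: `total`, `mapped`,
#'   `unmapped`, `unique`, `multi`).
#' @export
map_library <- function(reads, genome, config = mapping_config(),
                        rng_seed = 1L) {
  if (is.data.frame(reads)) {
    ids <- reads$id
    seqv <- reads$seq
  } else {
    seqv <- as.character(reads)
    ids <- if (!is.null(names(seqv)) && all(nzchar(names(seqv))))
      names(seqv) else sprintf("read%07d", seq_along(seqv))
  }
  seqs <- check_genome_for_mapping(genome_seqs_of(genome),
                                   config$read_length)
  set.seed(rng_seed)
  res <- cpp_map_reads(unname(toupper(seqs)), toupper(seqv),
                       config$read_length, config$max_mismatches,
                       collect_hits = FALSE)
  mapped <- !is.na(res$chrom)
  aln <- data.frame(read_id = ids[mapped],
                    chrom = names(seqs)[res$chrom[mapped]],
                    start = res$pos[mapped],
                    strand = c("+", "-")[res$strand[mapped] + 1L],
                    mismatches = res$mismatches[mapped],
                    multiplicity = res$multiplicity[mapped],
                    stringsAsFactors = FALSE)
  stats <- c(total = length(seqv), mapped = sum(mapped),
             unmapped = sum(!mapped),
             unique = sum(res$multiplicity[mapped] == 1L),
             multi = sum(res$multiplicity[mapped] > 1L))
  structure(list(alignments = aln, stats = stats,
                 read_length = config$read_length),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  s <- x$stats
  cat("alignment_set:", s["mapped"], "/", s["total"], "reads mapped (",
      s["unique"], "unique,", s["multi"], "multi )\n")
  invisible(x)
}

#' Write alignments as minimal SAM
#'
#' Mandatory columns plus `NM` (mismatch count) and `NH` (number of
#' equally-best hits). Sequence and quality columns are emitted when the
#' originating `read_set` is supplied.
#'
#' @param aln An `alignment_set`.
#' @param genome A `genome_build` or named character vector (for `@SQ`
#'   headers).
#' @param path Output path.
#' @param reads Optional `read_set` to supply SEQ/QUAL.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(aln, genome, path, reads = NULL) {
  seqs <- genome_seqs_of(genome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), nchar(seqs)), con)
  a <- aln$alignments
  if (nrow(a) > 0) {
    seqcol <- "*"
    qualcol <- "*"
    if (!is.null(reads)) {
      i <- match(a$read_id, reads$id)
      seqcol <- reads$seq[i]
      qualcol <- reads$qual[i]
    }
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d\tNH:i:%d",
                       a$read_id, ifelse(a$strand == "-", 16L, 0L), a$chrom,
                       a$start + 1L, aln$read_length, seqcol, qualcol,
                       a$mismatches, a$multiplicity), con)
  }
  invisible(path)
}

#' Write aligned read intervals as BED
#'
#' @param aln An `alignment_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
alignments_to_bed <- function(aln, path) {
  a <- aln$alignments
  bed <- data.frame(chrom = a$chrom, start = a$start,
                    end = a$start + aln$read_length, name = a$read_id,
                    score = a$mismatches, strand = a$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
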