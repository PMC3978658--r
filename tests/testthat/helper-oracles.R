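# shared fixtures and independent oracles for the test suite

# random unique-ish genome as a named character vector
random_genome <- function(lens, seed) {
  set.seed(seed)
  setNames(vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, ""), names(lens))
}

# independent mapping oracle: all best-stratum placements of `read` on both
# strands via Biostrings::matchPattern + direct mismatch recount
brute_best_hits <- function(read, seqs, max_mm = 2L) {
  hits <- NULL
  p_fwd <- Biostrings::DNAString(read)
  p_rev <- Biostrings::reverseComplement(p_fwd)
  for (chrom in names(seqs)) {
    subj <- Biostrings::DNAString(seqs[[chrom]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") p_fwd else p_rev
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm,
                                    with.indels = FALSE)
      if (length(m) == 0) next
      starts1 <- BiocGenerics::start(m)
      mm <- vapply(starts1, function(s) {
        ref <- substr(seqs[[chrom]], s, s + nchar(read) - 1L)
        sum(utf8ToInt(as.character(pat)) != utf8ToInt(ref))
      }, numeric(1))
      keep <- mm <= max_mm
      if (any(keep)) {
        hits <- rbind(hits, data.frame(chrom = chrom,
                                       start = starts1[keep] - 1L,
                                       strand = strand,
                                       mismatches = as.integer(mm[keep]),
                                       stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(hits)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  hits <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
  hits[order(hits$chrom, hits$start, hits$strand), , drop = FALSE]
}

sort_hits <- function(h) {
  h <- h[order(h$chrom, h$start, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# inject exactly `k` substitutions at given (or random) 0-based positions
substitute_at <- function(seq, positions0) {
  bases <- c("A", "C", "G", "T")
  for (p in positions0) {
    cur <- substr(seq, p + 1L, p + 1L)
    substr(seq, p + 1L, p + 1L) <- sample(setdiff(bases, cur), 1L)
  }
  seq
}

# minimal alignment_set for window-counting tests
manual_alignments <- function(chrom, start, read_length = 49L) {
  n <- length(start)
  structure(list(
    alignments = data.frame(read_id = sprintf("r%d", seq_len(n)),
                            chrom = chrom, start = as.integer(start),
                            strand = "+", mismatches = 0L,
                            multiplicity = 1L, stringsAsFactors = FALSE),
    stats = c(total = n, mapped = n, unmapped = 0L, unique = n, multi = 0L),
    read_length = as.integer(read_length)), class = "alignment_set")
}

# one-read-set builder for QC fixtures
make_reads <- function(seqs, quals = NULL) {
  n <- length(seqs)
  if (is.null(quals)) quals <- strrep("I", nchar(seqs)) # Q40
  rs <- data.frame(id = sprintf("fix%03d", seq_len(n)), seq = seqs,
                   qual = quals, origin_chrom = NA_character_,
                   origin_start = NA_integer_, origin_strand = NA_character_,
                   artifact = "none", stringsAsFactors = FALSE)
  class(rs) <- c("read_set", "data.frame")
  rs
}

# small two-chromosome genome with planted centromeres, for pipeline tests
small_run_config <- function(seed = 1L, ...) {
  default_run_config(seed = seed, n_chromosomes = 2L,
                     chrom_length = 200000L, coverage = 10, ...)
}

# a config with one chromosome carrying an arm duplicate of centromeric
# sequence at the given identity (the false-positive peak fixture)
duplicate_run_config <- function(seed, identity, dup_len = 1208L) {
  cen <- repeat_family_spec(unit_length = 177L, unit_at_fraction = 0.7,
                            copy_count = 120L, per_copy_divergence = 0.04)
  cen_start <- 100000L
  dup <- list(list(src_start = cen_start + 5000L,
                   src_end = cen_start + 5000L + dup_len,
                   dest_start = 40000L, identity = identity))
  chrom <- chromosome_spec("chr1", 250000L, cen, cen_start,
                           duplicates = dup)
  cfg <- default_run_config(seed = seed, n_chromosomes = 1L,
                            chrom_length = 250000L, coverage = 10,
                            include_minichromosome = FALSE)
  cfg$genome$chromosomes <- list(chrom)
  cfg$enrichment$background <- list(chrom = "chr1", start = 150000L,
                                    end = 243750L)
  cfg
}

# genome with a centromere-like segment and an arm duplicate at a chosen
# identity; substitution positions are nested across identities (same seed)
# so lower identity always carries a superset of the mutations
crossmap_fixture <- function(identity, seed = 70L) {
  set.seed(seed)
  arm <- paste(sample(c("A", "C", "G", "T"), 30000L, TRUE), collapse = "")
  src_start <- 20000L
  src <- substr(arm, src_start + 1L, src_start + 600L)
  k <- round((1 - identity / 100) * 600)
  dup <- if (k > 0) substitute_at(src, sample(0:599, k)) else src
  g <- c(chr = paste0(substr(arm, 1L, 5000L), dup,
                      substr(arm, 5601L, 30000L)))
  list(genome = g,
       a = list(chrom = "chr", start = 5000L, end = 5600L),
       b = list(chrom = "chr", start = src_start, end = src_start + 600L))
}

# copurification matrix with independent false-positive cells added
noisy_kkt_matrix <- function(fp_rate, seed) {
  ev <- kkt_subcomplex_fixture()
  m <- build_matrix(filter_evidence(ev))
  set.seed(seed)
  flip <- !m & matrix(runif(length(m)) < fp_rate, nrow(m))
  m[flip] <- TRUE
  m
}

# do the deduced groups match the expected membership blocks exactly?
groups_match <- function(calls, blocks) {
  got <- unname(lapply(split(calls$protein, calls$group), sort))
  want <- lapply(blocks, sort)
  length(got) == length(want) &&
    setequal(vapply(got, paste, "", collapse = ","),
             vapply(want, paste, "", collapse = ","))
}
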