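#' Specify a tandem-repeat family
#'
#' Describes a centromeric (or minichromosomal) tandem repeat array: the
#' length and AT fraction of the master unit, how many copies are laid down
#' and how much each copy diverges from the master by random substitution.
#'
#' @param unit_length Unit length in bp (default 177, the minichromosome
#'   core repeat unit length).
#' @param unit_at_fraction Expected A+T fraction of the unit in `[0, 1]`;
#'   centromeric repeat units are relatively AT rich, so the default is 0.7.
#' @param copy_count Number of tandem copies (>= 1).
#' @param per_copy_divergence Expected substitutions per base in `[0, 0.25]`
#'   applied independently to each copy; 0.04 yields copies at ~96 percent
#'   identity to the master unit.
#' @return A `repeat_family_spec` list.
#' @export
repeat_family_spec <- function(unit_length = 177L, unit_at_fraction = 0.7,
                               copy_count = 240L, per_copy_divergence = 0.04) {
  if (!is.numeric(unit_length) || unit_length < 1)
    stop_spec("unit_length must be >= 1")
  if (!is.numeric(unit_at_fraction) || unit_at_fraction < 0 ||
      unit_at_fraction > 1)
    stop_spec("unit_at_fraction must be in [0, 1]")
  if (!is.numeric(copy_count) || copy_count < 1)
    stop_spec("copy_count must be >= 1")
  if (!is.numeric(per_copy_divergence) || per_copy_divergence < 0 ||
      per_copy_divergence > 0.25)
    stop_spec("per_copy_divergence must be in [0, 0.25]")
  structure(list(unit_length = as.integer(unit_length),
                 unit_at_fraction = unit_at_fraction,
                 copy_count = as.integer(copy_count),
                 per_copy_divergence = per_copy_divergence),
            class = "repeat_family_spec")
}

#' Specify a synthetic chromosome
#'
#' A chromosome is i.i.d. background ("arm") sequence at a given GC fraction
#' with one centromeric repeat array inserted at a fixed position, plus
#' optional planted duplicates: copies of an interval of the finished
#' chromosome (typically centromeric sequence) pasted elsewhere at a target
#' percent identity. Planted duplicates reproduce the mechanism by which
#' near-identical sequence outside a centromere attracts randomly assigned
#' multi-mapping reads and creates false-positive peaks.
#'
#' All intervals are 0-based half-open.
#'
#' @param name Chromosome name.
#' @param length Chromosome length in bp.
#' @param centromere A [repeat_family_spec()].
#' @param centromere_start 0-based start of the repeat array.
#' @param arm_gc_fraction GC fraction of arm sequence (default 0.5).
#' @param duplicates A list of lists with fields `src_start`, `src_end`
#'   (0-based half-open source interval), `dest_start` (destination) and
#'   `identity` (target percent identity in `(0, 100]`).
#' @return A `chromosome_spec` list.
#' @export
chromosome_spec <- function(name, length, centromere, centromere_start,
                            arm_gc_fraction = 0.5, duplicates = list()) {
  stopifnot(inherits(centromere, "repeat_family_spec"))
  length <- as.integer(length)
  centromere_start <- as.integer(centromere_start)
  cen_len <- centromere$unit_length * centromere$copy_count
  ivs <- data.frame(start = centromere_start,
                    end = centromere_start + cen_len)
  for (d in duplicates) {
    stopifnot(all(c("src_start", "src_end", "dest_start", "identity")
                  %in% names(d)))
    if (d$identity <= 0 || d$identity > 100)
      stop_spec("duplicate identity must be in (0, 100]")
    dlen <- d$src_end - d$src_start
    if (dlen < 1) stop_spec("duplicate source interval is empty")
    ivs <- rbind(ivs, data.frame(start = d$dest_start,
                                 end = d$dest_start + dlen))
  }
  if (any(ivs$start < 0) || any(ivs$end > length))
    stop_spec("feature interval outside [0, %d) on %s", length, name)
  ivs <- ivs[order(ivs$start), , drop = FALSE]
  if (nrow(ivs) > 1 && any(ivs$start[-1] < ivs$end[-nrow(ivs)]))
    stop_spec("feature placements overlap on %s", name)
  structure(list(name = name, length = length,
                 arm_gc_fraction = arm_gc_fraction,
                 centromere = centromere,
                 centromere_start = centromere_start,
                 duplicates = duplicates),
            class = "chromosome_spec")
}

#' Specify a palindromic minichromosome contig
#'
#' The model minichromosome contig consists almost entirely of tandem 177 bp
#' repeats arranged palindromically: the sequence left of the inversion point
#' is the reverse complement of the sequence right of it (up to truncation at
#' the shorter side). Defaults give the 42,529 bp model contig with the
#' inversion point in the middle.
#'
#' @param unit_length Repeat unit length (default 177).
#' @param total_length Contig length (default 42529).
#' @param inversion_point 0-based position of the inversion point; defaults
#'   to `floor(total_length / 2)`.
#' @param unit_at_fraction AT fraction of the repeat unit (default 0.7).
#' @param name Contig name (default `"minichromosome"`).
#' @return A `minichromosome_spec` list.
#' @export
minichromosome_spec <- function(unit_length = 177L, total_length = 42529L,
                                inversion_point = NULL,
                                unit_at_fraction = 0.7,
                                name = "minichromosome") {
  unit_length <- as.integer(unit_length)
  total_length <- as.integer(total_length)
  if (total_length < 2L * unit_length)
    stop_spec("total_length must be at least twice unit_length")
  if (is.null(inversion_point)) inversion_point <- total_length %/% 2L
  inversion_point <- as.integer(inversion_point)
  if (inversion_point < 1L || inversion_point >= total_length)
    stop_spec("inversion_point must lie strictly inside the contig")
  structure(list(unit_length = unit_length, total_length = total_length,
                 inversion_point = inversion_point,
                 unit_at_fraction = unit_at_fraction, name = name),
            class = "minichromosome_spec")
}

#' Generate a repeat master unit
#'
#' Bases are drawn i.i.d.: A and T each with probability
#' `unit_at_fraction / 2`, G and C each with `(1 - unit_at_fraction) / 2`.
#'
#' @param spec A [repeat_family_spec()].
#' @param rng_seed Integer seed.
#' @return A single DNA string of length `spec$unit_length`.
#' @export
make_repeat_unit <- function(spec, rng_seed) {
  stopifnot(inherits(spec, "repeat_family_spec"))
  set.seed(rng_seed)
  at <- spec$unit_at_fraction
  random_dna(spec$unit_length, p = c(A = at / 2, C = (1 - at) / 2,
                                     G = (1 - at) / 2, T = at / 2))
}

# i.i.d. DNA of length n with per-base probabilities p (named A,C,G,T)
random_dna <- function(n, p) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# substitute each base independently with probability `rate`, always to a
# different base, so Hamming identity is 1 - realised substitution rate
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hit <- which(runif(n) < rate)
  if (length(hit) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    chars[i] <- sample(setdiff(bases, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

hamming_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  av <- utf8ToInt(a)
  bv <- utf8ToInt(b)
  100 * sum(av == bv) / length(av)
}

#' Build a tandem repeat array from a master unit
#'
#' Each of `copy_count` copies of `unit` is independently mutated at the
#' per-base rate `per_copy_divergence` and the copies are concatenated. The
#' Hamming identity of each copy to the master unit is reported, mirroring
#' how pairwise repeat-unit similarity (e.g. the >96 percent regime in which
#' 49 bp reads cannot be assigned unambiguously) is quantified.
#'
#' @param unit Master unit DNA string.
#' @param copy_count Number of copies (>= 1).
#' @param per_copy_divergence Expected substitutions per base.
#' @param rng_seed Integer seed.
#' @return A list with `sequence` (the array) and `identity` (numeric vector
#'   of per-copy percent identities to the master unit).
#' @export
build_repeat_array <- function(unit, copy_count, per_copy_divergence,
                               rng_seed) {
  if (copy_count < 1) stop_spec("copy_count must be >= 1")
  set.seed(rng_seed)
  copies <- character(copy_count)
  ident <- numeric(copy_count)
  for (i in seq_len(copy_count)) {
    copies[i] <- mutate_sequence(unit, per_copy_divergence)
    ident[i] <- hamming_identity(unit, copies[i])
  }
  list(sequence = paste(copies, collapse = ""), identity = ident)
}

#' Build one synthetic chromosome with ground truth
#'
#' Arms are i.i.d. sequence at `arm_gc_fraction`; the centromeric repeat
#' array is written over its interval; each planted duplicate then copies
#' its (post-centromere) source interval to the destination, mutated down to
#' the requested percent identity. Truth records are returned for the
#' centromere and every duplicate.
#'
#' @param spec A [chromosome_spec()].
#' @param rng_seed Integer seed.
#' @return A list with `sequence` and `truth` (data.frame with columns
#'   `chrom`, `start`, `end`, `label`, `identity`; 0-based half-open).
#' @export
build_chromosome <- function(spec, rng_seed) {
  stopifnot(inherits(spec, "chromosome_spec"))
  set.seed(derive_seed(rng_seed, paste0("arms:", spec$name)))
  gc <- spec$arm_gc_fraction
  seq <- random_dna(spec$length, p = c(A = (1 - gc) / 2, C = gc / 2,
                                       G = gc / 2, T = (1 - gc) / 2))
  cen <- spec$centromere
  unit <- make_repeat_unit(cen, derive_seed(rng_seed,
                                            paste0("unit:", spec$name)))
  arr <- build_repeat_array(unit, cen$copy_count, cen$per_copy_divergence,
                            derive_seed(rng_seed,
                                        paste0("array:", spec$name)))
  cs <- spec$centromere_start
  ce <- cs + nchar(arr$sequence)
  substr(seq, cs + 1L, ce) <- arr$sequence
  truth <- data.frame(chrom = spec$name, start = cs, end = ce,
                      label = "centromere",
                      identity = mean(arr$identity),
                      stringsAsFactors = FALSE)
  set.seed(derive_seed(rng_seed, paste0("dups:", spec$name)))
  for (d in spec$duplicates) {
    src <- substr(seq, d$src_start + 1L, d$src_end)
    rate <- 1 - d$identity / 100
    copy <- mutate_sequence(src, rate)
    ds <- d$dest_start
    de <- ds + nchar(copy)
    substr(seq, ds + 1L, de) <- copy
    truth <- rbind(truth, data.frame(chrom = spec$name, start = ds, end = de,
                                     label = "duplicate_copy",
                                     identity = hamming_identity(src, copy),
                                     stringsAsFactors = FALSE))
  }
  list(sequence = seq, truth = truth, repeat_unit = unit)
}

#' Build the palindromic minichromosome contig
#'
#' Tandem copies of the repeat unit fill the side(s) of the inversion point;
#' the left side is the reverse complement of the mirrored right side, so
#' the construction invariant `seq[ip - 1 - i] == complement(seq[ip + i])`
#' holds for every offset up to the shorter side's length.
#'
#' @param spec A [minichromosome_spec()].
#' @param rng_seed Integer seed.
#' @return A list with `sequence`, `truth` (one `minichromosome_repeat`
#'   feature spanning the contig) and `repeat_unit`.
#' @export
build_minichromosome <- function(spec, rng_seed) {
  stopifnot(inherits(spec, "minichromosome_spec"))
  fam <- repeat_family_spec(unit_length = spec$unit_length,
                            unit_at_fraction = spec$unit_at_fraction,
                            copy_count = 1L, per_copy_divergence = 0)
  unit <- make_repeat_unit(fam, derive_seed(rng_seed, "mini:unit"))
  L <- spec$inversion_point
  R <- spec$total_length - spec$inversion_point
  core_len <- max(L, R)
  core <- strrep(unit, ceiling(core_len / spec$unit_length))
  core <- substr(core, 1L, core_len)
  left <- revcomp(substr(core, 1L, L))
  right <- substr(core, 1L, R)
  seq <- paste0(left, right)
  truth <- data.frame(chrom = spec$name, start = 0L,
                      end = spec$total_length,
                      label = "minichromosome_repeat", identity = 100,
                      stringsAsFactors = FALSE)
  list(sequence = seq, truth = truth, repeat_unit = unit)
}

#' Assemble a genome build from chromosome and minichromosome specs
#'
#' @param chromosomes List of [chromosome_spec()] objects.
#' @param minichromosome Optional [minichromosome_spec()].
#' @param rng_seed Integer seed; every contained build derives its own
#'   sub-seed from it, so identical specs and seed give byte-identical
#'   genomes.
#' @return A `genome_build`: list with `seqs` (named character vector),
#'   `truth` (data.frame), `seed`, `units` (per-chromosome repeat units).
#' @export
build_genome <- function(chromosomes, minichromosome = NULL, rng_seed = 1L) {
  stopifnot(length(chromosomes) > 0 || !is.null(minichromosome))
  seqs <- character(0)
  truth <- NULL
  units <- list()
  for (cs in chromosomes) {
    b <- build_chromosome(cs, derive_seed(rng_seed, paste0("chrom:",
                                                           cs$name)))
    seqs[cs$name] <- b$sequence
    truth <- rbind(truth, b$truth)
    units[[cs$name]] <- b$repeat_unit
  }
  if (!is.null(minichromosome)) {
    b <- build_minichromosome(minichromosome,
                              derive_seed(rng_seed, "minichromosome"))
    seqs[minichromosome$name] <- b$sequence
    truth <- rbind(truth, b$truth)
    units[[minichromosome$name]] <- b$repeat_unit
  }
  rownames(truth) <- NULL
  structure(list(seqs = seqs, truth = truth, seed = as.integer(rng_seed),
                 units = units),
            class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat("genome_build:", length(x$seqs), "sequence(s),",
      sum(nchar(x$seqs)), "bp total\n")
  for (nm in names(x$seqs)) cat("  ", nm, ": ", nchar(x$seqs[[nm]]),
                                " bp\n", sep = "")
  cat("truth features:", nrow(x$truth), "\n")
  invisible(x)
}

#' Write a genome build to FASTA and BED
#'
#' The FASTA holds one record per chromosome; the BED holds the 0-based
#' half-open truth intervals with the feature label in the name column and
#' the mean percent identity in the score column.
#'
#' @param build A `genome_build`.
#' @param fasta_path Output FASTA path.
#' @param bed_path Output BED path (optional).
#' @return Invisibly, the paths written.
#' @export
write_genome <- function(build, fasta_path, bed_path = NULL) {
  stopifnot(inherits(build, "genome_build"), length(build$seqs) > 0)
  dss <- Biostrings::DNAStringSet(build$seqs)
  Biostrings::writeXStringSet(dss, fasta_path)
  if (!is.null(bed_path)) {
    bed <- build$truth[, c("chrom", "start", "end", "label", "identity")]
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(c(fasta = fasta_path, bed = bed_path))
}

#' Read a genome FASTA into the internal representation
#'
#' @param fasta_path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_genome_fasta <- function(fasta_path) {
  dss <- Biostrings::readDNAStringSet(fasta_path)
  setNames(toupper(as.character(dss)),
           sub("\\s.*$", "", names(dss)))
}
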