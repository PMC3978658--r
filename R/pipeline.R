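#' Demo run configuration
#'
#' The default study setup: four 400 kb chromosomes, each carrying one
#' AT-rich centromeric array of 240 x 177 bp units at 4 percent per-copy
#' divergence (~42.5 kb, ~96 percent within-array identity), plus the
#' palindromic 42,529 bp minichromosome contig. The ChIP library is
#' simulated at 10-fold occupancy over centromeres and 3-fold over the
#' minichromosome repeats; the input library is unenriched. Coverage is the
#' nominal per-library sequencing depth (read bases per genome base).
#'
#' @param seed Global integer seed.
#' @param n_chromosomes Number of megabase-like chromosomes (default 4).
#' @param chrom_length Chromosome length in bp (default 400000).
#' @param coverage Nominal depth per library (default 10).
#' @param centromere_fold ChIP fold enrichment over centromeres
#'   (default 10).
#' @param minichromosome_fold ChIP fold over the minichromosome (default 3).
#' @param include_minichromosome Include the palindromic contig
#'   (default TRUE).
#' @param duplicates Named list (by chromosome name) of planted-duplicate
#'   lists passed to [chromosome_spec()].
#' @param error_rate,adapter_rate,n_rate,lowq_rate Library artifact rates
#'   (defaults 0.005, 0.01, 0.005, 0.005).
#' @param fold_threshold,merge_gap,min_input Peak-calling and masking
#'   parameters (defaults 3, 1, 10).
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1L, n_chromosomes = 4L,
                               chrom_length = 400000L, coverage = 10,
                               centromere_fold = 10,
                               minichromosome_fold = 3,
                               include_minichromosome = TRUE,
                               duplicates = list(),
                               error_rate = 0.005, adapter_rate = 0.01,
                               n_rate = 0.005, lowq_rate = 0.005,
                               fold_threshold = 3, merge_gap = 1L,
                               min_input = 10L) {
  cen <- repeat_family_spec(unit_length = 177L, unit_at_fraction = 0.7,
                            copy_count = 240L, per_copy_divergence = 0.04)
  cen_start <- as.integer(chrom_length * 0.45)
  chroms <- lapply(seq_len(n_chromosomes), function(i) {
    nm <- paste0("chr", i)
    chromosome_spec(name = nm, length = chrom_length, centromere = cen,
                    centromere_start = cen_start,
                    duplicates = if (nm %in% names(duplicates))
                      duplicates[[nm]] else list())
  })
  mini <- if (include_minichromosome) minichromosome_spec() else NULL
  genome_bp <- n_chromosomes * chrom_length +
    if (include_minichromosome) mini$total_length else 0L
  n_frag <- as.integer(round(coverage * genome_bp / 49))
  lib <- function() {
    library_config(n_fragments = n_frag, read_length = 49L,
                   error_rate = error_rate, adapter_rate = adapter_rate,
                   n_rate = n_rate, lowq_rate = lowq_rate)
  }
  chip_folds <- c(centromere = centromere_fold)
  if (include_minichromosome)
    chip_folds["minichromosome_repeat"] <- minichromosome_fold
  bg_chrom <- paste0("chr", n_chromosomes)
  cen_end <- cen_start + cen$unit_length * cen$copy_count
  bg_start <- max(as.integer(chrom_length * 0.625), cen_end + 3000L)
  structure(list(
    seed = as.integer(seed),
    genome = list(chromosomes = chroms, minichromosome = mini),
    chip = list(config = lib(), fold_by_label = chip_folds),
    input = list(config = lib(), fold_by_label = numeric(0)),
    mapping = mapping_config(max_mismatches = 2L, read_length = 49L),
    enrichment = list(window_size = 150L, min_input = as.integer(min_input),
                      fold_threshold = fold_threshold,
                      merge_gap = as.integer(merge_gap),
                      background = list(chrom = bg_chrom,
                                        start = bg_start,
                                        end = as.integer(chrom_length *
                                                           0.975)))),
    class = "run_config")
}

#' Validate a run configuration
#'
#' Checks cross-field constraints and returns all violations, each naming
#' the offending field.
#'
#' @param config A `run_config`.
#' @return Character vector of error messages; empty when the configuration
#'   is valid.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  add <- function(e) errs <<- c(errs, e)
  if (is.null(config$seed) || !is.numeric(config$seed) || config$seed < 0)
    add("seed: must be a non-negative integer")
  chroms <- config$genome$chromosomes
  if (length(chroms) == 0 && is.null(config$genome$minichromosome))
    add("genome: no sequences configured")
  lens <- setNames(vapply(chroms, function(c) c$length, numeric(1)),
                   vapply(chroms, function(c) c$name, character(1)))
  if (!is.null(config$genome$minichromosome))
    lens[config$genome$minichromosome$name] <-
      config$genome$minichromosome$total_length
  bg <- config$enrichment$background
  if (!bg$chrom %in% names(lens)) {
    add(sprintf("enrichment.background.chrom: '%s' not in genome",
                bg$chrom))
  } else if (bg$start < 0 || bg$end > lens[[bg$chrom]] ||
             bg$start >= bg$end) {
    add(sprintf("enrichment.background: [%d,%d) outside %s of length %d",
                bg$start, bg$end, bg$chrom, lens[[bg$chrom]]))
  }
  for (cs in chroms) {
    if (cs$name != bg$chrom) next
    cen_start <- cs$centromere_start
    cen_end <- cen_start + cs$centromere$unit_length *
      cs$centromere$copy_count
    if (bg$start < cen_end && bg$end > cen_start)
      add(sprintf(
        "enrichment.background: [%d,%d) overlaps the %s centromere [%d,%d)",
        bg$start, bg$end, cs$name, cen_start, cen_end))
  }
  if (config$enrichment$window_size < 1)
    add("enrichment.window_size: must be >= 1")
  rl <- config$mapping$read_length
  for (lib in c("chip", "input")) {
    lc <- config[[lib]]$config
    if (lc$read_length != rl)
      add(sprintf("%s.config.read_length: %d differs from mapping (%d)",
                  lib, lc$read_length, rl))
    if (lc$n_fragments < 1)
      add(sprintf("%s.config.n_fragments: must be >= 1", lib))
  }
  errs
}

#' Run the full analysis pipeline
#'
#' Genome synthesis, ChIP and input library simulation, read cleaning,
#' mapping, window counting, enrichment ratios, background estimation, peak
#' calling, truth overlap flags, minichromosome summary and
#' false-positive-peak annotation — all driven by one global seed through
#' documented per-stage sub-seeds, so two runs with the same configuration
#' are identical.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param out_dir Optional directory; when given, all stage outputs are
#'   written there (FASTA, BED, FASTQ, SAM, TSV, bedGraph).
#' @param verbose Print stage progress.
#' @return A `run_report` list; the heavyweight intermediates (genome,
#'   window table, alignments) are attached under `$artifacts`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  errs <- validate_config(config)
  if (length(errs) > 0)
    stop_spec("invalid configuration:\n  %s", paste(errs, collapse = "\n  "))
  seed <- config$seed
  say <- function(...) if (verbose) message(sprintf(...))

  say("[genome] building synthetic genome")
  genome <- build_genome(config$genome$chromosomes,
                         config$genome$minichromosome,
                         derive_seed(seed, "genome"))

  libs <- list()
  for (lib in c("chip", "input")) {
    say("[%s] simulating library", lib)
    prof <- profile_from_truth(genome$truth, config[[lib]]$fold_by_label)
    reads <- simulate_library(genome, prof, config[[lib]]$config,
                              derive_seed(seed, lib),
                              id_prefix = paste0(lib, "_"))
    say("[%s] cleaning %d reads", lib, nrow(reads))
    qc <- qc_filter(reads, adapter = config[[lib]]$config$adapter)
    say("[%s] mapping %d clean reads", lib, nrow(qc$clean))
    aln <- map_library(qc$clean, genome, config$mapping,
                       derive_seed(seed, paste0("map_", lib)))
    libs[[lib]] <- list(raw = reads, qc = qc, aln = aln)
  }

  say("[enrichment] counting 150 bp windows and ratios")
  enr <- config$enrichment
  chip_counts <- count_windows(libs$chip$aln, genome, enr$window_size)
  input_counts <- count_windows(libs$input$aln, genome, enr$window_size)
  tab <- compute_ratios(chip_counts, input_counts,
                        chip_total = libs$chip$aln$stats[["mapped"]],
                        input_total = libs$input$aln$stats[["mapped"]],
                        min_input = enr$min_input)
  bg <- estimate_background(tab, enr$background$chrom,
                            enr$background$start, enr$background$end)
  peaks <- call_peaks(tab, bg, enr$fold_threshold, enr$merge_gap)
  peaks <- annotate_false_positive_peaks(peaks, genome$truth, genome)
  mini <- config$genome$minichromosome
  contig <- if (!is.null(mini) && mini$name %in% tab$chrom &&
                any(!tab$masked[tab$chrom == mini$name])) {
    contig_enrichment(tab, mini$name, bg)
  } else NULL

  report <- structure(list(
    seed = seed,
    stage_counts = list(
      chip = c(fragments = config$chip$config$n_fragments,
               reads = nrow(libs$chip$raw),
               clean = unname(libs$chip$qc$report[["clean"]]),
               mapped = unname(libs$chip$aln$stats[["mapped"]])),
      input = c(fragments = config$input$config$n_fragments,
                reads = nrow(libs$input$raw),
                clean = unname(libs$input$qc$report[["clean"]]),
                mapped = unname(libs$input$aln$stats[["mapped"]]))),
    qc = list(chip = libs$chip$qc$report, input = libs$input$qc$report),
    mapping = list(chip = libs$chip$aln$stats,
                   input = libs$input$aln$stats),
    background = bg,
    peaks = peaks,
    contig = contig),
    class = "run_report")

  stopifnot(report$stage_counts$chip[["clean"]] ==
              report$mapping$chip[["total"]],
            report$stage_counts$input[["clean"]] ==
              report$mapping$input[["total"]])

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_genome(genome, p("genome.fasta"), p("truth.bed"))
    for (lib in c("chip", "input")) {
      write_fastq(libs[[lib]]$raw, p(paste0(lib, ".fastq")))
      write_qc_report(libs[[lib]]$qc, p(paste0(lib, ".qc.tsv")))
      write_sam(libs[[lib]]$aln, genome, p(paste0(lib, ".sam")))
    }
    write_window_table(tab, p("windows.tsv"))
    write_bedgraph(tab, p("ratio.bedgraph"))
    write_peaks_bed(peaks, p("peaks.bed"))
    write_run_report(report, p("report.yaml"))
  }

  report$artifacts <- list(genome = genome, windows = tab,
                           chip = libs$chip, input = libs$input)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed", x$seed, ")\n")
  for (lib in c("chip", "input")) {
    sc <- x$stage_counts[[lib]]
    cat(sprintf("  %-5s: %d fragments -> %d reads -> %d clean -> %d mapped\n",
                lib, sc[["fragments"]], sc[["reads"]], sc[["clean"]],
                sc[["mapped"]]))
  }
  cat(sprintf("  background: %.3f (%d windows)\n", x$background$mean,
              x$background$n_windows))
  cat(sprintf("  peaks: %d (%d top, %d overlapping truth centromeres)\n",
              nrow(x$peaks), sum(x$peaks$is_top),
              sum(x$peaks$overlaps_truth_centromere)))
  if (!is.null(x$contig))
    cat(sprintf("  %s: mean ratio %.3f, %.0f%% of windows above background\n",
                x$contig$contig, x$contig$mean_ratio,
                100 * x$contig$fraction_above_background))
  invisible(x)
}

#' Export the ratio track as bedGraph
#'
#' Unmasked windows only; suitable for genome browsers.
#'
#' @param table A `window_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(table, path) {
  t <- table[!table$masked, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph name=chip_input_ratio", con)
  writeLines(sprintf("%s\t%d\t%d\t%.6g", t$chrom, t$start, t$end, t$ratio),
             con)
  invisible(path)
}

write_run_report <- function(report, path) {
  x <- list(seed = report$seed,
            stage_counts = lapply(report$stage_counts, as.list),
            qc = lapply(report$qc, as.list),
            mapping = lapply(report$mapping, as.list),
            background = report$background[c("chrom", "start", "end",
                                             "mean", "n_windows")],
            n_peaks = nrow(report$peaks),
            contig = report$contig)
  yaml::write_yaml(x, path)
  invisible(path)
}
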