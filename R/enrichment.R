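#' Count reads in nonoverlapping windows
#'
#' Chromosomes are partitioned into consecutive nonoverlapping windows
#' (150 bp by default; the final window may be shorter). In the default
#' `overlap` mode a read increments every window its interval overlaps by at
#' least one base, mirroring interval-coverage counting; the alternative
#' `start` mode assigns each read to the single window containing its
#' leftmost base.
#'
#' @param aln An `alignment_set` from [map_library()].
#' @param genome A `genome_build` or named character vector.
#' @param window_size Window size in bp (default 150).
#' @param mode `"overlap"` (default) or `"start"`.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `count`.
#' @export
count_windows <- function(aln, genome, window_size = 150L,
                          mode = c("overlap", "start")) {
  mode <- match.arg(mode)
  if (window_size < 1) stop_spec("window_size must be >= 1")
  seqs <- genome_seqs_of(genome)
  win <- window_grid(seqs, window_size)
  a <- aln$alignments
  if (nrow(a) > 0) {
    bad <- a$start < 0 | a$start + aln$read_length >
      nchar(seqs)[a$chrom]
    if (any(bad, na.rm = TRUE) || any(is.na(bad)))
      stop_spec("alignment outside chromosome bounds")
  }
  win_gr <- granges_from_bed0(win$chrom, win$start, win$end)
  GenomeInfoDb::seqlevels(win_gr) <- names(seqs)
  if (nrow(a) == 0) {
    win$count <- 0L
    return(win)
  }
  if (mode == "overlap") {
    read_gr <- granges_from_bed0(a$chrom, a$start, a$start + aln$read_length)
    GenomeInfoDb::seqlevels(read_gr) <- names(seqs)
    win$count <- GenomicRanges::countOverlaps(win_gr, read_gr,
                                              minoverlap = 1L)
  } else {
    read_gr <- granges_from_bed0(a$chrom, a$start, a$start + 1L)
    GenomeInfoDb::seqlevels(read_gr) <- names(seqs)
    win$count <- GenomicRanges::countOverlaps(win_gr, read_gr)
  }
  win
}

window_grid <- function(seqs, window_size) {
  out <- NULL
  for (chrom in names(seqs)) {
    len <- nchar(seqs[[chrom]])
    starts <- seq.int(0L, len - 1L, by = window_size)
    out <- rbind(out, data.frame(chrom = chrom, start = starts,
                                 end = pmin(starts + window_size, len),
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Per-window ChIP/input enrichment ratios
#'
#' The ratio is the input-normalised proportion:
#' `(chip_count / chip_total) / (input_count / input_total)`. Windows with
#' fewer than `min_input` raw input reads (default 10) are masked to reduce
#' noise and carry no ratio.
#'
#' @param chip_counts,input_counts Window count tables from
#'   [count_windows()] on the same grid.
#' @param chip_total,input_total Library totals used for normalisation
#'   (mapped read counts); default to the sums of the window counts'
#'   attributes if missing.
#' @param min_input Raw input count below which a window is masked.
#' @return A `window_table` data.frame: `chrom`, `window` (0-based index per
#'   chromosome), `start`, `end`, `input_count`, `chip_count`, `ratio`
#'   (NA when masked), `masked`.
#' @export
compute_ratios <- function(chip_counts, input_counts, chip_total,
                           input_total, min_input = 10L) {
  same_grid <- nrow(chip_counts) == nrow(input_counts) &&
    all(chip_counts$chrom == input_counts$chrom) &&
    all(chip_counts$start == input_counts$start) &&
    all(chip_counts$end == input_counts$end)
  if (!same_grid) stop_spec("ChIP and input window grids differ")
  if (chip_total <= 0 || input_total <= 0)
    stop_spec("library totals must be positive")
  tab <- data.frame(chrom = chip_counts$chrom,
                    window = stats::ave(chip_counts$start, chip_counts$chrom,
                                        FUN = seq_along) - 1L,
                    start = chip_counts$start, end = chip_counts$end,
                    input_count = input_counts$count,
                    chip_count = chip_counts$count,
                    stringsAsFactors = FALSE)
  tab$masked <- tab$input_count < min_input
  tab$ratio <- ifelse(tab$masked, NA_real_,
                      (tab$chip_count / chip_total) /
                        (tab$input_count / input_total))
  tab <- tab[, c("chrom", "window", "start", "end", "input_count",
                 "chip_count", "ratio", "masked")]
  class(tab) <- c("window_table", "data.frame")
  tab
}

#' Background enrichment level over a reference interval
#'
#' Arithmetic mean of the unmasked ratios of the windows fully contained in
#' the reference interval (a non-centromeric region; the analysis this
#' package models used positions 550,000-750,000 of one chromosome).
#'
#' @param table A `window_table`.
#' @param chrom Reference chromosome.
#' @param start,end Reference interval, 0-based half-open.
#' @return A `background_estimate` list: `chrom`, `start`, `end`, `mean`,
#'   `n_windows`.
#' @export
estimate_background <- function(table, chrom, start, end) {
  inside <- table$chrom == chrom & table$start >= start & table$end <= end
  use <- inside & !table$masked
  if (!any(use))
    stop_spec("no unmasked windows in %s:[%d,%d); choose another interval",
              chrom, start, end)
  structure(list(chrom = chrom, start = start, end = end,
                 mean = mean(table$ratio[use]), n_windows = sum(use)),
            class = "background_estimate")
}

#' @export
print.background_estimate <- function(x, ...) {
  cat(sprintf("background %.3f over %d windows in %s:[%d,%d)\n",
              x$mean, x$n_windows, x$chrom, x$start, x$end))
  invisible(x)
}

#' Call enrichment peaks
#'
#' Unmasked windows with ratio at least `fold_threshold` times the
#' background are merged into peaks when separated by at most `merge_gap`
#' windows; per chromosome the call with the largest mean ratio is flagged
#' as the top (candidate centromere) peak.
#'
#' @param table A `window_table`.
#' @param background Numeric background level or a `background_estimate`.
#' @param fold_threshold Fold over background required (default 3).
#' @param merge_gap Maximum number of non-qualifying windows bridged when
#'   merging adjacent qualifying windows (default 1).
#' @return A `peak_calls` data.frame: `chrom`, `start`, `end`, `n_windows`,
#'   `max_ratio`, `mean_ratio`, `is_top`.
#' @export
call_peaks <- function(table, background, fold_threshold = 3,
                       merge_gap = 1L) {
  if (inherits(background, "background_estimate"))
    background <- background$mean
  if (!is.numeric(background) || background <= 0)
    stop_spec("background must be positive")
  thr <- fold_threshold * background
  peaks <- NULL
  for (chrom in unique(table$chrom)) {
    t <- table[table$chrom == chrom, , drop = FALSE]
    qual <- !t$masked & !is.na(t$ratio) & t$ratio >= thr
    idx <- which(qual)
    if (length(idx) == 0L) next
    gap <- c(Inf, diff(idx))
    grp <- cumsum(gap > merge_gap + 1L)
    for (g in unique(grp)) {
      i <- idx[grp == g]
      peaks <- rbind(peaks, data.frame(
        chrom = chrom, start = t$start[min(i)], end = t$end[max(i)],
        n_windows = length(i), max_ratio = max(t$ratio[i]),
        mean_ratio = mean(t$ratio[i]), stringsAsFactors = FALSE))
    }
  }
  if (is.null(peaks)) {
    peaks <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), n_windows = integer(0),
                        max_ratio = numeric(0), mean_ratio = numeric(0),
                        is_top = logical(0))
  } else {
    peaks$is_top <- FALSE
    for (chrom in unique(peaks$chrom)) {
      i <- which(peaks$chrom == chrom)
      peaks$is_top[i[which.max(peaks$mean_ratio[i])]] <- TRUE
    }
  }
  class(peaks) <- c("peak_calls", "data.frame")
  peaks
}

#' Flag peaks by overlap with truth centromeres
#'
#' @param peaks A `peak_calls` data.frame.
#' @param truth Truth data.frame from a `genome_build`.
#' @return `peaks` with an added logical `overlaps_truth_centromere`.
#' @export
flag_peaks_truth <- function(peaks, truth) {
  cen <- truth[truth$label == "centromere", , drop = FALSE]
  ov <- logical(nrow(peaks))
  if (nrow(peaks) > 0 && nrow(cen) > 0) {
    pg <- granges_from_bed0(peaks$chrom, peaks$start, peaks$end)
    cg <- granges_from_bed0(cen$chrom, cen$start, cen$end)
    ov <- GenomicRanges::countOverlaps(pg, cg) > 0
  }
  peaks$overlaps_truth_centromere <- ov
  peaks
}

#' Enrichment summary for one contig
#'
#' Aggregates a contig's unmasked windows relative to a supplied background
#' level: used for the minichromosome contig, whose homogeneous repeats
#' preclude positional peak calls but whose overall enrichment is still
#' interpretable.
#'
#' @param table A `window_table`.
#' @param contig Contig name.
#' @param background Numeric background or `background_estimate`.
#' @return List with `contig`, `n_windows`, `mean_ratio`,
#'   `fraction_above_background`.
#' @export
contig_enrichment <- function(table, contig, background) {
  if (inherits(background, "background_estimate"))
    background <- background$mean
  if (!contig %in% table$chrom)
    stop_spec("contig '%s' not present in the window table", contig)
  t <- table[table$chrom == contig & !table$masked, , drop = FALSE]
  if (nrow(t) == 0L)
    stop_spec("contig '%s' has no unmasked windows", contig)
  list(contig = contig, n_windows = nrow(t), mean_ratio = mean(t$ratio),
       fraction_above_background = mean(t$ratio > background))
}

#' Write a window table, or peaks, as TSV/BED
#'
#' @param table A `window_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_window_table <- function(table, path) {
  write_tsv(as.data.frame(table), path)
  invisible(path)
}

#' @rdname write_window_table
#' @param peaks A `peak_calls` data.frame; written as BED with the mean
#'   ratio in the score column.
#' @export
write_peaks_bed <- function(peaks, path) {
  bed <- data.frame(chrom = peaks$chrom, start = peaks$start,
                    end = peaks$end,
                    name = sprintf("peak%03d", seq_len(nrow(peaks))),
                    score = round(peaks$mean_ratio, 4),
                    strand = ".")
  extra <- setdiff(names(peaks),
                   c("chrom", "start", "end", "mean_ratio"))
  bed <- cbind(bed, peaks[, extra, drop = FALSE])
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
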