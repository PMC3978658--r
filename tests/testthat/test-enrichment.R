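test_that("reads are counted in every 150 bp window they overlap", {
  g <- random_genome(c(chr = 1500L), 41L)
  aln <- manual_alignments("chr", c(10L, 140L))
  tab <- count_windows(aln, g)
  expect_equal(tab$count, c(1L + 1L, 1L, rep(0L, 8L)))
  # [10,59) stays in window 0; [140,189) spans windows 0 and 1

  aln_start <- count_windows(manual_alignments("chr", c(10L, 140L)), g,
                             mode = "start")
  expect_equal(aln_start$count, c(2L, rep(0L, 9L)))

  expect_error(count_windows(manual_alignments("chr", 1490L), g), "bounds")
})

test_that("window counts match a brute-force overlap recount", {
  g <- random_genome(c(chrA = 4000L, chrB = 2500L), 42L)
  set.seed(11)
  chrom <- sample(names(g), 1000L, replace = TRUE)
  start <- vapply(chrom, function(c) sample.int(nchar(g[[c]]) - 49L, 1L) - 1L,
                  integer(1))
  aln <- manual_alignments(chrom, start)
  tab <- count_windows(aln, g)
  for (i in seq_len(nrow(tab))) {
    expected <- sum(chrom == tab$chrom[i] & start < tab$end[i] &
                      start + 49L > tab$start[i])
    expect_equal(tab$count[i], expected)
  }
})

test_that("window partition tiles each chromosome exactly once", {
  g <- random_genome(c(chrA = 1000L, chrB = 451L), 43L)
  tab <- count_windows(manual_alignments("chrA", 0L), g)
  for (chrom in names(g)) {
    t <- tab[tab$chrom == chrom, ]
    expect_equal(t$start[1], 0L)
    expect_equal(t$end[nrow(t)], nchar(g[[chrom]]))
    expect_true(all(t$start[-1] == t$end[-nrow(t)]))
    expect_true(all(t$end - t$start <= 150L))
  }
  # final partial window is retained (451 = 3 * 150 + 1)
  expect_equal(sum(tab$chrom == "chrB"), 4L)
  expect_equal(tab$end[nrow(tab)] - tab$start[nrow(tab)], 1L)
})

test_that("enrichment ratios follow the normalised-proportion formula", {
  grid <- data.frame(chrom = "chr", start = c(0L, 150L), end = c(150L, 300L))
  chip <- cbind(grid, count = c(30L, 40L))
  input <- cbind(grid, count = c(10L, 9L))
  tab <- compute_ratios(chip, input, chip_total = 1000L, input_total = 1000L)
  expect_equal(tab$ratio[1], 3.0)
  expect_true(tab$masked[2]) # 9 input reads < 10 -> masked
  expect_true(is.na(tab$ratio[2]))

  # depth invariance: doubling one library's counts and total is a no-op
  chip2 <- chip
  chip2$count <- chip2$count * 2L
  tab2 <- compute_ratios(chip2, input, chip_total = 2000L,
                         input_total = 1000L)
  expect_equal(tab2$ratio, tab$ratio)

  bad <- input[1, , drop = FALSE]
  expect_error(compute_ratios(chip, cbind(bad, count = 1L), 1, 1), "grid")
})

test_that("background is the mean unmasked ratio in the reference interval", {
  tab <- data.frame(chrom = "chr", window = 0:3,
                    start = c(0L, 150L, 300L, 450L),
                    end = c(150L, 300L, 450L, 600L),
                    input_count = c(20L, 20L, 5L, 20L),
                    chip_count = c(10L, 30L, 2L, 99L),
                    ratio = c(0.5, 1.5, NA, 4.95),
                    masked = c(FALSE, FALSE, TRUE, FALSE))
  class(tab) <- c("window_table", "data.frame")
  bg <- estimate_background(tab, "chr", 0L, 450L)
  expect_equal(bg$mean, 1.0) # masked window ignored
  expect_equal(bg$n_windows, 2L)
  expect_error(estimate_background(tab, "chr", 300L, 450L), "unmasked")
})

test_that("peaks are threshold runs merged across small gaps", {
  mk_tab <- function(ratios, masked = rep(FALSE, length(ratios))) {
    n <- length(ratios)
    t <- data.frame(chrom = "chr", window = seq_len(n) - 1L,
                    start = (seq_len(n) - 1L) * 150L,
                    end = seq_len(n) * 150L,
                    input_count = 20L, chip_count = 20L,
                    ratio = ifelse(masked, NA, ratios), masked = masked)
    class(t) <- c("window_table", "data.frame")
    t
  }
  expect_equal(nrow(call_peaks(mk_tab(rep(1, 10)), background = 1)), 0L)

  one <- call_peaks(mk_tab(c(rep(1, 4), 10, rep(1, 5))), background = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(600L, 750L))
  expect_true(one$is_top)
  expect_equal(one$max_ratio, 10)

  # two qualifying windows separated by one weak window merge (gap 1)...
  merged <- call_peaks(mk_tab(c(1, 5, 1, 5, 1)), background = 1)
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(150L, 600L))
  # ...but a two-window gap splits them
  split <- call_peaks(mk_tab(c(5, 1, 1, 5, 1)), background = 1)
  expect_equal(nrow(split), 2L)

  # per-chromosome top flag goes to the largest mean ratio
  two <- call_peaks(mk_tab(c(4, 1, 1, 8, 1)), background = 1)
  expect_equal(two$is_top, c(FALSE, TRUE))
})

test_that("contig summaries aggregate unmasked windows against background", {
  n <- 40L
  set.seed(3)
  ratios <- 1 + rnorm(n, 0, 0.05)
  tab <- data.frame(chrom = "mini", window = seq_len(n) - 1L,
                    start = (seq_len(n) - 1L) * 150L,
                    end = seq_len(n) * 150L, input_count = 30L,
                    chip_count = 30L, ratio = ratios,
                    masked = rep(FALSE, n))
  class(tab) <- c("window_table", "data.frame")
  s <- contig_enrichment(tab, "mini", background = 1)
  expect_equal(s$mean_ratio, mean(ratios))
  expect_lt(abs(s$fraction_above_background - 0.5), 0.25)
  expect_error(contig_enrichment(tab, "absent", 1), "not present")
  tab$masked <- TRUE
  expect_error(contig_enrichment(tab, "mini", 1), "unmasked")
})

test_that("count conservation: overlap counting never undercounts", {
  g <- random_genome(c(chr = 3000L), 44L)
  set.seed(12)
  start <- sample(0L:(3000L - 49L), 500L, replace = TRUE)
  tab <- count_windows(manual_alignments("chr", start), g)
  expect_gte(sum(tab$count), 500L)
})
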