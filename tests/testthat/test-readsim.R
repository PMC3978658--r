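test_that("uniform occupancy gives uniform fragment starts", {
  g <- random_genome(c(chr = 50000L), 7L)
  cfg <- library_config(n_fragments = 5000L)
  flat <- occupancy_profile()
  p_ok <- vapply(1:20, function(s) {
    fr <- sample_fragments(g, flat, cfg, s)
    counts <- table(cut(fr$start, breaks = seq(0, 50000, length.out = 11),
                        include.lowest = TRUE))
    stats::chisq.test(as.integer(counts))$p.value
  }, numeric(1))
  expect_gte(sum(p_ok > 0.01), 18L)
})

test_that("fold enrichment controls the fragment fraction from a feature", {
  g <- random_genome(c(chr = 400000L), 8L)
  prof <- occupancy_profile(data.frame(chrom = "chr", start = 180000L,
                                       end = 220000L, fold = 10))
  cfg <- library_config(n_fragments = 20000L)
  fr <- sample_fragments(g, prof, cfg, 42L)
  frac <- mean(fr$start >= 180000L & fr$start < 220000L)
  expect_lt(abs(frac - (10 * 40) / (10 * 40 + 360)), 0.02)
})

test_that("zero fragments and empty genomes are handled", {
  g <- random_genome(c(chr = 1000L), 1L)
  cfg0 <- library_config(n_fragments = 0L)
  expect_equal(nrow(sample_fragments(g, occupancy_profile(), cfg0, 1L)), 0L)
  expect_error(sample_fragments(character(0), occupancy_profile(),
                                library_config(10L), 1L), "empty")
})

test_that("error-free reads reproduce the genomic substring on either strand", {
  g <- random_genome(c(chr = 20000L), 3L)
  cfg <- library_config(n_fragments = 500L, error_rate = 0)
  fr <- sample_fragments(g, occupancy_profile(), cfg, 5L)
  rs <- fragments_to_reads(fr, g, cfg, 6L)
  expect_true(all(nchar(rs$seq) == 49L))
  ref <- substr(rep(g[["chr"]], nrow(rs)), rs$origin_start + 1L,
                rs$origin_start + 49L)
  expected <- ifelse(rs$origin_strand == "+", ref, revcomp(ref))
  expect_identical(rs$seq, expected)
})

test_that("substitution errors occur at the configured rate", {
  g <- random_genome(c(chr = 30000L), 4L)
  cfg <- library_config(n_fragments = 10000L, error_rate = 0.01)
  fr <- sample_fragments(g, occupancy_profile(), cfg, 7L)
  rs <- fragments_to_reads(fr, g, cfg, 8L)
  ref <- substr(rep(g[["chr"]], nrow(rs)), rs$origin_start + 1L,
                rs$origin_start + 49L)
  ref <- ifelse(rs$origin_strand == "+", ref, revcomp(ref))
  mm <- mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)),
               rs$seq, ref, USE.NAMES = FALSE)
  observed <- sum(mm) / (49 * nrow(rs))
  expect_lt(abs(observed - 0.01), 0.002)
})

test_that("fragments shorter than the read length are skipped and counted", {
  g <- random_genome(c(chr = 5000L), 5L)
  fr <- data.frame(chrom = "chr", start = c(0L, 100L, 200L),
                   end = c(49L, 130L, 400L))
  cfg <- library_config(n_fragments = 3L, error_rate = 0)
  rs <- fragments_to_reads(fr, g, cfg, 9L)
  expect_equal(nrow(rs), 2L)
  expect_equal(attr(rs, "n_skipped"), 1L)
})

test_that("artifact injection respects rates and rule arithmetic", {
  g <- random_genome(c(chr = 20000L), 6L)
  cfg0 <- library_config(n_fragments = 200L, error_rate = 0)
  fr <- sample_fragments(g, occupancy_profile(), cfg0, 10L)
  rs <- fragments_to_reads(fr, g, cfg0, 11L)

  expect_identical(inject_artifacts(rs, cfg0, 12L), rs)

  cfg <- library_config(n_fragments = 200L, error_rate = 0,
                        adapter_rate = 0.2, n_rate = 0.2, lowq_rate = 0.2)
  art <- inject_artifacts(rs, cfg, 13L)
  ns <- art[art$artifact == "n_content", ]
  expect_gt(nrow(ns), 0L)
  n_count <- nchar(ns$seq) - nchar(gsub("N", "", ns$seq, fixed = TRUE))
  expect_true(all(n_count >= 3L)) # 3/49 = 6.1% > 5%
  lq <- art[art$artifact == "low_quality", ]
  expect_gt(nrow(lq), 0L)
  lowq <- vapply(lq$qual, function(q) sum(utf8ToInt(q) < 43L), numeric(1))
  expect_true(all(lowq >= 10L)) # 10/49 = 20.4% > 20%
  ad <- art[art$artifact == "adapter", ]
  expect_gt(nrow(ad), 0L)
  expect_true(all(startsWith(ad$seq, cfg$adapter)))
})

test_that("FASTQ output round-trips", {
  g <- random_genome(c(chr = 5000L), 7L)
  cfg <- library_config(n_fragments = 50L)
  rs <- simulate_library(g, occupancy_profile(), cfg, 14L)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(rs, fq)
  back <- read_fastq(fq)
  expect_identical(back$id, rs$id)
  expect_identical(back$seq, rs$seq)
  expect_identical(back$qual, rs$qual)
})

test_that("library simulation is seed-deterministic", {
  g <- random_genome(c(chr = 10000L), 8L)
  cfg <- library_config(n_fragments = 500L, adapter_rate = 0.05,
                        n_rate = 0.05, lowq_rate = 0.05)
  a <- simulate_library(g, occupancy_profile(), cfg, 99L)
  b <- simulate_library(g, occupancy_profile(), cfg, 99L)
  expect_identical(a, b)
  c <- simulate_library(g, occupancy_profile(), cfg, 100L)
  expect_false(identical(a$seq, c$seq))
})
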