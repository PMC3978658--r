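test_that("seed partitions follow the pigeonhole scheme", {
  cfg <- mapping_config(max_mismatches = 2L, read_length = 49L)
  expect_equal(cfg$partitions, c(17L, 16L, 16L))
  expect_equal(sum(cfg$partitions), 49L)
  cfg1 <- mapping_config(max_mismatches = 1L, read_length = 49L)
  expect_equal(cfg1$partitions, c(25L, 24L))
  expect_error(mapping_config(max_mismatches = -1L), "max_mismatches")
})

test_that("exact reads map uniquely to their origin", {
  g <- random_genome(c(chrA = 8000L, chrB = 6000L), 31L)
  read <- substr(g[["chrB"]], 1001L, 1049L)
  hits <- find_best_hits(read, g)[[1]]
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$chrom, "chrB")
  expect_equal(hits$start, 1000L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0L)

  expect_error(find_best_hits(read, character(0)), "empty")
})

test_that("mapping the reverse complement mirrors the coordinates", {
  g <- random_genome(c(chr = 10000L), 32L)
  read <- substr(g[["chr"]], 501L, 549L)
  fwd <- find_best_hits(read, g)[[1]]
  rev <- find_best_hits(revcomp(read), g)[[1]]
  expect_equal(rev$start, fwd$start)
  expect_equal(fwd$strand, "+")
  expect_equal(rev$strand, "-")
})

test_that("best stratum equals the brute-force Hamming scan", {
  set.seed(77)
  for (rep in 1:3) {
    g <- random_genome(c(chrA = 15000L, chrB = 15000L), 40L + rep)
    reads <- vapply(1:50, function(i) {
      chrom <- sample(names(g), 1L)
      s <- sample.int(nchar(g[[chrom]]) - 49L, 1L)
      r <- substr(g[[chrom]], s, s + 48L)
      if (runif(1) < 0.5) r <- revcomp(r)
      substitute_at(r, sample(0:48, sample(0:2, 1L)))
    }, "")
    hits <- find_best_hits(reads, g)
    for (i in seq_along(reads)) {
      expect_identical(sort_hits(hits[[i]]),
                       sort_hits(brute_best_hits(reads[i], g)))
    }
  }
})

test_that("N bases count as mismatches and reads beyond the budget drop out", {
  g <- random_genome(c(chr = 5000L), 33L)
  read <- substr(g[["chr"]], 2001L, 2049L)
  r2 <- read
  substr(r2, 5L, 5L) <- "N"
  substr(r2, 25L, 25L) <- "N"
  h2 <- find_best_hits(r2, g)[[1]]
  expect_equal(h2$start, 2000L)
  expect_equal(h2$mismatches, 2L)
  r3 <- r2
  substr(r3, 45L, 45L) <- "N"
  expect_identical(sort_hits(find_best_hits(r3, g)[[1]]),
                   sort_hits(brute_best_hits(r3, g)))
})

test_that("multi-mappers are split uniformly between identical loci", {
  set.seed(5)
  core <- paste(sample(c("A", "C", "G", "T"), 5000L, TRUE), collapse = "")
  seg <- substr(core, 1001L, 1200L)
  g <- c(chr = paste0(core, seg)) # second identical copy at 5000
  reads <- vapply(1:1000, function(i) {
    s <- sample(1000:1151, 1L)
    substr(g[["chr"]], s + 1L, s + 49L)
  }, "")
  aln <- map_library(reads, g, rng_seed = 8L)
  expect_true(all(aln$alignments$multiplicity == 2L))
  first <- sum(aln$alignments$start < 4000L)
  expect_lt(abs(first - 500), 3 * sqrt(250))
})

test_that("library mapping statistics are consistent and deterministic", {
  g <- random_genome(c(chr = 20000L), 34L)
  cfg0 <- library_config(n_fragments = 1000L, error_rate = 0)
  rs <- simulate_library(g, occupancy_profile(), cfg0, 51L)
  aln <- map_library(rs, g, rng_seed = 52L)
  s <- aln$stats
  expect_equal(unname(s[["mapped"]] + s[["unmapped"]]), unname(s[["total"]]))
  expect_equal(unname(s[["unique"]] + s[["multi"]]), unname(s[["mapped"]]))
  # error-free reads from unique sequence: >= 99% unique to the origin
  a <- aln$alignments
  i <- match(a$read_id, rs$id)
  agree <- a$start == rs$origin_start[i] & a$chrom == rs$origin_chrom[i]
  expect_gte(mean(agree), 0.99)

  aln2 <- map_library(rs, g, rng_seed = 52L)
  expect_identical(aln$alignments, aln2$alignments)

  empty <- map_library(character(0), g)
  expect_equal(unname(empty$stats[["total"]]), 0L)
  expect_equal(nrow(empty$alignments), 0L)
})

test_that("SAM and BED exports carry the mapping columns", {
  g <- random_genome(c(chr = 2000L), 35L)
  reads <- c(a = substr(g[["chr"]], 101L, 149L),
             b = revcomp(substr(g[["chr"]], 501L, 549L)))
  aln <- map_library(reads, g, rng_seed = 1L)
  sam <- tempfile(fileext = ".sam")
  write_sam(aln, g, sam)
  lines <- readLines(sam)
  body <- lines[!startsWith(lines, "@")]
  expect_equal(length(body), 2L)
  f <- strsplit(body, "\t")
  flags <- vapply(f, function(x) as.integer(x[2]), integer(1))
  poss <- vapply(f, function(x) as.integer(x[4]), integer(1))
  expect_setequal(flags, c(0L, 16L))
  expect_setequal(poss, c(101L, 501L))
  expect_true(all(grepl("NM:i:0", body)))

  bed <- tempfile(fileext = ".bed")
  alignments_to_bed(aln, bed)
  bd <- read.table(bed, sep = "\t")
  expect_equal(bd$V3 - bd$V2, c(49L, 49L))
})
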