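test_that("repeat units have the requested length and base composition", {
  spec <- repeat_family_spec(unit_length = 177L, unit_at_fraction = 0.5,
                             copy_count = 1L, per_copy_divergence = 0)
  unit <- make_repeat_unit(spec, 1L)
  expect_equal(nchar(unit), 177L)
  expect_true(grepl("^[ACGT]+$", unit))

  one <- repeat_family_spec(unit_length = 1L, unit_at_fraction = 1,
                            copy_count = 1L, per_copy_divergence = 0)
  expect_true(make_repeat_unit(one, 5L) %in% c("A", "T"))

  # binomial sampling: mean AT fraction over seeds near the target
  spec <- repeat_family_spec(unit_length = 1000L, unit_at_fraction = 0.7,
                             copy_count = 1L, per_copy_divergence = 0)
  at <- vapply(1:20, function(s) {
    u <- make_repeat_unit(spec, s)
    mean(strsplit(u, "")[[1]] %in% c("A", "T"))
  }, numeric(1))
  expect_lt(abs(mean(at) - 0.7), 0.03)

  expect_error(repeat_family_spec(unit_at_fraction = 1.2), "fraction")
  expect_error(repeat_family_spec(unit_length = 0), "unit_length")
})

test_that("repeat arrays concatenate mutated copies with tracked identity", {
  spec <- repeat_family_spec(unit_length = 177L, copy_count = 240L,
                             per_copy_divergence = 0)
  unit <- make_repeat_unit(spec, 2L)

  arr0 <- build_repeat_array(unit, 3L, 0, 3L)
  expect_equal(arr0$sequence, strrep(unit, 3))
  expect_equal(arr0$identity, rep(100, 3))

  arr <- build_repeat_array(unit, 240L, 0.04, 4L)
  expect_equal(nchar(arr$sequence), 177L * 240L)

  # expected identity 96% under the substitution-only divergence model
  arr50 <- build_repeat_array(unit, 50L, 0.04, 5L)
  expect_lt(abs(mean(arr50$identity) - 96), 1)
})

test_that("chromosome builds insert features and emit matching truth", {
  cen <- repeat_family_spec(unit_length = 100L, copy_count = 20L,
                            per_copy_divergence = 0.02)
  plain <- chromosome_spec("c1", 20000L, cen, 5000L)
  b <- build_chromosome(plain, 11L)
  expect_equal(nchar(b$sequence), 20000L)
  expect_equal(nrow(b$truth), 1L)
  expect_equal(b$truth$label, "centromere")
  expect_equal(c(b$truth$start, b$truth$end), c(5000L, 7000L))

  dup_exact <- chromosome_spec("c2", 20000L, cen, 5000L, duplicates = list(
    list(src_start = 5200L, src_end = 6000L, dest_start = 12000L,
         identity = 100)))
  b2 <- build_chromosome(dup_exact, 12L)
  expect_equal(substr(b2$sequence, 12001L, 12800L),
               substr(b2$sequence, 5201L, 6000L))

  # planted 92% identity over the 1,208 bp false-positive interval scale,
  # verified by a direct Hamming recount
  dup92 <- chromosome_spec("c3", 20000L, cen, 5000L, duplicates = list(
    list(src_start = 5000L, src_end = 6208L, dest_start = 12000L,
         identity = 92)))
  b3 <- build_chromosome(dup92, 13L)
  src <- strsplit(substr(b3$sequence, 5001L, 6208L), "")[[1]]
  dst <- strsplit(substr(b3$sequence, 12001L, 13208L), "")[[1]]
  expect_lt(abs(100 * mean(src == dst) - 92), 1)
  expect_equal(b3$truth$identity[b3$truth$label == "duplicate_copy"],
               100 * mean(src == dst))

  expect_error(chromosome_spec("c4", 20000L, cen, 5000L, duplicates = list(
    list(src_start = 5000L, src_end = 6000L, dest_start = 6500L,
         identity = 100))), "overlap")
  expect_error(chromosome_spec("c5", 6000L, cen, 5000L), "outside")
})

test_that("minichromosome builds are palindromic around the inversion point", {
  b <- build_minichromosome(minichromosome_spec(), 21L)
  expect_equal(nchar(b$sequence), 42529L)

  check_palindrome <- function(seq, ip) {
    n <- nchar(seq)
    span <- min(ip, n - ip)
    left <- substr(seq, ip - span + 1L, ip)
    right <- substr(seq, ip + 1L, ip + span)
    identical(left, revcomp(right))
  }
  expect_true(check_palindrome(b$sequence, 42529L %/% 2L))

  # brute-force check on a tiny instance
  tiny <- build_minichromosome(
    minichromosome_spec(unit_length = 4L, total_length = 16L,
                        inversion_point = 8L), 3L)
  s <- strsplit(tiny$sequence, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in 0:7) expect_identical(s[8 - i], unname(comp[s[9 + i]]))

  expect_error(minichromosome_spec(unit_length = 177L, total_length = 300L),
               "twice")
})

test_that("genome FASTA/BED output round-trips and is seed-deterministic", {
  cen <- repeat_family_spec(unit_length = 50L, copy_count = 10L,
                            per_copy_divergence = 0.05)
  specs <- list(chromosome_spec("chrA", 5000L, cen, 1000L),
                chromosome_spec("chrB", 5000L, cen, 2000L))
  build <- build_genome(specs, minichromosome = NULL, rng_seed = 9L)
  fa <- tempfile(fileext = ".fasta")
  bed <- tempfile(fileext = ".bed")
  write_genome(build, fa, bed)

  back <- read_genome_fasta(fa)
  expect_equal(length(back), 2L)
  expect_identical(unname(back), unname(build$seqs))
  expect_equal(length(readLines(bed)), nrow(build$truth))

  bed_df <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(bed_df$V2, build$truth$start)
  expect_equal(bed_df$V3, build$truth$end)

  build2 <- build_genome(specs, minichromosome = NULL, rng_seed = 9L)
  expect_identical(build$seqs, build2$seqs)
  build3 <- build_genome(specs, minichromosome = NULL, rng_seed = 10L)
  expect_false(identical(build$seqs, build3$seqs))
})

test_that("centromere array AT content tracks the configured fraction", {
  cen <- repeat_family_spec(unit_length = 177L, unit_at_fraction = 0.7,
                            copy_count = 60L, per_copy_divergence = 0.04)
  spec <- chromosome_spec("chr1", 30000L, cen, 10000L)
  b <- build_chromosome(spec, 31L)
  arr <- substr(b$sequence, 10001L, 10000L + 177L * 60L)
  at <- mean(strsplit(arr, "")[[1]] %in% c("A", "T"))
  expect_lt(abs(at - 0.7), 0.03)
})
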