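revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

test_that("canonical k-mer counting matches hand enumeration", {
  # "ACGT" at k = 3 yields ACG and CGT, which are reverse complements of
  # each other, so both canonicalise to ACG: one distinct k-mer at depth 2.
  h <- count_kmers("ACGT", k = 3)
  expect_equal(nrow(h), 1)
  expect_equal(h$depth, 2L)
  expect_equal(h$n_kmers, 1L)
  expect_equal(attr(h, "total_kmers"), 2)

  # "AACCC" at k = 3: AAC, ACC, CCC; canonical forms AAC (< GTT),
  # ACC (< GGT), CCC (< GGG) are all distinct, each depth 1
  h2 <- count_kmers("AACCC", k = 3)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$depth, 1L)
  expect_equal(h2$n_kmers, 3L)
})

test_that("count_kmers validates its inputs", {
  expect_error(count_kmers(character(0)), "empty")
  expect_error(count_kmers("ACGTACGTACGT", k = 4), "odd")
  expect_error(count_kmers("ACGT", k = 27), "between")
})

test_that("a read and its reverse complement collapse onto one strand", {
  read <- "ACGGTTAACCGGTACGATCA"
  h1 <- count_kmers(read, k = 11)
  h2 <- count_kmers(c(read, revcomp(read)), k = 11)
  expect_equal(h2$depth, 2 * h1$depth)
  expect_equal(sum(h2$n_kmers), sum(h1$n_kmers))
})

test_that("k-mers spanning an N are skipped", {
  read <- "ACGTTGCACCA"
  with_n <- sub("T", "N", read)
  h <- count_kmers(c(read, with_n), k = 11)
  expect_equal(attr(h, "total_kmers"), 1)  # only the clean read counts
})

test_that("genome size estimation follows the histogram algebra", {
  # every k-mer at depth 30, 3e6 counted k-mers -> 1e5 bp
  ideal <- tibble::tibble(depth = 30L, n_kmers = 1e5)
  est <- estimate_genome_size(ideal)
  expect_equal(est$genome_size_bp, 1e5)
  expect_equal(est$peak_depth, 30L)
  expect_equal(est$error_cutoff, 0L)

  # an error spike at depth 1-2 is cut at the local minimum and does not
  # move the size estimate
  spiked <- tibble::tibble(depth = c(1L, 2L, 3L, 29L, 30L, 31L),
                           n_kmers = c(5e4, 1e4, 100, 2e4, 6e4, 2e4))
  est2 <- estimate_genome_size(spiked)
  expect_gte(est2$error_cutoff, 2L)
  expect_lt(est2$error_cutoff, 29L)
  expect_equal(est2$peak_depth, 30L)
  clean <- estimate_genome_size(spiked[4:6, ])
  expect_equal(est2$genome_size_bp, clean$genome_size_bp)

  # monotone-decreasing histogram has no coverage peak
  noisy <- tibble::tibble(depth = 1:5,
                          n_kmers = c(1e5, 5e4, 2e4, 1e4, 5e3))
  expect_error(estimate_genome_size(noisy), "no coverage peak")
})

test_that("the survey recovers a simulated genome size within 5%", {
  genome <- simulate_genome_sequence(1e5, seed = 21)
  reads <- simulate_reads(genome, coverage = 30, read_length = 150,
                          seed = 22)
  expect_lt(abs(nrow(reads) - 20000), 2)  # coverage arithmetic
  est <- estimate_genome_size(count_kmers(reads, k = 17))
  expect_lt(abs(est$genome_size_bp - 1e5) / 1e5, 0.05)

  # invariant to k
  est21 <- estimate_genome_size(count_kmers(reads, k = 21))
  expect_lt(abs(est21$genome_size_bp - est$genome_size_bp) /
              est$genome_size_bp, 0.02)

  # doubling coverage doubles the peak depth, not the size
  reads2 <- simulate_reads(genome, coverage = 60, read_length = 150,
                           seed = 23)
  est2 <- estimate_genome_size(count_kmers(reads2, k = 17))
  expect_lt(abs(est2$genome_size_bp - est$genome_size_bp) /
              est$genome_size_bp, 0.02)
  expect_lt(abs(est2$peak_depth - 2 * est$peak_depth), 0.1 * est2$peak_depth)
})

test_that("read simulation respects its preconditions and seed contract", {
  genome <- simulate_genome_sequence(2000, seed = 1)
  expect_error(simulate_reads(genome, coverage = 0, read_length = 100),
               "coverage")
  expect_error(simulate_reads(genome, coverage = 1, read_length = 5000),
               "exceeds")
  r1 <- simulate_reads(genome, coverage = 3, read_length = 100, seed = 4)
  r2 <- simulate_reads(genome, coverage = 3, read_length = 100, seed = 4)
  expect_identical(r1, r2)
  expect_true(all(nchar(r1$seq) == 100))
})
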