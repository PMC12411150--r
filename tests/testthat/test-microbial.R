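ref_seq <- with_seed_local(55, random_dna(3000))
ref <- microbial_reference("EBV-like", ref_seq, source_id = "synthetic")

mutate_at <- function(read, pos) {
  v <- strsplit(read, "")[[1]]
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  paste(v, collapse = "")
}

revcomp <- function(s)
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))

test_that("ungapped matching honours the mismatch budget on both strands", {
  read <- substr(ref_seq, 501, 550)
  expect_true(read_matches(read, ref, 1))
  expect_true(read_matches(mutate_at(read, 7), ref, 1))
  expect_false(read_matches(mutate_at(read, c(7, 30)), ref, 1))
  expect_true(read_matches(mutate_at(read, c(7, 30)), ref, 2))
  expect_true(read_matches(revcomp(read), ref, 0))
  expect_error(read_matches("", ref), "empty")
  expect_error(read_matches(strrep("A", 4000), ref), "longer")
})

test_that("N never matches, in read or reference", {
  r <- microbial_reference("x", "ACGTNACGT")
  expect_true(read_matches("ACGT", r, 0))
  expect_false(read_matches("GTNAC", r, 0))    # N-vs-N is still a mismatch
  expect_true(read_matches("GTNAC", r, 1))     # one budget spent on the N
  expect_false(read_matches("NNNNN", r, 4))
})

test_that("matched counts are monotone in the mismatch budget", {
  set.seed(9)
  reads <- c(spike_microbial_reads(4, ref, 0, seed = 1),
             spike_microbial_reads(4, ref, 1, seed = 2),
             spike_microbial_reads(4, ref, 2, seed = 3))
  counts <- vapply(0:3, function(mm)
    screen_sample(reads, ref, screen_params(max_mismatches = mm))$matched_read_count,
    integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 4L)
  expect_equal(counts[2], 8L)
  expect_equal(counts[3], 12L)
})

test_that("five matching reads flag a sample, four do not", {
  reads5 <- spike_microbial_reads(5, ref, 0, seed = 11)
  r5 <- screen_sample(reads5, ref)
  expect_equal(r5$matched_read_count, 5L)
  expect_true(r5$positive)

  reads4 <- spike_microbial_reads(4, ref, 0, seed = 11)
  r4 <- screen_sample(reads4, ref)
  expect_equal(r4$matched_read_count, 4L)
  expect_false(r4$positive)

  # two-mismatch reads are never counted at the default budget
  far <- spike_microbial_reads(10, ref, 2, seed = 12)
  expect_equal(screen_sample(far, ref)$matched_read_count, 0L)

  # empty read set
  r0 <- screen_sample(character(0), ref)
  expect_equal(r0$matched_read_count, 0L)
  expect_false(r0$positive)
})

test_that("the screen is invariant to read order and strand", {
  reads <- c(spike_microbial_reads(6, ref, 0, seed = 21),
             with_seed_local(22, replicate(6, random_dna(100))))
  base <- screen_sample(reads, ref)$matched_read_count
  expect_equal(screen_sample(rev(reads), ref)$matched_read_count, base)
  flipped <- vapply(reads, revcomp, character(1))
  expect_equal(screen_sample(flipped, ref)$matched_read_count, base)
})

test_that("the indexed scan agrees with the naive oracle on random fixtures", {
  set.seed(77)
  small_ref <- random_dna(400)
  for (r in 1:40) {
    read <- if (r %% 2 == 0) {
      s <- sample(350, 1)
      mutate_at(substr(small_ref, s, s + 39), sample(40, sample(0:2, 1)))
    } else random_dna(40)
    mm <- sample(0:2, 1)
    expect_identical(read_matches(read, small_ref, mm),
                     oracle_read_matches(read, small_ref, mm))
  }
})

test_that("spiked matching reads are counted exactly against background", {
  set.seed(5)
  bg_ref <- random_dna(10000)
  for (k in c(0, 3, 7)) {
    reads <- c(spike_microbial_reads(k, ref, 0, seed = k + 1),
               with_seed_local(k + 50, replicate(20, {
                 s <- sample(9900, 1); substr(bg_ref, s, s + 99)
               })))
    expect_equal(screen_sample(reads, ref)$matched_read_count, as.integer(k))
  }
})

test_that("FASTA/FASTQ read sets and references round-trip through files", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  reads <- spike_microbial_reads(5, ref, 0, seed = 31)
  write_reads_fastq(reads, fq)
  res <- screen_sample(fq, ref)
  expect_equal(res$matched_read_count, 5L)
  expect_true(res$positive)

  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">EBV-like synthetic", ref_seq), fa)
  ref2 <- read_reference_fasta(fa, label = "EBV-like")
  expect_equal(ref2$sequence, ref_seq)
  expect_equal(screen_sample(reads, ref2)$matched_read_count, 5L)
})
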