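mk_segs <- function(mean, n_bins, chrom = "chr1", start_bin = 1) {
  data.frame(chrom = chrom, start = 0, end = n_bins * 2e5,
             start_bin = start_bin, end_bin = start_bin + n_bins,
             n_bins = n_bins, seg_mean = mean, abs_seg_mean = abs(mean),
             p_value = 0.01, stringsAsFactors = FALSE)
}

test_that("gain/loss calls need both magnitude and length", {
  th <- call_control()
  expect_equal(call_segments(mk_segs(5, 60), th)$call, "gain")
  expect_equal(call_segments(mk_segs(-4, 10), th)$call, "neutral")
  expect_equal(call_segments(mk_segs(0, 60), th)$call, "neutral")
  expect_equal(call_segments(mk_segs(-4, 60), th)$call, "loss")
  # boundary: exactly z_gain and exactly min_event_bins qualifies
  expect_equal(call_segments(mk_segs(3, 50), th)$call, "gain")
  expect_equal(call_segments(mk_segs(3, 49), th)$call, "neutral")
})

test_that("raising the gain threshold never creates a new gain call", {
  set.seed(31)
  for (r in 1:20) {
    seg <- mk_segs(runif(1, -6, 6), sample(30:80, 1))
    calls <- vapply(c(2, 3, 4, 5), function(zg)
      call_segments(seg, call_control(z_gain = zg))$call, character(1))
    gains <- calls == "gain"
    expect_true(all(diff(gains) <= 0))   # monotone: once lost, never regained
  }
})

test_that("CIN status, aberrant fraction and aberrant arms follow the rule", {
  grid <- toy_grid(2)
  pr <- as_profile(rep(0, nrow(grid)), grid, sample_id = "s1")
  qc_ok <- qc_sample(pr)
  th <- call_control(exclude_chroms = character(0))

  # no called segments -> CIN-negative
  segs <- call_segments(mk_segs(0.5, 150), th)
  r0 <- call_cin(segs, th, qc_ok, pr)
  expect_equal(r0$status, "CIN-negative")
  expect_equal(r0$aberrant_fraction, 0)
  expect_equal(nrow(r0$aberrant_arms), 0)

  # a whole-arm gain: chr1 p arm is bins 1..75
  segs1 <- call_segments(rbind(mk_segs(5, 75),
                               mk_segs(0, 225, start_bin = 76)), th)
  r1 <- call_cin(segs1, th, qc_ok, pr)
  expect_equal(r1$status, "CIN-positive")
  expect_equal(r1$aberrant_fraction, 75 / 300)
  expect_equal(r1$aberrant_arms,
               data.frame(arm = "1p", direction = "gain",
                          stringsAsFactors = FALSE))

  # QC-failed samples carry no calls
  z_noisy <- rep(c(1, -1), length.out = nrow(grid))
  pr_bad <- as_profile(z_noisy, grid, sample_id = "bad")
  qc_bad <- qc_sample(pr_bad)
  expect_false(qc_bad$passed)
  rqc <- call_cin(segs1, th, qc_bad, pr_bad)
  expect_equal(rqc$status, "QC-failed")
  expect_true(is.na(rqc$aberrant_fraction))
})

test_that("excluded chromosomes never drive CIN status", {
  g <- genome_definition(c("chr1", "chrX"), c(3e7, 3e7), c(1.5e7, 1.5e7))
  grid <- make_bins(g, 2e5)
  pr <- as_profile(rep(0, nrow(grid)), grid)
  qc_ok <- qc_sample(pr)
  # a called gain spanning all of chrX only
  segs <- call_segments(mk_segs(6, 150, chrom = "chrX", start_bin = 151),
                        call_control())
  r <- call_cin(segs, call_control(), qc_ok, pr)
  expect_equal(r$status, "CIN-negative")
})

test_that("arm frequencies count evaluable samples with each direction", {
  grid <- toy_grid(2)
  pr <- as_profile(rep(0, nrow(grid)), grid)
  qc_ok <- qc_sample(pr)
  th <- call_control(exclude_chroms = character(0))
  gain13 <- call_cin(call_segments(mk_segs(5, 75), th), th, qc_ok, pr)
  flat <- call_cin(call_segments(mk_segs(0, 300), th), th, qc_ok, pr)
  res <- list(gain13, gain13, gain13, flat)
  af <- summarize_arms(res, grid)
  expect_equal(af$gain_freq[af$arm == "1p"], 0.75)
  expect_true(all(af$loss_freq == 0))
  # no calls anywhere -> all zero
  af0 <- summarize_arms(list(flat), grid)
  expect_true(all(af0$gain_freq == 0) && all(af0$loss_freq == 0))
  expect_error(summarize_arms(list(), grid), "evaluable")
})

test_that("gene calls take the dominant overlapping segment, ties to neutral", {
  grid <- toy_grid(1)
  pr <- as_profile(rep(0, nrow(grid)), grid)
  th <- call_control(min_event_bins = 5)
  # segments: gain over bins 1..10, neutral 11..150
  segs <- call_segments(rbind(mk_segs(5, 10),
                              mk_segs(0, 140, start_bin = 11)), th)
  gene_in_gain <- data.frame(symbol = "G1", chrom = "chr1",
                             start = 2e5, end = 6e5)
  expect_equal(unname(annotate_genes(segs, gene_in_gain, pr)), "amplified")

  # larger overlap with the neutral side wins
  spanning <- data.frame(symbol = "G2", chrom = "chr1",
                         start = 1.8e6, end = 3e6)   # 1 gain bin, 5 neutral
  expect_equal(unname(annotate_genes(segs, spanning, pr)), "neutral")

  # equal overlap, conflicting calls -> neutral
  segs2 <- call_segments(rbind(mk_segs(5, 10),
                               mk_segs(-5, 10, start_bin = 11),
                               mk_segs(0, 130, start_bin = 21)), th)
  tied <- data.frame(symbol = "G3", chrom = "chr1",
                     start = 1.8e6, end = 2.2e6)     # 1 bin each side
  expect_equal(unname(annotate_genes(segs2, tied, pr)), "neutral")

  # gene on unusable bins only -> not evaluable
  z <- rep(0, nrow(grid)); z[1:3] <- NA
  pr_mask <- as_profile(z, grid)
  head_gene <- data.frame(symbol = "G4", chrom = "chr1", start = 0, end = 4e5)
  expect_equal(unname(annotate_genes(segs, head_gene, pr_mask)),
               "not-evaluable")
})

test_that("planted event direction is always recovered on noise-free input", {
  grid <- toy_grid(1, len = 4e7)
  th <- call_control()
  for (sign in c(1, -1)) {
    z <- rep(0, 200); z[51:120] <- sign * 4
    pr <- as_profile(z, grid)
    segs <- call_segments(
      segment_profile(pr, seg_control(n_permutations = 100, seed = 5)), th)
    ev <- segs[segs$call != "neutral", ]
    expect_equal(nrow(ev), 1)
    expect_equal(ev$call, if (sign > 0) "gain" else "loss")
  }
})
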