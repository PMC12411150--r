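grid3 <- make_bins(genome_definition("chr1", 6e5, 3e5), 2e5)

test_that("baseline mean/sd and usability flags follow the control matrix", {
  cm <- rbind(c(100, 100, 100),   # zero variance -> unusable
              c(90, 110, 100),
              c(0, 0, 0))         # zero mean -> unusable
  bl <- build_baseline(cm, grid3)
  expect_equal(bl$mean, c(100, 100, 0))
  expect_equal(bl$sd[2], sd(c(90, 110, 100)))
  expect_equal(bl$usable, c(FALSE, TRUE, FALSE))
  # two-point sd example
  bl2 <- build_baseline(cbind(c(90, 90, 90), c(110, 110, 110)), grid3)
  expect_equal(bl2$mean, rep(100, 3))
  expect_equal(bl2$sd, rep(14.142, 3), tolerance = 1e-4)
  expect_error(build_baseline(matrix(1:3, ncol = 1), grid3), "2 control")
  expect_error(build_baseline(matrix(1, 2, 2), grid3), "rows")
})

test_that("z and log2 ratio apply the control formula, masking unusable bins", {
  cm <- cbind(c(90, 100, 100), c(110, 100, 100))
  bl <- build_baseline(cm, grid3)            # bins 2,3 unusable (sd 0)
  pr <- normalize_sample(c(120, 5, 5), bl)
  expect_equal(pr$z[1], (120 - 100) / bl$sd[1])
  expect_true(all(is.na(pr$z[2:3])))
  expect_true(all(is.na(pr$log2_ratio[2:3])))

  grid1 <- make_bins(genome_definition("chr1", 2e5, 1e5), 2e5)
  bl1 <- build_baseline(matrix(c(90, 100, 110), 1, 3), grid1)  # mean 100, sd 10
  expect_equal(normalize_sample(120, bl1)$z, 2.0, tolerance = 1e-12)
  expect_equal(normalize_sample(100, bl1)$z, 0)
  expect_equal(normalize_sample(100, bl1)$log2_ratio, 0)
  expect_equal(normalize_sample(50, bl1)$log2_ratio, -1)
  # zero coverage: z from the raw 0, log ratio from a 0.5 pseudocount
  pr0 <- normalize_sample(0, bl1)
  expect_equal(pr0$z, -10)
  expect_equal(pr0$log2_ratio, log2(0.5 / 100))
})

test_that("z is exactly invariant when sample and controls share a scale factor", {
  grid <- toy_grid(1)
  sim <- simulate_cohort(grid, sim_config(seed = 2, n_controls = 6))
  x <- sim$controls[, 1] + 3
  bl <- build_baseline(sim$controls, grid)
  bl_scaled <- build_baseline(sim$controls * 7, grid)
  expect_equal(normalize_sample(x * 7, bl_scaled)$z,
               normalize_sample(x, bl)$z, tolerance = 1e-12)
})

test_that("a held-out control normalizes to near-zero mean z", {
  grid <- toy_grid(2)
  sim <- simulate_cohort(grid, sim_config(seed = 8, n_controls = 21,
                                          depth_mean = 200))
  bl <- build_baseline(sim$controls[, -1], grid)   # leave one out
  pr <- normalize_sample(sim$controls[, 1], bl)
  expect_lt(abs(mean(pr$z, na.rm = TRUE)), 0.2)
})

test_that("the QC statistic is the median absolute adjacent difference", {
  grid <- toy_grid(1)
  n <- nrow(grid)
  flat <- as_profile(rep(0.2, n), grid)
  q <- qc_sample(flat)
  expect_equal(q$statistic, 0)
  expect_true(q$passed)

  zig <- as_profile(rep(c(0.5, -0.5), length.out = n), grid)
  qz <- qc_sample(zig)
  expect_equal(qz$statistic, 1.0)
  expect_false(qz$passed)

  # adjacency never crosses chromosomes: a step at a chromosome boundary
  # contributes nothing
  g2 <- toy_grid(2)
  stepped <- as_profile(rep(c(0, 5), each = nrow(g2) / 2), g2)
  expect_equal(qc_sample(stepped)$statistic, 0)
})

test_that("a boundary statistic of exactly 0.38 passes (strictly-exceeds rule)", {
  grid <- toy_grid(1)
  n <- nrow(grid)
  lr <- rep(0, n); lr[seq(2, n, by = 2)] <- 0.38   # |diffs| all 0.38
  pr <- as_profile(lr, grid)
  q <- qc_sample(pr)
  expect_equal(q$statistic, 0.38)
  expect_true(q$passed)
  expect_false(qc_sample(pr, threshold = 0.379)$passed)
})

test_that("the QC statistic grows with per-bin jitter and gates accordingly", {
  grid <- toy_grid(1)
  cfg0 <- sim_config(seed = 4, n_controls = 10)
  sim <- simulate_cohort(grid, cfg0)
  bl <- build_baseline(sim$controls, grid)
  base <- shallowCNA:::bin_baseline(grid, cfg0)
  stats <- vapply(c(0, 0.25, 0.5), function(s) {
    median(vapply(1:20, function(r) {
      x <- withr::with_seed(100 * s + r, {
        jit <- 2^rnorm(nrow(grid), 0, s)
        rnbinom(nrow(grid), mu = base * jit, size = cfg0$dispersion)
      })
      qc_sample(normalize_sample(x, bl))$statistic
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(stats) > 0))
  expect_lt(stats[1], 0.38)   # clean samples pass
  expect_gt(stats[3], 0.38)   # sd-0.5 jitter fails
})

test_that("QC needs at least one adjacent usable pair", {
  grid <- toy_grid(1)
  z <- rep(NA_real_, nrow(grid)); z[3] <- 0   # a single usable bin
  pr <- as_profile(z, grid)
  expect_error(qc_sample(pr), "adjacent")
})

test_that("bin-count TSVs round-trip against a grid", {
  grid <- toy_grid(1)
  sim <- simulate_cohort(grid, sim_config(seed = 3, n_controls = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(chrom = grid$chrom, start = grid$start,
                         end = grid$end, sim$controls),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- read_bin_counts(path, grid)
  expect_equal(unname(m), unname(sim$controls))
})
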