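#' Simulation configuration for synthetic shallow-WGS cohorts
#'
#' The simulator draws per-bin read counts from a negative binomial
#' distribution around a shared per-bin baseline. The baseline is
#' log-normal across bins (`bin_effect_sd`), mimicking the stable
#' mappability/GC structure that all samples of a sequencing batch share;
#' the negative binomial (`variance = mu + mu^2 / dispersion`) carries the
#' sample-to-sample counting noise. Case samples multiply the baseline by
#' `purity * c/2 + (1 - purity)` inside planted events with `c` total
#' copies, i.e. a tumor of the given purity diluted by diploid tissue.
#'
#' @param seed integer master seed; every sample derives its own
#'   substream from it, so adding samples never reshuffles existing ones.
#' @param n_controls number of control samples (>= 2, a baseline standard
#'   deviation must exist).
#' @param depth_mean expected reads per bin (production shallow WGS at
#'   10M read pairs is roughly 650 reads per 200-kb bin; desk-scale
#'   defaults run lower).
#' @param dispersion negative-binomial size parameter.
#' @param bin_effect_sd standard deviation (natural-log scale) of the
#'   shared per-bin baseline effects.
#' @param noise_inflation multiplier > 1 controlling the QC-failure mode:
#'   failing samples receive independent per-bin multiplicative jitter
#'   `2^N(0, log2(noise_inflation))`. The default `sqrt(2)` gives log2
#'   jitter sd 0.5.
#' @param purity tumor fraction in `[0, 1]` applied to planted events.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_controls = 20L, depth_mean = 200,
                       dispersion = 50, bin_effect_sd = 0.1,
                       noise_inflation = sqrt(2), purity = 1.0) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  if (n_controls < 2) stop("n_controls must be >= 2")
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (bin_effect_sd < 0) stop("bin_effect_sd must be >= 0")
  if (purity < 0 || purity > 1) stop("purity must be in [0, 1]")
  structure(list(seed = seed, n_controls = as.integer(n_controls),
                 depth_mean = depth_mean, dispersion = dispersion,
                 bin_effect_sd = bin_effect_sd,
                 noise_inflation = noise_inflation, purity = purity),
            class = "sim_config")
}

# Deterministic substream seed: mixes the master seed with a stream index
# so per-sample draws are independent of cohort size; result fits in a
# 32-bit signed integer.
substream_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1103515245 + as.double(stream) * 12820163 +
                12345) %% 2147483647)
}

# Evaluate a function with a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Shared per-bin baseline expectations (log-normal around depth_mean).
bin_baseline <- function(grid, config) {
  with_seed(substream_seed(config$seed, 0L), {
    n <- nrow(grid)
    config$depth_mean *
      exp(stats::rnorm(n, 0, config$bin_effect_sd) - config$bin_effect_sd^2 / 2)
  })
}

# Per-bin copy factor purity*c/2 + (1-purity) from an event list.
# events: data.frame/list rows with chrom, start, end, total_copies.
copy_factor <- function(grid, events, purity) {
  f <- rep(1, nrow(grid))
  if (is.null(events) || length(events) == 0L) return(f)
  ev <- as.data.frame(do.call(rbind, lapply(events, function(e)
    data.frame(chrom = e$chrom, start = as.numeric(e$start),
               end = as.numeric(e$end),
               total_copies = as.numeric(e$total_copies),
               stringsAsFactors = FALSE))))
  genome <- attr(grid, "genome")
  for (k in seq_len(nrow(ev))) {
    g <- match(ev$chrom[k], genome$chrom)
    if (is.na(g)) stop("event on unknown chromosome: ", ev$chrom[k])
    if (ev$start[k] >= ev$end[k]) stop("event start must be < end")
    if (ev$start[k] < 0 || ev$end[k] > genome$length[g])
      stop("event outside chromosome: ", ev$chrom[k])
    if (ev$total_copies[k] < 0) stop("total_copies must be >= 0")
  }
  for (ch in unique(ev$chrom)) {
    sub <- ev[ev$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop("overlapping events within one sample on ", ch)
  }
  for (k in seq_len(nrow(ev))) {
    idx <- which(grid$chrom == ev$chrom[k] &
                 grid$start < ev$end[k] & grid$end > ev$start[k])
    f[idx] <- purity * ev$total_copies[k] / 2 + (1 - purity)
  }
  f
}

#' Simulate a control cohort and case samples with planted events
#'
#' Control counts are negative-binomial draws around the shared per-bin
#' baseline; each case multiplies the baseline by the purity-diluted copy
#' factor of its planted events before drawing. The returned ground truth
#' records, per case, the event list and the expected log2 copy ratio per
#' bin (`log2(purity * c/2 + (1 - purity))` inside events, 0 elsewhere).
#'
#' @param grid a [make_bins()] grid.
#' @param config a [sim_config()].
#' @param case_specs a list of per-case event lists; each event is a list
#'   with `chrom`, `start`, `end`, `total_copies` (2 = neutral).
#' @return A list with `controls` (bins x samples count matrix), `cases`
#'   (bins x cases, or NULL), and `truth` (events, `expected_log2`
#'   matrix, `qc_mode` flags, `microbial` spike counts).
#' @examples
#' g <- genome_definition(c("a", "b"), c(2e6, 2e6), c(1e6, 1e6))
#' grid <- make_bins(g, 2e5)
#' sim <- simulate_cohort(grid, sim_config(seed = 7, n_controls = 4),
#'   case_specs = list(list(list(chrom = "a", start = 0, end = 1e6,
#'                               total_copies = 4))))
#' @export
simulate_cohort <- function(grid, config, case_specs = list()) {
  stopifnot(inherits(grid, "bin_grid"), inherits(config, "sim_config"))
  n <- nrow(grid)
  base <- bin_baseline(grid, config)
  controls <- vapply(seq_len(config$n_controls), function(k) {
    with_seed(substream_seed(config$seed, k),
              stats::rnbinom(n, mu = base, size = config$dispersion))
  }, numeric(n))
  colnames(controls) <- sprintf("control_%02d", seq_len(config$n_controls))

  n_cases <- length(case_specs)
  cases <- NULL
  expected_log2 <- NULL
  if (n_cases > 0) {
    factors <- vapply(case_specs, copy_factor, numeric(n), grid = grid,
                      purity = config$purity)
    cases <- vapply(seq_len(n_cases), function(s) {
      with_seed(substream_seed(config$seed, 100000L + s),
                stats::rnbinom(n, mu = base * factors[, s],
                               size = config$dispersion))
    }, numeric(n))
    colnames(cases) <- sprintf("case_%02d", seq_len(n_cases))
    expected_log2 <- log2(factors)
    expected_log2[factors == 0] <- -Inf
    colnames(expected_log2) <- colnames(cases)
  }
  list(controls = controls, cases = cases,
       truth = list(events = case_specs, expected_log2 = expected_log2,
                    qc_mode = rep(FALSE, n_cases),
                    microbial = rep(0L, n_cases)))
}

#' Simulate a sample noisy enough to fail the adjacent-bin QC gate
#'
#' Draws a diploid sample like a control but with independent per-bin
#' multiplicative jitter `2^N(0, log2(noise_inflation))` on the expected
#' counts. At the default `noise_inflation = sqrt(2)` (log2 jitter sd
#' 0.5) the adjacent-bin QC statistic concentrates near
#' `0.6745 * 0.5 * sqrt(2) ~= 0.48`, well above the 0.38 gate.
#'
#' @param grid a [make_bins()] grid.
#' @param config a [sim_config()] with `noise_inflation > 1`.
#' @param stream substream index offsetting the RNG, so several failing
#'   samples can be drawn from one config.
#' @return Integer-valued count vector, one entry per bin.
#' @export
make_qc_failure_sample <- function(grid, config, stream = 1L) {
  stopifnot(inherits(grid, "bin_grid"), inherits(config, "sim_config"))
  if (config$noise_inflation <= 1)
    stop("noise_inflation must be > 1 for the QC-failure mode")
  n <- nrow(grid)
  base <- bin_baseline(grid, config)
  sd_log2 <- log2(config$noise_inflation)
  with_seed(substream_seed(config$seed, 900000L + as.integer(stream)), {
    jitter <- 2^stats::rnorm(n, 0, sd_log2)
    stats::rnbinom(n, mu = base * jitter, size = config$dispersion)
  })
}

#' Plant microbial reads drawn from a reference sequence
#'
#' Extracts substrings of the reference at random positions and applies
#' exactly `mismatches_per_read` substitutions at distinct random
#' positions (always to a different base), for spiking into a sample's
#' read set.
#'
#' @param n_reads number of reads to generate.
#' @param reference a [microbial_reference()] or a plain nucleotide
#'   string.
#' @param mismatches_per_read substitutions planted per read.
#' @param read_length read length in bp (default 100).
#' @param seed RNG seed (the caller's RNG state is restored afterwards).
#' @return Character vector of read sequences.
#' @export
spike_microbial_reads <- function(n_reads, reference, mismatches_per_read = 0L,
                                  read_length = 100L, seed = 1L) {
  seqc <- if (inherits(reference, "microbial_reference"))
    reference$sequence else as.character(reference)
  L <- nchar(seqc)
  if (read_length > L) stop("read length exceeds reference length")
  if (mismatches_per_read < 0) stop("mismatches_per_read must be >= 0")
  if (mismatches_per_read > read_length)
    stop("cannot plant more mismatches than read positions")
  if (n_reads == 0) return(character(0))
  bases <- c("A", "C", "G", "T")
  with_seed(as.integer(seed), {
    vapply(seq_len(n_reads), function(i) {
      s <- sample.int(L - read_length + 1L, 1L)
      rd <- strsplit(substr(seqc, s, s + read_length - 1L), "")[[1]]
      if (mismatches_per_read > 0) {
        pos <- sample.int(read_length, mismatches_per_read)
        for (p in pos) rd[p] <- sample(setdiff(bases, rd[p]), 1L)
      }
      paste(rd, collapse = "")
    }, character(1))
  })
}
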