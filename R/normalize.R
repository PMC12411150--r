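#' Build the per-bin control baseline
#'
#' For every bin, the mean and (n-1 denominator) standard deviation of
#' the raw control coverage; bins with zero variance or zero mean carry
#' no information for standardization and are flagged unusable.
#'
#' @param control_matrix numeric matrix, bins x control samples, one row
#'   per grid bin.
#' @param grid a [make_bins()] grid with `nrow(grid) == nrow(control_matrix)`.
#' @return A list of class `"control_baseline"` with `mean`, `sd`,
#'   `usable`, `n_controls`, and the grid.
#' @export
build_baseline <- function(control_matrix, grid) {
  control_matrix <- as.matrix(control_matrix)
  if (!inherits(grid, "bin_grid")) stop("grid must be a bin_grid")
  if (nrow(control_matrix) != nrow(grid))
    stop("control matrix has ", nrow(control_matrix),
         " rows but grid has ", nrow(grid), " bins")
  if (ncol(control_matrix) < 2) stop("need at least 2 control samples")
  if (any(!is.finite(control_matrix)) || any(control_matrix < 0))
    stop("control counts must be finite and non-negative")
  m <- rowMeans(control_matrix)
  s <- apply(control_matrix, 1, stats::sd)
  structure(list(mean = m, sd = s, usable = s > 0 & m > 0,
                 n_controls = ncol(control_matrix), grid = grid),
            class = "control_baseline")
}

#' Normalize one sample against the control baseline
#'
#' Computes, per usable bin, the standardized score
#' `z = (coverage_raw - mean(controls)) / sd(controls)` and the copy
#' ratio `log2(coverage_raw / mean(controls))`. A zero count at a usable
#' bin keeps `z` from the raw 0 but takes its log ratio from a 0.5-read
#' pseudocount, avoiding `-Inf`. Unusable bins are carried as `NA`,
#' never as zero.
#'
#' @param sample numeric vector of raw per-bin coverage, or a one-column
#'   matrix; length must match the baseline's grid.
#' @param baseline a [build_baseline()] object.
#' @param sample_id sample label carried into reports.
#' @return A list of class `"normalized_profile"` with `sample_id`, `z`,
#'   `log2_ratio`, `raw`, `usable`, and the grid.
#' @export
normalize_sample <- function(sample, baseline, sample_id = "sample") {
  if (!inherits(baseline, "control_baseline"))
    stop("baseline must come from build_baseline()")
  x <- as.numeric(sample)
  if (length(x) != length(baseline$mean))
    stop("sample has ", length(x), " bins, baseline has ",
         length(baseline$mean))
  if (any(!is.finite(x)) || any(x < 0))
    stop("sample coverage must be finite and non-negative")
  usable <- baseline$usable
  if (!any(usable)) stop("all bins unusable in baseline")
  z <- rep(NA_real_, length(x))
  lr <- rep(NA_real_, length(x))
  z[usable] <- (x[usable] - baseline$mean[usable]) / baseline$sd[usable]
  xu <- x[usable]
  xu[xu == 0] <- 0.5                      # pseudocount for the log ratio only
  lr[usable] <- log2(xu / baseline$mean[usable])
  structure(list(sample_id = sample_id, z = z, log2_ratio = lr, raw = x,
                 usable = usable, grid = baseline$grid),
            class = "normalized_profile")
}

#' Wrap a precomputed per-bin signal as a normalized profile
#'
#' For callers that bring their own standardized signal (or for null
#' studies on synthetic Gaussian profiles): builds the profile object
#' [segment_profile()] and [qc_sample()] operate on without a control
#' baseline.
#'
#' @param z numeric per-bin signal, one value per grid bin.
#' @param grid a [make_bins()] grid.
#' @param sample_id sample label.
#' @param log2_ratio optional log2 copy-ratio vector; defaults to `z`.
#' @param usable optional logical mask; defaults to the finite entries
#'   of `z`.
#' @return A `"normalized_profile"` object.
#' @export
as_profile <- function(z, grid, sample_id = "sample", log2_ratio = NULL,
                       usable = NULL) {
  if (!inherits(grid, "bin_grid")) stop("grid must be a bin_grid")
  z <- as.numeric(z)
  if (length(z) != nrow(grid)) stop("z length must match the grid")
  if (is.null(usable)) usable <- is.finite(z)
  if (is.null(log2_ratio)) log2_ratio <- z
  structure(list(sample_id = sample_id, z = z, log2_ratio = log2_ratio,
                 raw = rep(NA_real_, length(z)), usable = usable,
                 grid = grid),
            class = "normalized_profile")
}

#' Sample quality gate from adjacent-bin log-ratio noise
#'
#' The statistic is the median, over all within-chromosome pairs of
#' adjacent usable bins, of the absolute difference of the log2 copy
#' ratio. A flat or smoothly segmented genome gives a small value; FFPE
#' degradation or library failure inflates bin-to-bin scatter and drives
#' it up. A sample passes while the statistic does not exceed the
#' threshold (a value of exactly 0.38 passes).
#'
#' @param profile a [normalize_sample()] profile.
#' @param threshold gate value (default 0.38).
#' @param ratio which log ratio scale the gate uses: `"log2"` (default)
#'   or `"ln"`.
#' @param method `"median_abs_diff"` (default): median of |first
#'   differences|; `"mad_of_diff"`: median absolute deviation about the
#'   median of the differences (alternative reading, `stats::mad` with
#'   constant 1).
#' @return A list of class `"qc_report"` with `statistic`, `threshold`,
#'   `passed`, `n_pairs`, `sample_id`.
#' @export
qc_sample <- function(profile, threshold = 0.38,
                      ratio = c("log2", "ln"),
                      method = c("median_abs_diff", "mad_of_diff")) {
  if (!inherits(profile, "normalized_profile"))
    stop("profile must come from normalize_sample()")
  ratio <- match.arg(ratio)
  method <- match.arg(method)
  lr <- profile$log2_ratio
  if (ratio == "ln") lr <- lr * log(2)
  diffs <- unlist(lapply(split(seq_along(lr), profile$grid$chrom), function(idx) {
    v <- lr[idx][profile$usable[idx]]
    if (length(v) >= 2) diff(v) else numeric(0)
  }), use.names = FALSE)
  if (length(diffs) == 0L)
    stop("too few usable bins to form any adjacent pair")
  statistic <- if (method == "median_abs_diff")
    stats::median(abs(diffs)) else stats::mad(diffs, constant = 1)
  structure(list(statistic = statistic, threshold = threshold,
                 passed = statistic <= threshold, n_pairs = length(diffs),
                 sample_id = profile$sample_id),
            class = "qc_report")
}

#' Read a bin-count TSV
#'
#' Expects header columns `chrom`, `start`, `end` followed by one column
#' per sample, rows in grid order.
#'
#' @param path path to the TSV.
#' @param grid optional [make_bins()] grid to validate against.
#' @return Numeric matrix bins x samples (sample names from the header).
#' @export
read_bin_counts <- function(path, grid = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(d)))
    stop("bin-count TSV needs columns chrom, start, end")
  if (!is.null(grid)) {
    if (nrow(d) != nrow(grid) || any(d$chrom != grid$chrom) ||
        any(d$start != grid$start))
      stop("bin-count TSV does not match the grid")
  }
  m <- as.matrix(d[, setdiff(names(d), need), drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Write a normalized profile as TSV
#'
#' @param profile a [normalize_sample()] profile.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_profile <- function(profile, path) {
  g <- profile$grid
  d <- data.frame(chrom = g$chrom, start = g$start, end = g$end,
                  raw = profile$raw, z = round(profile$z, 6),
                  log2_ratio = round(profile$log2_ratio, 6),
                  usable = profile$usable)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count read starts per bin from a coordinate-sorted alignment file
#'
#' Optional front-end for callers holding BAM rather than count tables:
#' counts primary alignments with mapping quality at or above `min_mapq`
#' by read-start position. Requires the Rsamtools package.
#'
#' @param bam_path path to an indexed, coordinate-sorted BAM.
#' @param grid a [make_bins()] grid; chromosome names must match the BAM.
#' @param min_mapq minimum mapping quality (default 20).
#' @return Numeric vector of counts, one per bin.
#' @export
bin_counts_from_bam <- function(bam_path, grid, min_mapq = 20) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("bin_counts_from_bam() requires the Rsamtools package")
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flag, what = c("rname", "pos", "mapq"))
  b <- Rsamtools::scanBam(bam_path, param = p)[[1]]
  keep <- !is.na(b$mapq) & b$mapq >= min_mapq & !is.na(b$pos)
  rn <- as.character(b$rname)[keep]
  pos0 <- b$pos[keep] - 1L                 # BAM pos is 1-based
  counts <- numeric(nrow(grid))
  for (ch in unique(grid$chrom)) {
    idx <- which(grid$chrom == ch)
    p0 <- pos0[rn == ch]
    if (length(p0) == 0) next
    k <- findInterval(p0, grid$start[idx])   # bins are contiguous per chrom
    k <- k[k >= 1 & p0 < max(grid$end[idx])]
    counts[idx] <- tabulate(k, nbins = length(idx))
  }
  counts
}
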