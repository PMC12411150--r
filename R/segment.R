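#' Segmentation parameters
#'
#' Controls the circular binary segmentation recursion: a candidate split
#' is accepted when its full-shuffle permutation p-value falls below
#' `alpha` and every resulting piece holds at least `min_seg_bins` bins.
#'
#' @param alpha significance level for accepting a split (default 0.05).
#' @param n_permutations permutations per tested split (default 1000,
#'   minimum 100).
#' @param min_seg_bins minimum bins per segment (default 3).
#' @param max_depth recursion depth bound (default 20).
#' @param merge_tol merge adjacent segments whose means differ by less
#'   than this after the recursion; 0 disables merging (default).
#' @param seed optional integer seed set once before segmenting a
#'   profile, making the permutation stream reproducible.
#' @return A validated list of class `"seg_params"`.
#' @export
seg_control <- function(alpha = 0.05, n_permutations = 1000L,
                        min_seg_bins = 3L, max_depth = 20L,
                        merge_tol = 0, seed = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  if (min_seg_bins < 1) stop("min_seg_bins must be >= 1")
  if (max_depth < 1) stop("max_depth must be >= 1")
  if (merge_tol < 0) stop("merge_tol must be >= 0")
  structure(list(alpha = alpha, n_permutations = as.integer(n_permutations),
                 min_seg_bins = as.integer(min_seg_bins),
                 max_depth = as.integer(max_depth), merge_tol = merge_tol,
                 seed = seed),
            class = "seg_params")
}

#' Best circular split of a signal
#'
#' Treats the signal as a circle and finds the arc `(i, j]` (0-based
#' boundaries, arc = elements `i+1 .. j`) maximizing the pooled-variance
#' two-sample t statistic between the arc and its complement, with both
#' parts at least `min_seg_bins` long. Ties are broken toward smaller
#' `i`, then smaller `j`. When the pooled variance is (numerically)
#' zero, a split separating unequal means scores `T = Inf`; a constant
#' signal scores `T = 0` and reports the first feasible arc.
#'
#' @param signal numeric vector, length at least `2 * min_seg_bins`.
#' @param min_seg_bins minimum bins on each side of the split.
#' @return A list with `i`, `j` (integer boundaries) and `t`.
#' @export
cbs_split_statistic <- function(signal, min_seg_bins = 3L) {
  x <- as.numeric(signal)
  if (any(!is.finite(x))) stop("signal must be finite")
  if (length(x) < 2 * min_seg_bins)
    stop("signal shorter than 2 * min_seg_bins")
  cpp_best_arc(x, as.integer(min_seg_bins))
}

#' Permutation p-value for an observed split statistic
#'
#' Fully shuffles the signal `n_permutations` times, recomputes the
#' maximal arc statistic each time, and applies the add-one rule
#' `p = (1 + #\{max T >= T_obs\}) / (1 + n_permutations)`. Shuffles draw
#' from R's RNG, so `set.seed()` (or `seg_control(seed = )` upstream)
#' makes the value reproducible.
#'
#' @param signal numeric vector under test.
#' @param t_observed the observed maximal arc statistic.
#' @param params a [seg_control()] object.
#' @return The permutation p-value in `(0, 1]`.
#' @export
permutation_p <- function(signal, t_observed, params = seg_control()) {
  stopifnot(inherits(params, "seg_params"))
  x <- as.numeric(signal)
  if (length(x) < 2 * params$min_seg_bins)
    stop("signal shorter than 2 * min_seg_bins")
  cpp_permutation_p(x, t_observed, params$n_permutations, params$min_seg_bins)
}

# Recursive circular binary segmentation of one chromosome's signal.
# Returns a data.frame of (lo, hi, p) over 1-based inclusive positions in
# the signal vector; p is the p-value of the split that created the piece
# (1 for an unsplit root).
cbs_recurse <- function(x, params, depth = 1L, p_created = 1) {
  n <- length(x)
  leaf <- data.frame(lo = 1L, hi = n, p = p_created)
  if (n < 2 * params$min_seg_bins || depth > params$max_depth) return(leaf)
  sp <- cpp_best_arc(x, params$min_seg_bins)
  if (sp$t <= 0) return(leaf)
  p <- cpp_permutation_p(x, sp$t, params$n_permutations, params$min_seg_bins)
  if (p >= params$alpha) return(leaf)
  cuts <- c(sp$i, sp$j)                  # boundaries inside (0, n)
  cuts <- cuts[cuts > 0 & cuts < n]
  bounds <- c(0L, cuts, n)
  sizes <- diff(bounds)
  if (any(sizes < params$min_seg_bins)) return(leaf)   # reject edge slivers
  out <- lapply(seq_along(sizes), function(k) {
    lo <- bounds[k] + 1L; hi <- bounds[k + 1L]
    piece <- cbs_recurse(x[lo:hi], params, depth + 1L, p)
    piece$lo <- piece$lo + lo - 1L
    piece$hi <- piece$hi + lo - 1L
    piece
  })
  do.call(rbind, out)
}

#' Segment a normalized profile with circular binary segmentation
#'
#' Per chromosome, unusable bins are dropped, the Z-score signal is
#' recursively split by the best circular arc statistic whenever the
#' permutation p-value clears `alpha`, and adjacent segments closer than
#' `merge_tol` in mean are merged back. Segment coordinates are mapped
#' back to genomic bp through the grid; `n_bins` counts the usable bins
#' a segment summarizes, and `seg_mean` is the mean Z over them.
#'
#' @param profile a [normalize_sample()] profile.
#' @param params a [seg_control()] object.
#' @param signal which per-bin statistic to segment: `"z"` (default,
#'   the standardized coverage) or `"log2_ratio"`.
#' @return A `data.frame` of class `"cn_segments"`: `chrom`, `start`,
#'   `end` (bp, 0-based half-open), `start_bin`, `end_bin` (grid row
#'   indices, half-open), `n_bins`, `seg_mean`, `abs_seg_mean`,
#'   `p_value`, plus the `sample_id` attribute.
#' @export
segment_profile <- function(profile, params = seg_control(),
                            signal = c("z", "log2_ratio")) {
  if (!inherits(profile, "normalized_profile"))
    stop("profile must come from normalize_sample()")
  stopifnot(inherits(params, "seg_params"))
  signal <- match.arg(signal)
  if (!is.null(params$seed)) set.seed(params$seed)
  vals <- profile[[signal]]
  grid <- profile$grid
  out <- list()
  for (ch in unique(grid$chrom)) {
    idx <- which(grid$chrom == ch & profile$usable)
    if (length(idx) == 0L) next
    x <- vals[idx]
    segs <- if (length(x) == 1L)
      data.frame(lo = 1L, hi = 1L, p = 1) else cbs_recurse(x, params)
    segs$mean <- vapply(seq_len(nrow(segs)), function(k)
      mean(x[segs$lo[k]:segs$hi[k]]), numeric(1))
    if (params$merge_tol > 0 && nrow(segs) > 1) {
      k <- 1L
      while (k < nrow(segs)) {
        if (abs(segs$mean[k + 1L] - segs$mean[k]) < params$merge_tol) {
          lo <- segs$lo[k]; hi <- segs$hi[k + 1L]
          segs$lo[k] <- lo; segs$hi[k] <- hi
          segs$mean[k] <- mean(x[lo:hi])
          segs$p[k] <- min(segs$p[k], segs$p[k + 1L])
          segs <- segs[-(k + 1L), , drop = FALSE]
        } else k <- k + 1L
      }
    }
    out[[ch]] <- data.frame(
      chrom = ch,
      start = grid$start[idx[segs$lo]],
      end = grid$end[idx[segs$hi]],
      start_bin = idx[segs$lo],
      end_bin = idx[segs$hi] + 1L,
      n_bins = segs$hi - segs$lo + 1L,
      seg_mean = segs$mean,
      abs_seg_mean = abs(segs$mean),
      p_value = segs$p,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) stop("profile has no usable bins")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "sample_id") <- profile$sample_id
  attr(res, "signal") <- signal
  class(res) <- c("cn_segments", "data.frame")
  res
}

#' Write segments in SEG format
#'
#' SEG is the tab-separated dialect used by segmentation viewers:
#' `ID, chrom, loc.start, loc.end, num.mark, seg.mean` with 1-based
#' inclusive coordinates (converted from the internal 0-based half-open
#' frame).
#'
#' @param segments a [segment_profile()] result.
#' @param path output path.
#' @param sample_id sample label; defaults to the one on `segments`.
#' @return Invisibly, the path.
#' @export
write_seg <- function(segments, path, sample_id = NULL) {
  if (is.null(sample_id)) sample_id <- attr(segments, "sample_id")
  d <- data.frame(ID = sample_id, chrom = segments$chrom,
                  loc.start = segments$start + 1L, loc.end = segments$end,
                  num.mark = segments$n_bins,
                  seg.mean = round(segments$seg_mean, 6))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write segment calls as BED (0-based half-open)
#'
#' @param segments a [segment_profile()] result, optionally carrying a
#'   `call` column from [call_segments()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_bed <- function(segments, path) {
  name <- if (!is.null(segments$call)) segments$call else "segment"
  d <- data.frame(chrom = segments$chrom, start = segments$start,
                  end = segments$end, name = name,
                  score = round(segments$seg_mean, 6))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
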