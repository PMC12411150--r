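#' Calling thresholds for gains, losses and CIN status
#'
#' The pipeline calls a segment by the magnitude of its mean Z-score and
#' its length, then declares a sample CIN-positive when it carries at
#' least one called segment and the called fraction of its usable genome
#' reaches `cin_min_aberrant_fraction`. Defaults make a whole-arm event
#' (tens of Mb at |Z| >= 3) CIN-positive while leaving flat profiles
#' negative; every threshold is surfaced here and recorded in reports.
#'
#' @param z_gain minimum segment mean (Z units) for a gain (default +3).
#' @param z_loss maximum segment mean for a loss (default -3).
#' @param min_event_bins minimum usable bins per called segment
#'   (default 50, i.e. 10 Mb of 200-kb bins).
#' @param cin_min_aberrant_fraction minimum called fraction of the
#'   usable genome for CIN-positivity (default 0: any qualifying event).
#' @param arm_coverage_fraction a chromosome arm is reported aberrant
#'   when called segments of one direction cover more than this fraction
#'   of its usable bins (default 0.5).
#' @param exclude_chroms chromosomes ignored by CIN status and arm
#'   summaries (default `"chrX"`: mixed-sex cohorts make X dosage a
#'   confound).
#' @return A validated list of class `"call_params"`.
#' @export
call_control <- function(z_gain = 3, z_loss = -3, min_event_bins = 50L,
                         cin_min_aberrant_fraction = 0,
                         arm_coverage_fraction = 0.5,
                         exclude_chroms = "chrX") {
  if (!(z_loss < 0 && 0 < z_gain)) stop("need z_loss < 0 < z_gain")
  if (min_event_bins < 1) stop("min_event_bins must be >= 1")
  if (cin_min_aberrant_fraction < 0 || cin_min_aberrant_fraction > 1)
    stop("cin_min_aberrant_fraction must be in [0, 1]")
  if (arm_coverage_fraction <= 0 || arm_coverage_fraction >= 1)
    stop("arm_coverage_fraction must be in (0, 1)")
  structure(list(z_gain = z_gain, z_loss = z_loss,
                 min_event_bins = as.integer(min_event_bins),
                 cin_min_aberrant_fraction = cin_min_aberrant_fraction,
                 arm_coverage_fraction = arm_coverage_fraction,
                 exclude_chroms = exclude_chroms),
            class = "call_params")
}

#' Call segments as gain, loss or neutral
#'
#' A segment is a gain when `seg_mean >= z_gain`, a loss when
#' `seg_mean <= z_loss`, in both cases requiring at least
#' `min_event_bins` bins; anything else is neutral.
#'
#' @param segments a [segment_profile()] result for one sample.
#' @param thresholds a [call_control()] object.
#' @return The segments with an added `call` column.
#' @export
call_segments <- function(segments, thresholds = call_control()) {
  stopifnot(inherits(thresholds, "call_params"))
  long <- segments$n_bins >= thresholds$min_event_bins
  call <- rep("neutral", nrow(segments))
  call[long & segments$seg_mean >= thresholds$z_gain] <- "gain"
  call[long & segments$seg_mean <= thresholds$z_loss] <- "loss"
  segments$call <- call
  segments
}

# usable-bin count per (chrom, arm) and per segment/arm overlap
arm_key <- function(chrom, arm) paste0(sub("^chr", "", chrom), arm)

#' Per-sample CIN status from called segments
#'
#' A QC-failed sample is reported as such and carries no calls. Otherwise
#' the sample is CIN-positive when it has at least one gain/loss call and
#' the called fraction of usable bins (excluded chromosomes aside)
#' reaches the configured minimum. Chromosome arms where calls of one
#' direction cover more than `arm_coverage_fraction` of the arm's usable
#' bins are listed as aberrant.
#'
#' @param called segments with a `call` column from [call_segments()].
#' @param thresholds a [call_control()] object.
#' @param qc the sample's [qc_sample()] report.
#' @param profile the sample's [normalize_sample()] profile (supplies
#'   the usable-bin denominator and arm labels).
#' @return A list of class `"cin_result"`: `sample_id`, `status` (one of
#'   `"CIN-positive"`, `"CIN-negative"`, `"QC-failed"`),
#'   `called_segments`, `aberrant_arms` (data.frame `arm`, `direction`),
#'   `aberrant_fraction`, `thresholds`.
#' @export
call_cin <- function(called, thresholds, qc, profile) {
  stopifnot(inherits(thresholds, "call_params"),
            inherits(qc, "qc_report"),
            inherits(profile, "normalized_profile"))
  sample_id <- profile$sample_id
  if (!qc$passed) {
    return(structure(list(sample_id = sample_id, status = "QC-failed",
                          called_segments = NULL,
                          aberrant_arms = data.frame(arm = character(0),
                                                     direction = character(0)),
                          aberrant_fraction = NA_real_,
                          thresholds = thresholds),
                     class = "cin_result"))
  }
  grid <- profile$grid
  keep_chrom <- !(grid$chrom %in% thresholds$exclude_chroms)
  usable <- profile$usable & keep_chrom
  seg <- called[!(called$chrom %in% thresholds$exclude_chroms), , drop = FALSE]
  eventful <- seg[seg$call != "neutral", , drop = FALSE]
  aberrant_bins <- sum(eventful$n_bins)
  frac <- if (sum(usable) > 0) aberrant_bins / sum(usable) else 0
  positive <- nrow(eventful) > 0 && frac >= thresholds$cin_min_aberrant_fraction

  arms <- data.frame(arm = character(0), direction = character(0),
                     stringsAsFactors = FALSE)
  if (nrow(eventful) > 0) {
    keys <- arm_key(grid$chrom, grid$arm)
    for (ak in unique(keys[usable])) {
      arm_idx <- which(usable & keys == ak)
      for (dir in c("gain", "loss")) {
        ev <- eventful[eventful$call == dir, , drop = FALSE]
        if (nrow(ev) == 0) next
        cov <- 0L
        for (k in seq_len(nrow(ev)))
          cov <- cov + sum(arm_idx >= ev$start_bin[k] & arm_idx < ev$end_bin[k])
        if (cov > thresholds$arm_coverage_fraction * length(arm_idx))
          arms <- rbind(arms, data.frame(arm = ak, direction = dir,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(sample_id = sample_id,
                 status = if (positive) "CIN-positive" else "CIN-negative",
                 called_segments = called, aberrant_arms = arms,
                 aberrant_fraction = frac, thresholds = thresholds),
            class = "cin_result")
}

#' Arm-level gain/loss frequencies across a cohort
#'
#' For every chromosome arm, the fraction of CIN-evaluable samples (all
#' except QC failures) whose aberrant-arm list contains that arm with a
#' gain (respectively loss).
#'
#' @param results a list of [call_cin()] results.
#' @param grid the [make_bins()] grid the cohort was analyzed on.
#' @return A `data.frame` with `arm`, `gain_freq`, `loss_freq`.
#' @export
summarize_arms <- function(results, grid) {
  evaluable <- Filter(function(r) r$status != "QC-failed", results)
  if (length(evaluable) == 0L) stop("no evaluable samples")
  arms <- unique(arm_key(grid$chrom, grid$arm))
  gain <- loss <- setNames(numeric(length(arms)), arms)
  for (r in evaluable) {
    aa <- r$aberrant_arms
    if (nrow(aa) > 0) {
      gain[unique(aa$arm[aa$direction == "gain"])] <-
        gain[unique(aa$arm[aa$direction == "gain"])] + 1
      loss[unique(aa$arm[aa$direction == "loss"])] <-
        loss[unique(aa$arm[aa$direction == "loss"])] + 1
    }
  }
  data.frame(arm = arms, gain_freq = unname(gain) / length(evaluable),
             loss_freq = unname(loss) / length(evaluable),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene-level copy-number calls for one sample
#'
#' Each gene takes the call of the overlapping segment with the largest
#' usable-bin overlap; an exact tie between segments with conflicting
#' calls resolves to neutral, and a gene whose locus holds no usable
#' bins is not evaluable.
#'
#' @param called segments with a `call` column from [call_segments()].
#' @param loci gene-locus `data.frame` as from [default_gene_loci()].
#' @param profile the sample's [normalize_sample()] profile.
#' @return A character vector of calls (`"amplified"`, `"lost"`,
#'   `"neutral"`, `"not-evaluable"`) named by gene symbol.
#' @export
annotate_genes <- function(called, loci, profile) {
  grid <- profile$grid
  out <- setNames(rep("not-evaluable", nrow(loci)), loci$symbol)
  for (k in seq_len(nrow(loci))) {
    bins <- gene_bins(loci[k, ], grid)
    bins <- bins[profile$usable[bins]]
    if (length(bins) == 0L) next
    ov <- vapply(seq_len(nrow(called)), function(s)
      sum(bins >= called$start_bin[s] & bins < called$end_bin[s]),
      numeric(1))
    if (all(ov == 0)) next
    best <- which(ov == max(ov))
    calls <- unique(called$call[best])
    g <- if (length(calls) == 1L) calls else "neutral"
    out[k] <- switch(g, gain = "amplified", loss = "lost", "neutral")
  }
  out
}
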