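#' Fit copy-number profiles and CIN status for a cohort
#'
#' The package's front end: takes raw bin counts for case samples and a
#' control cohort, and runs the full model for every case -- control
#' baseline, per-bin Z-scores and log2 copy ratios, the adjacent-bin QC
#' gate, circular binary segmentation of the Z signal, gain/loss
#' calling, per-sample CIN status, and cohort-level arm frequencies and
#' gene calls.
#'
#' @param case_counts numeric matrix (bins x case samples) or vector for
#'   a single case; rows follow the bin grid.
#' @param control_counts numeric matrix (bins x controls), at least two
#'   columns.
#' @param genome a [genome_definition()] (default [hg19_genome()]).
#' @param bin_size bin width in bp (default 200 kb); ignored when `grid`
#'   is supplied.
#' @param grid optionally, a ready-made [make_bins()] grid.
#' @param qc_threshold adjacent-bin gate value (default 0.38).
#' @param seg_params a [seg_control()] object.
#' @param call_params a [call_control()] object.
#' @param gene_loci gene-locus table (default [default_gene_loci()]
#'   when the genome is the bundled one, else none).
#' @param seed optional integer seed for the permutation stream.
#' @return An object of class `"scna"`: a list with `grid`, `baseline`,
#'   `profiles`, `qc`, `segments` (called), `cin`, `arm_freq`,
#'   `gene_calls`, and the parameters used. Methods: [print.scna()],
#'   [summary.scna()], [plot.scna()], [residuals.scna()].
#' @examples
#' g <- genome_definition(c("chr1", "chr2"), c(3e7, 3e7), c(1.5e7, 1.5e7))
#' grid <- make_bins(g, 2e5)
#' sim <- simulate_cohort(grid, sim_config(seed = 3, n_controls = 8),
#'   case_specs = list(list(list(chrom = "chr1", start = 0, end = 1.5e7,
#'                               total_copies = 4))))
#' fit <- scna(sim$cases, sim$controls, grid = grid,
#'             seg_params = seg_control(n_permutations = 100, seed = 1))
#' summary(fit)
#' @export
scna <- function(case_counts, control_counts, genome = hg19_genome(),
                 bin_size = 200000, grid = NULL, qc_threshold = 0.38,
                 seg_params = seg_control(), call_params = call_control(),
                 gene_loci = NULL, seed = NULL) {
  if (is.null(grid)) grid <- make_bins(genome, bin_size)
  if (is.null(dim(case_counts)))
    case_counts <- matrix(case_counts, ncol = 1)
  case_counts <- as.matrix(case_counts)
  if (is.null(colnames(case_counts)))
    colnames(case_counts) <- sprintf("case_%02d", seq_len(ncol(case_counts)))
  if (is.null(gene_loci) &&
      identical(attr(grid, "genome")$chrom, hg19_genome()$chrom))
    gene_loci <- default_gene_loci()
  if (!is.null(seed)) seg_params$seed <- NULL  # one stream for the whole fit
  baseline <- build_baseline(control_counts, grid)
  if (!is.null(seed)) set.seed(as.integer(seed))
  else if (!is.null(seg_params$seed)) set.seed(seg_params$seed)

  ids <- colnames(case_counts)
  profiles <- list(); qc <- list(); segments <- list(); cin <- list()
  gene_calls <- NULL
  for (s in seq_along(ids)) {
    pr <- normalize_sample(case_counts[, s], baseline, sample_id = ids[s])
    rep_qc <- qc_sample(pr, threshold = qc_threshold)
    profiles[[ids[s]]] <- pr
    qc[[ids[s]]] <- rep_qc
    if (rep_qc$passed) {
      sp <- seg_params; sp$seed <- NULL    # stream already seeded
      seg <- call_segments(segment_profile(pr, sp), call_params)
      segments[[ids[s]]] <- seg
      cin[[ids[s]]] <- call_cin(seg, call_params, rep_qc, pr)
      if (!is.null(gene_loci)) {
        gc_row <- annotate_genes(seg, gene_loci, pr)
        gene_calls <- rbind(gene_calls, gc_row)
      }
    } else {
      segments[[ids[s]]] <- NULL
      cin[[ids[s]]] <- call_cin(data.frame(), call_params, rep_qc, pr)
      if (!is.null(gene_loci)) {
        gc_row <- setNames(rep("not-evaluable", nrow(gene_loci)),
                           gene_loci$symbol)
        gene_calls <- rbind(gene_calls, gc_row)
      }
    }
  }
  if (!is.null(gene_calls)) rownames(gene_calls) <- ids
  arm_freq <- if (any(vapply(cin, function(r) r$status != "QC-failed",
                             logical(1))))
    summarize_arms(cin, grid) else NULL
  structure(list(grid = grid, baseline = baseline, profiles = profiles,
                 qc = qc, segments = segments, cin = cin,
                 arm_freq = arm_freq, gene_calls = gene_calls,
                 qc_threshold = qc_threshold, seg_params = seg_params,
                 call_params = call_params, gene_loci = gene_loci,
                 seed = seed),
            class = "scna")
}

#' @export
print.scna <- function(x, ...) {
  st <- vapply(x$cin, function(r) r$status, character(1))
  cat("Shallow-WGS copy-number fit\n")
  cat(sprintf("  bins: %d (%d chromosomes, %.0f kb)\n", nrow(x$grid),
              length(unique(x$grid$chrom)), attr(x$grid, "bin_size") / 1000))
  cat(sprintf("  controls: %d   cases: %d\n", x$baseline$n_controls,
              length(x$profiles)))
  cat(sprintf("  CIN-positive: %d   CIN-negative: %d   QC-failed: %d\n",
              sum(st == "CIN-positive"), sum(st == "CIN-negative"),
              sum(st == "QC-failed")))
  invisible(x)
}

#' Summarize a fitted cohort
#'
#' @param object an [scna()] fit.
#' @param ... unused.
#' @return A list of class `"summary.scna"` with the per-sample status
#'   table, QC statistics, aberrant fractions, and the arm-frequency
#'   matrix.
#' @method summary scna
#' @export
summary.scna <- function(object, ...) {
  st <- vapply(object$cin, function(r) r$status, character(1))
  samples <- data.frame(
    sample_id = names(object$cin),
    status = st,
    qc_statistic = vapply(object$qc, function(q) q$statistic, numeric(1)),
    aberrant_fraction = vapply(object$cin, function(r)
      if (is.na(r$aberrant_fraction)) NA_real_ else r$aberrant_fraction,
      numeric(1)),
    n_aberrant_arms = vapply(object$cin, function(r)
      nrow(r$aberrant_arms), numeric(1)),
    row.names = NULL)
  structure(list(samples = samples, arm_freq = object$arm_freq,
                 gene_calls = object$gene_calls,
                 qc_threshold = object$qc_threshold),
            class = "summary.scna")
}

#' @export
print.summary.scna <- function(x, ...) {
  cat("Per-sample CIN status (QC gate at", x$qc_threshold, "):\n")
  print(x$samples, row.names = FALSE)
  if (!is.null(x$arm_freq)) {
    hot <- x$arm_freq[x$arm_freq$gain_freq > 0 | x$arm_freq$loss_freq > 0, ]
    if (nrow(hot)) {
      cat("\nAberrant arms (cohort frequency):\n")
      print(hot, row.names = FALSE)
    }
  }
  invisible(x)
}

#' Plot one sample's copy-number profile
#'
#' Per-bin Z-scores along the genome with segment means overlaid;
#' called gains red, losses blue.
#'
#' @param x an [scna()] fit.
#' @param sample sample name or index (default first).
#' @param ... passed to [graphics::plot()].
#' @method plot scna
#' @export
plot.scna <- function(x, sample = 1, ...) {
  pr <- x$profiles[[sample]]
  seg <- x$segments[[if (is.numeric(sample)) names(x$profiles)[sample]
                     else sample]]
  idx <- seq_along(pr$z)
  graphics::plot(idx, pr$z, pch = 16, cex = 0.3, col = "grey50",
                 xlab = "bin", ylab = "Z", main = pr$sample_id, ...)
  bnd <- cumsum(table(factor(pr$grid$chrom, levels = unique(pr$grid$chrom))))
  graphics::abline(v = bnd + 0.5, col = "grey85")
  if (!is.null(seg)) {
    cols <- c(gain = "red3", loss = "blue3", neutral = "black")
    graphics::segments(seg$start_bin, seg$seg_mean, seg$end_bin - 1,
                       seg$seg_mean, lwd = 2,
                       col = cols[if (is.null(seg$call)) "neutral" else seg$call])
  }
  invisible(x)
}

#' Residual Z-scores about the fitted segment means
#'
#' @param object an [scna()] fit.
#' @param sample sample name or index (default first).
#' @param ... unused.
#' @return Numeric vector, `NA` on unusable bins and for QC-failed
#'   samples (which have no segmentation).
#' @method residuals scna
#' @export
residuals.scna <- function(object, sample = 1, ...) {
  pr <- object$profiles[[sample]]
  nm <- if (is.numeric(sample)) names(object$profiles)[sample] else sample
  seg <- object$segments[[nm]]
  r <- rep(NA_real_, length(pr$z))
  if (is.null(seg)) return(r)
  for (k in seq_len(nrow(seg))) {
    idx <- seg$start_bin[k]:(seg$end_bin[k] - 1L)
    idx <- idx[pr$usable[idx] & pr$grid$chrom[idx] == seg$chrom[k]]
    r[idx] <- pr$z[idx] - seg$seg_mean[k]
  }
  r
}

#' CIN status vector of a fit
#'
#' @param fit an [scna()] fit.
#' @return Named character vector of per-sample statuses.
#' @export
cin_status <- function(fit) {
  stopifnot(inherits(fit, "scna"))
  vapply(fit$cin, function(r) r$status, character(1))
}
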