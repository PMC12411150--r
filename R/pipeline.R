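#' Pipeline configuration
#'
#' One flat, serializable record of every constant the pipeline uses:
#' the 200-kb bin width, the 0.38 QC gate, the 0.05 split significance,
#' the calling thresholds, the microbial screen's 1-mismatch budget and
#' more-than-four read rule, and the master seed. Round-trips through
#' JSON losslessly (see [write_config()] / [read_config()]).
#'
#' @param bin_size bin width in bp.
#' @param qc_threshold adjacent-bin gate value.
#' @param alpha split significance level.
#' @param n_permutations permutations per tested split.
#' @param min_seg_bins minimum bins per segment.
#' @param merge_tol post-recursion merge tolerance.
#' @param z_gain,z_loss,min_event_bins,cin_min_aberrant_fraction,arm_coverage_fraction,exclude_chroms
#'   calling thresholds, as in [call_control()].
#' @param max_mismatches,min_reads_exclusive microbial screen rule, as
#'   in [screen_params()].
#' @param seed master seed for all randomness.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(bin_size = 200000, qc_threshold = 0.38,
                            alpha = 0.05, n_permutations = 1000L,
                            min_seg_bins = 3L, merge_tol = 0,
                            z_gain = 3, z_loss = -3, min_event_bins = 50L,
                            cin_min_aberrant_fraction = 0,
                            arm_coverage_fraction = 0.5,
                            exclude_chroms = "chrX",
                            max_mismatches = 1L, min_reads_exclusive = 4L,
                            seed = 1L) {
  # constructor validation happens in the component constructors
  sc <- seg_control(alpha = as.numeric(alpha),
                    n_permutations = n_permutations,
                    min_seg_bins = min_seg_bins,
                    merge_tol = as.numeric(merge_tol))
  cc <- call_control(z_gain = as.numeric(z_gain),
                     z_loss = as.numeric(z_loss),
                     min_event_bins = min_event_bins,
                     cin_min_aberrant_fraction =
                       as.numeric(cin_min_aberrant_fraction),
                     arm_coverage_fraction = as.numeric(arm_coverage_fraction),
                     exclude_chroms = exclude_chroms)
  mp <- screen_params(max_mismatches = max_mismatches,
                      min_reads_exclusive = min_reads_exclusive)
  bin_size <- as.numeric(bin_size)
  qc_threshold <- as.numeric(qc_threshold)
  if (bin_size <= 0) stop("bin_size must be positive")
  if (qc_threshold <= 0) stop("qc_threshold must be positive")
  structure(list(bin_size = bin_size, qc_threshold = qc_threshold,
                 alpha = sc$alpha, n_permutations = sc$n_permutations,
                 min_seg_bins = sc$min_seg_bins, merge_tol = sc$merge_tol,
                 z_gain = cc$z_gain, z_loss = cc$z_loss,
                 min_event_bins = cc$min_event_bins,
                 cin_min_aberrant_fraction = cc$cin_min_aberrant_fraction,
                 arm_coverage_fraction = cc$arm_coverage_fraction,
                 exclude_chroms = cc$exclude_chroms,
                 max_mismatches = mp$max_mismatches,
                 min_reads_exclusive = mp$min_reads_exclusive,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a [pipeline_config()].
#' @param path JSON path.
#' @return `write_config` returns the path invisibly; `read_config`
#'   returns the reconstructed [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, v)
}

seg_params_of <- function(config) {
  seg_control(alpha = config$alpha, n_permutations = config$n_permutations,
              min_seg_bins = config$min_seg_bins,
              merge_tol = config$merge_tol)
}

call_params_of <- function(config) {
  call_control(z_gain = config$z_gain, z_loss = config$z_loss,
               min_event_bins = config$min_event_bins,
               cin_min_aberrant_fraction = config$cin_min_aberrant_fraction,
               arm_coverage_fraction = config$arm_coverage_fraction,
               exclude_chroms = config$exclude_chroms)
}

#' Run the full pipeline on bin-count inputs and write a run directory
#'
#' Stages: control baseline, per-sample normalization, QC gate,
#' segmentation, gain/loss and CIN calling, arm and gene summaries,
#' cohort statistics, and optionally the microbial read screen. Every
#' stage's output lands in `out_dir` in plain-text formats, together
#' with a manifest recording the configuration, seed, package version
#' and MD5 of every written file; identical config and inputs give
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param control_counts control matrix (bins x samples) or path to a
#'   bin-count TSV.
#' @param case_counts case matrix or TSV path; may be NULL (baseline
#'   plus an empty cohort report).
#' @param out_dir run directory (created if missing).
#' @param genome a [genome_definition()] (default [hg19_genome()]).
#' @param grid optional ready-made grid overriding `genome`/`bin_size`.
#' @param metadata optional data.frame with `sample_id` and `subtype`
#'   for cohort statistics.
#' @param microbial_reads optional named list of read vectors (or
#'   FASTA/FASTQ paths), screened per sample.
#' @param microbial_reference optional [microbial_reference()] used for
#'   the screen.
#' @param gene_loci gene-locus table; default as in [scna()].
#' @return Invisibly, a list with the [scna()] fit and the manifest.
#' @export
run_pipeline <- function(config, control_counts, case_counts = NULL,
                         out_dir = "scna_run", genome = hg19_genome(),
                         grid = NULL, metadata = NULL,
                         microbial_reads = NULL, microbial_reference = NULL,
                         gene_loci = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(grid)) grid <- make_bins(genome, config$bin_size)
  if (is.character(control_counts))
    control_counts <- read_bin_counts(control_counts, grid)
  if (is.character(case_counts))
    case_counts <- read_bin_counts(case_counts, grid)

  baseline <- build_baseline(control_counts, grid)
  utils::write.table(
    data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
               mean = round(baseline$mean, 6), sd = round(baseline$sd, 6),
               usable = baseline$usable),
    file.path(out_dir, "baseline.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  fit <- NULL
  files <- c("baseline.tsv")
  if (!is.null(case_counts) && ncol(as.matrix(case_counts)) > 0) {
    fit <- scna(case_counts, control_counts, grid = grid,
                qc_threshold = config$qc_threshold,
                seg_params = seg_params_of(config),
                call_params = call_params_of(config),
                gene_loci = gene_loci, seed = config$seed)
    dir.create(file.path(out_dir, "profiles"), showWarnings = FALSE)
    seg_path <- file.path(out_dir, "segments.seg")
    unlink(seg_path)
    first <- TRUE
    for (id in names(fit$profiles)) {
      write_profile(fit$profiles[[id]],
                    file.path(out_dir, "profiles", paste0(id, ".tsv")))
      files <- c(files, file.path("profiles", paste0(id, ".tsv")))
      seg <- fit$segments[[id]]
      if (!is.null(seg)) {
        d <- data.frame(ID = id, chrom = seg$chrom,
                        loc.start = seg$start + 1L, loc.end = seg$end,
                        num.mark = seg$n_bins,
                        seg.mean = round(seg$seg_mean, 6))
        suppressWarnings(utils::write.table(
          d, seg_path, sep = "\t", quote = FALSE, row.names = FALSE,
          col.names = first, append = !first))
        first <- FALSE
        write_bed(seg, file.path(out_dir, "profiles", paste0(id, ".bed")))
        files <- c(files, file.path("profiles", paste0(id, ".bed")))
      }
    }
    if (!first) files <- c(files, "segments.seg")

    qc_json <- lapply(fit$qc, function(q)
      list(sample_id = q$sample_id, statistic = q$statistic,
           threshold = q$threshold, passed = q$passed))
    jsonlite::write_json(qc_json, file.path(out_dir, "qc.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, "qc.json")

    if (!is.null(fit$arm_freq)) {
      utils::write.table(fit$arm_freq, file.path(out_dir, "arm_freq.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, "arm_freq.tsv")
    }
    if (!is.null(fit$gene_calls)) {
      utils::write.table(
        data.frame(sample_id = rownames(fit$gene_calls),
                   fit$gene_calls, check.names = FALSE),
        file.path(out_dir, "gene_calls.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, "gene_calls.tsv")
    }

    report <- lapply(names(fit$cin), function(id) {
      r <- fit$cin[[id]]
      list(sample_id = id, status = r$status,
           aberrant_fraction = r$aberrant_fraction,
           aberrant_arms = r$aberrant_arms,
           qc_statistic = fit$qc[[id]]$statistic,
           thresholds = list(z_gain = config$z_gain, z_loss = config$z_loss,
                             min_event_bins = config$min_event_bins,
                             qc_threshold = config$qc_threshold,
                             alpha = config$alpha))
    })
    jsonlite::write_json(report, file.path(out_dir, "samples.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, "samples.json")
  }

  cohort <- list(n_cases = if (is.null(fit)) 0L else length(fit$profiles))
  if (!is.null(fit) && !is.null(metadata)) {
    st <- cin_status(fit)
    md <- metadata[match(names(st), metadata$sample_id), ]
    tab <- build_cohort_table(unname(st), md$subtype)
    if (nrow(tab) >= 2 && all(colSums(tab) >= 0) &&
        !any(rowSums(tab) == 0) && !all(tab[, 1] == 0) &&
        !all(tab[, 2] == 0)) {
      ct <- try(cohort_test(tab), silent = TRUE)
      if (!inherits(ct, "try-error"))
        cohort$subtype_test <- list(statistic = ct$statistic,
                                    df = ct$degrees_of_freedom,
                                    p_value = ct$p_value,
                                    rows_used = ct$rows_used)
    }
    cohort$table <- as.data.frame.matrix(unclass(tab))
    cohort$dropout <- attr(tab, "dropout")
  }
  jsonlite::write_json(cohort, file.path(out_dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, "cohort.json")

  if (!is.null(microbial_reads) && !is.null(microbial_reference)) {
    screens <- lapply(names(microbial_reads), function(id) {
      res <- screen_sample(microbial_reads[[id]], microbial_reference,
                           screen_params(config$max_mismatches,
                                         config$min_reads_exclusive))
      list(sample_id = id, label = res$label,
           count = res$matched_read_count, positive = res$positive)
    })
    jsonlite::write_json(screens, file.path(out_dir, "microbial.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, "microbial.json")
  }

  manifest <- list(
    package = "shallowCNA",
    version = as.character(utils::packageVersion("shallowCNA")),
    config = unclass(config),
    seed = config$seed,
    files = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fit = fit, manifest = manifest, out_dir = out_dir))
}

#' Simulate a cohort dataset and write it to disk
#'
#' Runs [simulate_cohort()] (plus optional QC-failure samples and
#' microbial spike-ins) and writes control/case bin-count TSVs, the
#' ground-truth JSON, and a FASTQ of spiked reads.
#'
#' @param out_dir dataset directory (created if missing).
#' @param grid a [make_bins()] grid.
#' @param config a [sim_config()].
#' @param case_specs per-case event lists, as in [simulate_cohort()].
#' @param n_qc_failures how many noise-inflated samples to append.
#' @param spike list with `reference` ([microbial_reference()]),
#'   `n_reads`, `mismatches_per_read`; NULL to skip.
#' @return Invisibly, the simulation result with file paths attached.
#' @export
simulate_dataset <- function(out_dir, grid, config, case_specs = list(),
                             n_qc_failures = 0L, spike = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(grid, config, case_specs)
  coords <- data.frame(chrom = grid$chrom, start = grid$start,
                       end = grid$end)
  utils::write.table(cbind(coords, sim$controls),
                     file.path(out_dir, "controls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cases <- sim$cases
  if (n_qc_failures > 0) {
    extra <- vapply(seq_len(n_qc_failures), function(k)
      make_qc_failure_sample(grid, config, stream = k), numeric(nrow(grid)))
    colnames(extra) <- sprintf("qcfail_%02d", seq_len(n_qc_failures))
    cases <- if (is.null(cases)) extra else cbind(cases, extra)
    sim$truth$qc_mode <- c(sim$truth$qc_mode, rep(TRUE, n_qc_failures))
  }
  if (!is.null(cases))
    utils::write.table(cbind(coords, cases),
                       file.path(out_dir, "cases.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(
    events = sim$truth$events,
    expected_log2 = if (is.null(sim$truth$expected_log2)) NULL else
      apply(sim$truth$expected_log2, 2, identity, simplify = FALSE),
    qc_mode = sim$truth$qc_mode,
    microbial = sim$truth$microbial,
    config = unclass(config))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(spike)) {
    reads <- spike_microbial_reads(spike$n_reads, spike$reference,
                                   spike$mismatches_per_read %||% 0L,
                                   seed = config$seed)
    write_reads_fastq(reads, file.path(out_dir, "spikes.fastq"))
  }
  sim$out_dir <- out_dir
  invisible(sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
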