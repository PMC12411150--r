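#' Pearson chi-square test on a contingency table
#'
#' The plain Pearson statistic `sum((O - E)^2 / E)` with expected counts
#' from the row/column margins, no continuity correction, and the upper
#' chi-square tail on `(rows - 1)(cols - 1)` degrees of freedom. Flags
#' (rather than warns about) expected counts below 5.
#'
#' @param counts numeric matrix of non-negative counts, at least 2x2,
#'   with no all-zero row or column.
#' @return A list of class `"chisq_result"`: `statistic`,
#'   `degrees_of_freedom`, `p_value`, `expected_counts`, `min_expected`,
#'   `small_expected` (logical flag).
#' @examples
#' pearson_chi_square(matrix(c(12, 27, 6, 2, 8, 8), nrow = 3, byrow = TRUE))
#' @export
pearson_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("contingency table needs at least 2 rows and 2 columns")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  if (sum(counts) <= 0) stop("grand total must be positive")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate margins: all-zero row or column")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(statistic = unname(ht$statistic),
                 degrees_of_freedom = unname(ht$parameter),
                 p_value = ht$p.value,
                 expected_counts = ht$expected,
                 min_expected = min(ht$expected),
                 small_expected = min(ht$expected) < 5),
            class = "chisq_result")
}

#' Percentage summary of a count
#'
#' `100 * positive / total`, truncated to two decimals -- the convention
#' that reports 12 of 39 as 30.76%.
#'
#' @param positive number of positives, `0 <= positive <= total`.
#' @param total denominator, `> 0`.
#' @return The percentage to two decimals.
#' @examples
#' proportion_summary(12, 39)   # 30.76
#' @export
proportion_summary <- function(positive, total) {
  if (total <= 0) stop("total must be positive")
  if (positive < 0 || positive > total)
    stop("positive must lie in [0, total]")
  floor(100 * positive / total * 100 + 1e-9) / 100
}

#' Assemble the subtype-by-CIN-status contingency table
#'
#' Counts CIN-positive and CIN-negative samples per subtype label.
#' QC-failed samples are excluded from the table and reported in the
#' `dropout` attribute; an undetermined subtype keeps its own row.
#'
#' @param status character vector of per-sample statuses
#'   (`"CIN-positive"`, `"CIN-negative"`, `"QC-failed"`), or a list of
#'   [call_cin()] results.
#' @param subtype character vector of subtype labels, same length.
#' @param undetermined_label label marking samples without a subtype
#'   (default `"N/A"`); kept as a row but excluded by the default
#'   [cohort_test()].
#' @return An integer matrix (subtypes x c(CIN-positive, CIN-negative))
#'   of class `"cohort_table"`, with attributes `dropout` (QC-failed
#'   sample indices) and `undetermined_label`.
#' @export
build_cohort_table <- function(status, subtype, undetermined_label = "N/A") {
  if (is.list(status) && length(status) && inherits(status[[1]], "cin_result"))
    status <- vapply(status, function(r) r$status, character(1))
  status <- as.character(status)
  ok <- c("CIN-positive", "CIN-negative", "QC-failed")
  if (any(!status %in% ok))
    stop("unknown status values: ",
         paste(setdiff(unique(status), ok), collapse = ", "))
  if (length(status) != length(subtype))
    stop("status and subtype must have the same length")
  subtype <- as.character(subtype)
  subtype[is.na(subtype)] <- undetermined_label
  drop <- which(status == "QC-failed")
  keep <- status != "QC-failed"
  levels <- unique(subtype[keep])
  tab <- vapply(c("CIN-positive", "CIN-negative"), function(st)
    vapply(levels, function(sb)
      sum(status[keep] == st & subtype[keep] == sb), integer(1)),
    integer(length(levels)))
  tab <- matrix(tab, nrow = length(levels),
                dimnames = list(levels, c("CIN-positive", "CIN-negative")))
  attr(tab, "dropout") <- drop
  attr(tab, "undetermined_label") <- undetermined_label
  class(tab) <- c("cohort_table", class(tab))
  tab
}

#' Test CIN status against subtype across the cohort
#'
#' Runs the Pearson chi-square (default) or Fisher's exact test on a
#' [build_cohort_table()] table. By default the undetermined-subtype row
#' is excluded, so the headline test compares only the defined subtypes;
#' the returned object records which rows were used.
#'
#' @param table a [build_cohort_table()] table (or plain count matrix).
#' @param include_undetermined keep the undetermined row (default FALSE).
#' @param method `"chisq"` (default) or `"fisher"`.
#' @return For `"chisq"`, a [pearson_chi_square()] result with an added
#'   `rows_used` field; for `"fisher"`, the `stats::fisher.test` result.
#' @export
cohort_test <- function(table, include_undetermined = FALSE,
                        method = c("chisq", "fisher")) {
  method <- match.arg(method)
  tab <- unclass(table)
  ul <- attr(table, "undetermined_label")
  if (!include_undetermined && !is.null(ul) && ul %in% rownames(tab))
    tab <- tab[rownames(tab) != ul, , drop = FALSE]
  if (method == "fisher") return(stats::fisher.test(tab))
  res <- pearson_chi_square(tab)
  res$rows_used <- rownames(tab)
  res
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$degrees_of_freedom, x$p_value))
  if (x$small_expected)
    cat(sprintf("  note: smallest expected count %.2f < 5\n", x$min_expected))
  invisible(x)
}
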