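# Printed cohort tables: three defined adenoma subtypes x CIN status, and
# sex x subtype.
subtype_cin <- matrix(c(12, 27, 6, 2, 8, 8), nrow = 3, byrow = TRUE,
                      dimnames = list(c("tubular", "villous", "tubulovillous"),
                                      c("CIN-positive", "CIN-negative")))
sex_subtype <- matrix(c(25, 7, 8, 14, 1, 8), nrow = 2, byrow = TRUE,
                      dimnames = list(c("male", "female"),
                                      c("tubular", "villous", "tubulovillous")))

test_that("chi-square on the printed cohort tables matches hand computation", {
  r <- pearson_chi_square(subtype_cin)
  expect_equal(r$statistic, oracle_chisq(subtype_cin), tolerance = 1e-12)
  expect_equal(r$statistic, 6.03, tolerance = 0.005)
  expect_equal(r$degrees_of_freedom, 2)
  expect_equal(round(r$p_value, 3), 0.049)
  expect_true(r$small_expected)        # villous row has small expecteds

  r2 <- pearson_chi_square(sex_subtype)
  expect_equal(round(r2$p_value, 3), 0.197)
  expect_equal(r2$degrees_of_freedom, 2)
})

test_that("proportional margins give statistic 0 and p 1", {
  r <- pearson_chi_square(matrix(c(10, 10, 20, 20), nrow = 2, byrow = TRUE))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("the statistic is permutation-invariant and expecteds conserve margins", {
  set.seed(13)
  for (r in 1:20) {
    tab <- matrix(rpois(6, 15) + 1, nrow = 3)
    res <- pearson_chi_square(tab)
    perm <- pearson_chi_square(tab[sample(3), sample(2)])
    expect_equal(res$statistic, perm$statistic, tolerance = 1e-12)
    expect_equal(rowSums(res$expected_counts), rowSums(tab))
    expect_equal(colSums(res$expected_counts), colSums(tab))
  }
})

test_that("the statistic equals the textbook computation on random tables", {
  set.seed(29)
  for (r in 1:100) {
    nr <- sample(2:4, 1); nc <- sample(2:3, 1)
    tab <- matrix(rpois(nr * nc, 8) + 1, nrow = nr)
    expect_equal(pearson_chi_square(tab)$statistic, oracle_chisq(tab),
                 tolerance = 1e-9)
  }
})

test_that("degenerate tables are rejected", {
  expect_error(pearson_chi_square(matrix(1:3, ncol = 1)), "2 rows")
  expect_error(pearson_chi_square(matrix(c(0, 0, 1, 2), nrow = 2,
                                         byrow = TRUE)), "margins")
  expect_error(pearson_chi_square(matrix(c(-1, 2, 3, 4), nrow = 2)),
               "non-negative")
})

test_that("percentages truncate to two decimals in the cohort's style", {
  expect_equal(proportion_summary(12, 39), 30.76)
  expect_equal(proportion_summary(6, 8), 75.00)
  expect_equal(proportion_summary(8, 16), 50.00)
  expect_equal(proportion_summary(0, 10), 0)
  expect_equal(proportion_summary(1, 3), 33.33)
  expect_error(proportion_summary(1, 0), "positive")
  expect_error(proportion_summary(5, 4), "total")
})

test_that("cohort tables assemble from statuses, drop QC failures, keep N/A", {
  status <- c("CIN-positive", "CIN-positive", "CIN-positive", "CIN-negative",
              "QC-failed", "CIN-negative")
  subtype <- c("tubular", "tubular", "tubular", "villous", "tubular", NA)
  tab <- build_cohort_table(status, subtype)
  expect_equal(unclass(tab)[c("tubular", "villous", "N/A"), "CIN-positive"],
               c(tubular = 3L, villous = 0L, `N/A` = 0L))
  expect_equal(unclass(tab)["villous", "CIN-negative"], 1L)
  expect_equal(attr(tab, "dropout"), 5L)
  expect_error(build_cohort_table("weird", "tubular"), "unknown status")
})

test_that("the default cohort test excludes the undetermined row", {
  status <- c(rep("CIN-positive", 12), rep("CIN-negative", 27),
              rep("CIN-positive", 6), rep("CIN-negative", 2),
              rep("CIN-positive", 8), rep("CIN-negative", 8),
              rep("CIN-positive", 6), rep("CIN-negative", 8))
  subtype <- c(rep("tubular", 39), rep("villous", 8),
               rep("tubulovillous", 16), rep(NA, 14))
  tab <- build_cohort_table(status, subtype)
  res <- cohort_test(tab)
  expect_equal(round(res$p_value, 3), 0.049)
  expect_equal(sort(res$rows_used),
               sort(c("tubular", "villous", "tubulovillous")))
  res_all <- cohort_test(tab, include_undetermined = TRUE)
  expect_equal(res_all$degrees_of_freedom, 3)
  expect_gt(res_all$p_value, res$p_value)
  # Fisher alternative runs on the same table
  expect_s3_class(cohort_test(tab, method = "fisher"), "htest")
})

test_that("subtype-dependent event rates are detectable at the cohort design", {
  # planted CIN rates 0.3 / 0.75 / 0.5 at subtype sizes 39 / 8 / 16
  set.seed(17)
  hits <- 0; total <- 0
  for (r in 1:200) {
    pos <- c(rbinom(1, 39, 0.3), rbinom(1, 8, 0.75), rbinom(1, 16, 0.5))
    tab <- cbind(pos, c(39, 8, 16) - pos)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    total <- total + 1
    if (pearson_chi_square(tab)$p_value < 0.05) hits <- hits + 1
  }
  expect_gt(hits / total, 0.5)
})
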