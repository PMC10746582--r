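test_that("limits format like publication table cells", {
  expect_equal(format_limit(96.4, FALSE, NA, ci = c(92.1, 101.6)),
               "96 (92–102)")
  expect_equal(format_limit(9, TRUE, 9, ci = c(9, 9)),
               "< 9 (< 9– < 9)")
  expect_equal(format_limit(10.0, FALSE, NA), "10")
  expect_equal(format_limit(2.337, FALSE, NA, ci = c(2.1, 2.6),
                            decimals = 1), "2.3 (2.1–2.6)")
  # censored CI endpoint under an observed limit
  expect_equal(format_limit(9.6, FALSE, 7, ci = c(6.2, 10.4)),
               "10 (< 7–10)")
})

test_that("a full synthetic grid renders 14 logical rows and 42 cells", {
  cohort <- generate_cohort(default_cohort_config(seed = 3))
  results <- estimate_reference_intervals(cohort, boot_reps = 50, seed = 1)
  comp <- compare_all_feeding(exclude_elevated_crp(cohort))
  report <- build_report(results, comp)
  expect_equal(nrow(report$rows), 42)  # 7 analytes x 2 ages x 3 groups
  expect_equal(nrow(dplyr::distinct(report$rows, analyte, age_months)), 14)
  # every series appears exactly once
  expect_equal(
    anyDuplicated(report$rows[c("analyte", "age_months", "group")]), 0
  )
  # one nutrition p per analyte x age
  p_per <- dplyr::summarise(
    dplyr::group_by(report$rows, analyte, age_months),
    k = dplyr::n_distinct(p_nutrition)
  )
  expect_true(all(p_per$k == 1))
  # without comparisons no p column appears
  report2 <- build_report(results)
  expect_false("p_nutrition" %in% names(report2$rows))
  txt <- render_report(report)
  expect_true(any(grepl("p\\(nutrition\\)", txt)))
})

test_that("duplicate series keys are rejected", {
  cohort <- generate_cohort(default_cohort_config(seed = 3))
  results <- estimate_reference_intervals(
    cohort, boot_reps = 0, groups = "all"
  )
  expect_error(build_report(dplyr::bind_rows(results, results[1, ])),
               "Duplicate")
})

test_that("outlier footnotes pass through per cell", {
  results <- tibble::tibble(
    analyte = c("ALP", "GGT"), units = "U/L", age_months = 6,
    group = "all", n = c(278L, 274L),
    median = c(257, 18), median_censored = FALSE,
    q25 = c(209, 14), q25_censored = FALSE,
    q75 = c(309, 22), q75_censored = FALSE,
    method = "nonparametric", n_used = c(277L, 273L),
    outliers_removed = c(1L, 1L), censored_fraction = 0, loq = NA_real_,
    lower = c(123, 9), lower_censored = FALSE,
    lower_ci_lo = c(106, 8), lower_ci_hi = c(128, 10),
    upper = c(467, 40), upper_censored = FALSE,
    upper_ci_lo = c(430, 37), upper_ci_hi = c(538, 45)
  )
  report <- build_report(results)
  expect_equal(nrow(report$footnotes), 2)
  expect_true(all(report$footnotes$outliers_removed == 1))
  expect_true(any(grepl("ALP, 6 months, all: 1 outlier",
                        render_report(report))))
})

test_that("the CSV report round-trips numeric results to printed precision", {
  cohort <- generate_cohort(default_cohort_config(seed = 6))
  results <- estimate_reference_intervals(cohort, boot_reps = 50, seed = 2)
  report <- build_report(results)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_report(report, csv)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(results))
  merged <- dplyr::left_join(
    results, back, by = c("analyte", "age_months", "group"),
    suffix = c("", ".csv")
  )
  expect_equal(merged$lower.csv, merged$lower)
  expect_equal(merged$upper.csv, merged$upper)
  # CSV text fields are ASCII-safe (hyphen ranges)
  expect_false(any(grepl("–", back$ul_text)))
  # the formatted cell reproduces the numeric limit at printed precision
  obs <- !merged$upper_censored
  printed <- as.numeric(sub(" .*$", "", merged$ul_text[obs]))
  expect_equal(printed, round(merged$upper[obs]), tolerance = 1e-12)
})

test_that("current-limit flags compare CIs against supplied cut-offs", {
  cohort <- generate_cohort(default_cohort_config(seed = 8))
  results <- estimate_reference_intervals(cohort, boot_reps = 100,
                                          seed = 3, groups = "all")
  current <- tibble::tibble(
    analyte = "ALT", age_months = 3, current_ll = NA_real_, current_ul = 40
  )
  report <- build_report(results, current_limits = current)
  row <- report$rows[report$rows$analyte == "ALT" &
                       report$rows$age_months == 3, ]
  # the synthetic 3-month ALT upper limit sits far above 40 U/L
  expect_true(row$ul_outside_current)
})
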