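test_that("identical configs yield byte-identical cohorts", {
  a <- generate_cohort(default_cohort_config(seed = 123))
  b <- generate_cohort(default_cohort_config(seed = 123))
  expect_identical(a, b)
  c <- generate_cohort(default_cohort_config(seed = 124))
  expect_false(identical(a, c))
})

test_that("group substreams are independent of the group list", {
  full <- generate_cohort(default_cohort_config(seed = 9))
  cfg_one <- one_group_config(226, seed = 9, age = 3, feeding = "breastfed")
  solo <- generate_cohort(cfg_one)
  expect_identical(
    solo,
    full[full$age_months == 3 & full$feeding == "breastfed", ]
  )
})

test_that("zero-size groups give an empty cohort", {
  cfg <- one_group_config(0, seed = 1)
  expect_equal(nrow(generate_cohort(cfg)), 0)
})

test_that("a LOQ above the distribution censors essentially everything", {
  # ALT spec with LOQ far above the 99.9th percentile
  hi_loq <- lognormal_quantile(0.999, log(36), 0.39) * 2
  cfg <- one_group_config(10000, seed = 3, analyte = "ALT", loq = hi_loq)
  cohort <- generate_cohort(cfg)
  alt <- parse_value(cohort$ALT)
  expect_gte(mean(alt$censored), 0.99)
})

test_that("no observed value ever falls below its analyte LOQ", {
  cohort <- generate_cohort(default_cohort_config(seed = 17))
  specs <- default_analyte_specs()
  long <- cohort_measurements(cohort)
  long <- dplyr::left_join(
    long, specs[c("age_months", "feeding", "analyte", "loq")],
    by = c("age_months", "feeding", "analyte"), suffix = c("", "_spec")
  )
  expect_true(all(long$value[!long$censored] >= long$loq_spec[!long$censored]))
  expect_true(all(long$value[long$censored] == long$loq[long$censored]))
})

test_that("generated samples match the parameterising summary", {
  # AST fit from 51 (43-63): sample median within 51 +/- 1.5 at n = 10000
  fit <- fit_lognormal_median_iqr(51, 43, 63)
  cfg <- one_group_config(10000, seed = 21, analyte = "AST",
                          log_median = fit$log_median,
                          log_sigma = fit$log_sigma)
  ast <- parse_value(generate_cohort(cfg)$AST)
  expect_equal(median(ast$value), 51, tolerance = 1.5 / 51)
  # distributional fidelity: median and IQR ratio within 3%
  q <- quantile(ast$value, c(0.25, 0.75), names = FALSE)
  expect_equal(q[2] / q[1], 63 / 43, tolerance = 0.03)
})

test_that("empirical quantiles of generator draws match the analytic truth", {
  cfg <- one_group_config(1e5, seed = 31, analyte = "ALP")
  sp <- cfg$analyte_specs
  sp <- sp[sp$age_months == 3 & sp$feeding == "breastfed" &
             sp$analyte == "ALP", ]
  alp <- parse_value(generate_cohort(cfg)$ALP)$value
  for (p in c(0.025, 0.5, 0.975)) {
    expect_equal(
      quantile(alp, p, names = FALSE, type = 6),
      lognormal_quantile(p, sp$log_median, sp$log_sigma),
      tolerance = 0.01
    )
  }
})

test_that("cohort CSV and config files round-trip", {
  cfg <- default_cohort_config(seed = 5)
  cohort <- generate_cohort(cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, csv)
  expect_identical(as.data.frame(read_cohort(csv)), as.data.frame(cohort))

  toml <- withr::local_tempfile(fileext = ".toml")
  write_cohort_config(cfg, toml)
  cfg2 <- read_cohort_config(toml)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$crp_threshold, cfg$crp_threshold)
  expect_equal(
    dplyr::arrange(cfg2$groups, age_months, feeding),
    dplyr::arrange(cfg$groups, age_months, feeding)
  )
  s1 <- dplyr::arrange(cfg$analyte_specs, age_months, feeding, analyte)
  s2 <- dplyr::arrange(cfg2$analyte_specs, age_months, feeding, analyte)
  expect_equal(s2$log_median, s1$log_median, tolerance = 1e-12)
  expect_equal(s2$log_sigma, s1$log_sigma, tolerance = 1e-12)
  expect_identical(generate_cohort(cfg2), cohort)
})

test_that("configs validate group uniqueness and spec coverage", {
  groups <- tibble::tibble(
    age_months = c(3, 3), feeding = c("breastfed", "breastfed"),
    n = c(10L, 10L), crp_elevated_prob = 0.05
  )
  expect_error(cohort_config(groups), "unique")
  groups2 <- tibble::tibble(age_months = 4, feeding = "breastfed", n = 10L,
                            crp_elevated_prob = 0.05)
  expect_error(cohort_config(groups2), "lacks analyte spec")
})
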