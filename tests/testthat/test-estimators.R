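test_that("method selection follows size and censoring rules", {
  expect_equal(select_method(226, 0.02), "nonparametric")
  expect_equal(select_method(49, 0.02), "robust")
  expect_equal(select_method(49, 0.6), "direct_percentile")
  # "over 120" is strict
  expect_equal(select_method(120, 0), "robust")
  expect_equal(select_method(121, 0), "nonparametric")
  # censoring rule dominates sample size
  expect_equal(select_method(500, 0.5), "direct_percentile")
})

test_that("nonparametric ranks interpolate as r = p(n+1)", {
  ri <- nonparametric_ri(1:120, boot_reps = 0)
  expect_equal(ri$lower$value, 3.025)
  expect_equal(ri$upper$value, 117.975)
})

test_that("constant series give zero-width limits and CIs", {
  ri <- nonparametric_ri(rep(7, 130), boot_reps = 100, seed = 1)
  expect_equal(ri$lower$value, 7)
  expect_equal(ri$upper$value, 7)
  expect_equal(ri$lower_ci, c(7, 7))
  expect_equal(ri$upper_ci, c(7, 7))
})

test_that("nonparametric limits recover Gaussian quantiles", {
  set.seed(314)
  x <- rnorm(5000) + 10
  ri <- nonparametric_ri(x, boot_reps = 0)
  expect_equal(ri$lower$value, 10 - 1.96, tolerance = 0.1 / 8)
  expect_equal(ri$upper$value, 10 + 1.96, tolerance = 0.1 / 12)
  # point limits never leave the sample range
  expect_gte(ri$lower$value, min(x))
  expect_lte(ri$upper$value, max(x))
})

test_that("point limits equal the independent sort-and-interpolate oracle", {
  set.seed(2024)
  for (i in 1:100) {
    n <- sample(5:400, 1)
    x <- switch(sample(3, 1), rnorm(n, 50, 9), rlnorm(n, 3, 0.8),
                runif(n, 0, 1))
    ri <- suppressWarnings(nonparametric_ri(x, boot_reps = 0))
    expect_equal(c(ri$lower$value, ri$upper$value), naive_rank_limits(x),
                 tolerance = 1e-12)
  }
})

test_that("rank convention matches the type-6 library quantile", {
  set.seed(8)
  x <- rlnorm(300, 3, 0.5)
  ri <- nonparametric_ri(x, boot_reps = 0)
  expect_equal(c(ri$lower$value, ri$upper$value),
               quantile(x, c(0.025, 0.975), type = 6, names = FALSE),
               tolerance = 1e-12)
})

test_that("robust location is the symmetry fixed point", {
  ri <- suppressWarnings(robust_ri(c(1, 2, 3, 4, 5), boot_reps = 0))
  centre <- (ri$lower$value + ri$upper$value) / 2
  expect_equal(centre, 3, tolerance = 1e-8)
})

test_that("zero MAD degenerates the robust interval with a warning", {
  expect_warning(
    ri <- robust_ri(rep(4, 30), boot_reps = 50, seed = 1),
    "Zero MAD"
  )
  expect_equal(ri$lower$value, 4)
  expect_equal(ri$upper$value, 4)
  expect_equal(ri$upper_ci, c(4, 4))
})

test_that("robust and nonparametric limits agree on a large Gaussian sample", {
  set.seed(77)
  x <- rnorm(5000, 10, 1)
  np <- nonparametric_ri(x, boot_reps = 0)
  rb <- robust_ri(x, boot_reps = 0)
  expect_lt(abs(np$lower$value - rb$lower$value), 0.1)
  expect_lt(abs(np$upper$value - rb$upper$value), 0.1)
})

test_that("direct percentiles report censored-block limits as < LOQ", {
  s <- make_series(observed = seq(2.1, 5, length.out = 40), n_cens = 60,
                   loq = 2)
  ri <- direct_percentile_ri(s)
  # rank 2.525 falls inside the 60-strong censored block
  expect_true(ri$lower$censored)
  expect_equal(ri$lower$value, 2)
  # rank 98.475 lies in the observed tail
  expect_false(ri$upper$censored)
  expect_gt(ri$upper$value, 2)
  expect_null(ri$lower_ci)
  expect_null(ri$upper_ci)
  # all censored: both limits below range
  all_c <- make_series(observed = numeric(0), n_cens = 10, loq = 2)
  ri2 <- direct_percentile_ri(all_c)
  expect_true(ri2$lower$censored && ri2$upper$censored)
})

test_that("all three methods are shift/scale equivariant", {
  set.seed(55)
  x <- rlnorm(150, 3, 0.4)
  a <- 2.5; b <- 7
  for (est in list(
    function(v) nonparametric_ri(v, boot_reps = 0),
    function(v) suppressWarnings(robust_ri(v, boot_reps = 0)),
    function(v) direct_percentile_ri(v)
  )) {
    r1 <- est(x)
    r2 <- est(a * x + b)
    expect_equal(r2$lower$value, a * r1$lower$value + b, tolerance = 1e-9)
    expect_equal(r2$upper$value, a * r1$upper$value + b, tolerance = 1e-9)
  }
})

test_that("bootstrap CIs always bracket their point limit", {
  set.seed(66)
  for (i in 1:10) {
    x <- rlnorm(sample(c(60, 150, 300), 1), 3, runif(1, 0.2, 0.9))
    ri <- suppressWarnings(
      estimate_series(x, boot_reps = 200, seed = i, screen_outliers = FALSE)
    )
    expect_lte(ri$lower_ci[1], ri$lower$value)
    expect_gte(ri$lower_ci[2], ri$lower$value)
    expect_lte(ri$upper_ci[1], ri$upper$value)
    expect_gte(ri$upper_ci[2], ri$upper$value)
  }
})

test_that("estimation composes screening and method selection", {
  ri <- estimate_series(c(1:121, 10000), boot_reps = 0)
  expect_equal(ri$outliers$removed_values, 10000)
  expect_equal(ri$n_used, 121)
  expect_equal(ri$method, "nonparametric")

  ri2 <- estimate_series(1:50, boot_reps = 0)
  expect_equal(ri2$method, "robust")
  expect_equal(ri2$outliers$removed_count, 0)

  s <- make_series(observed = seq(2.1, 4, length.out = 30), n_cens = 70,
                   loq = 2)
  ri3 <- estimate_series(s, boot_reps = 0)
  expect_equal(ri3$method, "direct_percentile")
})

test_that("empty series error and bootstrap seeding is reproducible", {
  expect_error(nonparametric_ri(numeric(0)), "empty")
  expect_error(direct_percentile_ri(numeric(0)), "empty")
  x <- rlnorm(200, 3, 0.3)
  a <- nonparametric_ri(x, boot_reps = 100, seed = 5)
  b <- nonparametric_ri(x, boot_reps = 100, seed = 5)
  expect_identical(tidy(a), tidy(b))
})

test_that("tidy and glance summarise a fitted interval", {
  ri <- estimate_series(rnorm(150, 10), boot_reps = 50, seed = 2,
                        analyte = "AST")
  td <- tidy(ri)
  expect_equal(nrow(td), 1)
  expect_equal(td$analyte, "AST")
  expect_true(all(c("lower", "upper", "lower_ci_lo", "upper_ci_hi",
                    "outliers_removed") %in% names(td)))
  gl <- glance(ri)
  expect_equal(gl$boot_reps, 50)
  p <- autoplot(ri)
  expect_s3_class(p, "ggplot")
})
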