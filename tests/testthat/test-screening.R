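test_that("one-third-range rule removes the worked-case outlier", {
  r <- dixon_screen(c(1:19, 100))
  expect_equal(r$removed_values, 100)
  expect_equal(r$removed_tail, "high")
  expect_equal(r$surviving_n, 19)
  # plain ladder: both tail ratios are 1/19, nothing fires
  expect_equal(dixon_screen(1:20)$removed_count, 0)
  # zero range: guard, no removals
  expect_equal(dixon_screen(c(5, 5, 5, 5))$removed_count, 0)
})

test_that("screening caps removals at 5% of the original sample", {
  # a geometric ladder where the top gap always exceeds 1/3 of range
  x <- 2^(1:100)
  r <- dixon_screen(x)
  expect_lte(r$removed_count, 5)
  expect_equal(r$removed_count, 5)
})

test_that("screening warns and keeps everything below n = 3", {
  expect_warning(r <- dixon_screen(c(1, 2)), "undefined")
  expect_equal(r$removed_count, 0)
  expect_equal(r$surviving_n, 2)
})

test_that("screening is shift/scale equivariant and idempotent", {
  set.seed(7)
  for (i in 1:25) {
    x <- rlnorm(40, 3, runif(1, 0.3, 1.2))
    a <- runif(1, 0.5, 20)
    b <- runif(1, -5, 50)
    r1 <- dixon_screen(x)
    r2 <- dixon_screen(a * x + b)
    expect_equal(r2$removed_values, a * r1$removed_values + b,
                 tolerance = 1e-12)
    expect_equal(r2$removed_tail, r1$removed_tail)
    # idempotence on its own output
    r3 <- dixon_screen(r1$kept)
    expect_equal(r3$removed_count, 0)
  }
})

test_that("censored values sit in the tied block and never fire low", {
  s <- make_series(observed = c(10, 11, 12, 13, 14), n_cens = 4, loq = 9)
  r <- dixon_screen(s)
  expect_equal(r$removed_count, 0)
  expect_true(all(r$kept$value[r$kept$censored] == 9))
})

test_that("Harris-Boyd statistics reproduce the worked arithmetic", {
  hb <- harris_boyd(120, 15, 10, 120, 10, 10)
  expect_equal(hb$z, 5 / sqrt(200 / 120), tolerance = 1e-9)
  expect_equal(hb$z_star, 3, tolerance = 1e-9)
  expect_true(hb$partition)
  hb2 <- harris_boyd(60, 15, 10, 60, 10, 10)
  expect_equal(hb2$z, 2.7386, tolerance = 1e-4)
  expect_equal(hb2$z_star, 3 * sqrt(60 / 120), tolerance = 1e-9)
  expect_true(hb2$partition)
  # identical summaries: z = 0, sd ratio 1, no partition
  hb3 <- harris_boyd(50, 10, 2, 50, 10, 2)
  expect_equal(hb3$z, 0)
  expect_false(hb3$partition)
})

test_that("the sd-ratio companion rule can force a partition alone", {
  hb <- harris_boyd(100, 10, 1, 100, 10, 1.6)
  expect_lte(hb$z, hb$z_star)
  expect_true(hb$partition)
  expect_equal(hb$sd_ratio, 1.6)
})

test_that("Harris-Boyd is symmetric and shift/scale invariant", {
  set.seed(12)
  for (i in 1:20) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    m1 <- rnorm(1, 10); m2 <- rnorm(1, 10)
    s1 <- runif(1, 0.5, 3); s2 <- runif(1, 0.5, 3)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    h12 <- harris_boyd(n1, m1, s1, n2, m2, s2)
    h21 <- harris_boyd(n2, m2, s2, n1, m1, s1)
    hab <- harris_boyd(n1, a * m1 + b, a * s1, n2, a * m2 + b, a * s2)
    expect_equal(h12$z, h21$z)
    expect_equal(h12$partition, h21$partition)
    expect_equal(hab$z, h12$z, tolerance = 1e-12)
    expect_equal(hab$sd_ratio, h12$sd_ratio, tolerance = 1e-12)
  }
  expect_error(harris_boyd(1, 5, 1, 50, 5, 1), "n >= 2")
  expect_error(harris_boyd(10, 5, 0, 50, 5, 0))
})

test_that("partition testing runs across the cohort grid", {
  cohort <- generate_cohort(default_cohort_config(seed = 4))
  pt <- partition_test(cohort, by = "feeding")
  expect_equal(nrow(pt), 14)  # 7 analytes x 2 ages
  expect_true(all(c("z", "z_star", "sd_ratio", "partition") %in% names(pt)))
  pt_sex <- partition_test(cohort, by = "sex")
  # no sex effect is simulated; partitions should be rare
  expect_lt(mean(pt_sex$partition), 0.5)
})
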