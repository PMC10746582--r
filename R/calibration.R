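#' Simulation-based calibration of the nonparametric limits
#'
#' Validation utility: simulates `n_reps` Gaussian cohorts, estimates
#' the reference limits and their bootstrap confidence intervals on
#' each with [nonparametric_ri()], and summarises (a) how often each
#' limit's CI covers the true population percentile and (b) the mean
#' population mass lying beyond the estimated limits. For a
#' well-calibrated pipeline the CI coverage matches `ci_level` and the
#' mean tail masses match the target percentiles (2.5% below the lower
#' limit, 97.5% at or below the upper).
#'
#' @param n_reps Number of simulated cohorts (default 1000).
#' @param n Cohort size (default 240).
#' @param mean,sd Gaussian population parameters (default N(10, 1)).
#' @param ci_level,boot_reps Passed to [nonparametric_ri()].
#' @param seed Master seed; each replicate uses a derived substream.
#' @return A list with `summary` (one-row tibble: coverage percentages
#'   for both limits and mean tail masses, in percent) and
#'   `replicates` (per-replicate limits, CI bounds and coverage flags).
#' @export
#' @examples
#' cal <- gaussian_calibration(n_reps = 20, boot_reps = 100, seed = 1)
#' cal$summary
gaussian_calibration <- function(n_reps = 1000, n = 240, mean = 10,
                                 sd = 1, ci_level = 0.90,
                                 boot_reps = 2000, seed = 1) {
  true_l <- qnorm(0.025, mean, sd)
  true_u <- qnorm(0.975, mean, sd)
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    rep_seed <- (as.numeric(seed) + 1009 * i) %% 2147483629
    rows[[i]] <- withr::with_seed(rep_seed, {
      x <- rnorm(n, mean, sd)
      ri <- nonparametric_ri(x, ci_level = ci_level,
                             boot_reps = boot_reps)
      tibble(
        lower = ri$lower$value, upper = ri$upper$value,
        lower_ci_lo = ri$lower_ci[1], lower_ci_hi = ri$lower_ci[2],
        upper_ci_lo = ri$upper_ci[1], upper_ci_hi = ri$upper_ci[2]
      )
    })
  }
  reps <- dplyr::bind_rows(rows)
  reps$covers_lower <- reps$lower_ci_lo <= true_l &
    true_l <= reps$lower_ci_hi
  reps$covers_upper <- reps$upper_ci_lo <= true_u &
    true_u <= reps$upper_ci_hi
  reps$mass_below_lower <- pnorm(reps$lower, mean, sd)
  reps$mass_at_or_below_upper <- pnorm(reps$upper, mean, sd)
  list(
    summary = tibble(
      n_reps = n_reps, n = n, ci_level = ci_level,
      coverage_lower_pct = 100 * mean(reps$covers_lower),
      coverage_upper_pct = 100 * mean(reps$covers_upper),
      mean_mass_below_lower_pct = 100 * mean(reps$mass_below_lower),
      mean_mass_at_or_below_upper_pct =
        100 * mean(reps$mass_at_or_below_upper)
    ),
    replicates = reps
  )
}

#' True quantiles implied by the generator for every estimation series
#'
#' For parameter-recovery checks: the exact 2.5th and 97.5th
#' percentiles of each analyte x age x group series under a cohort
#' configuration — closed-form log-normal quantiles for the feeding
#' groups, mixture quantiles (weighted by group size) for the pooled
#' "all" series.
#'
#' @param config A [cohort_config()].
#' @param probs Percentiles to evaluate (default `c(0.025, 0.975)`).
#' @return A tibble: `analyte`, `age_months`, `group`, `loq`, then one
#'   column per requested percentile (`q_2.5`, `q_97.5`, ...).
#' @export
true_series_quantiles <- function(config, probs = c(0.025, 0.975)) {
  stopifnot(inherits(config, "cohort_config"))
  specs <- dplyr::left_join(
    config$analyte_specs,
    config$groups[c("age_months", "feeding", "n")],
    by = c("age_months", "feeding")
  )
  specs <- specs[!is.na(specs$n) & specs$n > 0, , drop = FALSE]
  grid <- tidyr::expand_grid(
    analyte = unique(specs$analyte),
    age_months = unique(specs$age_months),
    group = c("all", unique(specs$feeding))
  )
  purrr::pmap_dfr(grid, function(analyte, age_months, group) {
    sp <- specs[specs$analyte == analyte &
                  specs$age_months == age_months, , drop = FALSE]
    if (group != "all") sp <- sp[sp$feeding == group, , drop = FALSE]
    if (!nrow(sp)) return(NULL)
    q <- if (nrow(sp) == 1) {
      lognormal_quantile(probs, sp$log_median, sp$log_sigma)
    } else {
      lognormal_mixture_quantile(probs, sp$log_median, sp$log_sigma,
                                 weights = sp$n)
    }
    out <- tibble(analyte = analyte, age_months = age_months,
                  group = group, loq = max(sp$loq))
    for (j in seq_along(probs)) {
      out[[paste0("q_", format(100 * probs[j]))]] <- q[j]
    }
    out
  })
}
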