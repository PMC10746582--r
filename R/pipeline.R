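#' Estimate reference intervals for every analyte, age and group
#'
#' The end-to-end estimation pass over a cohort: CRP exclusion,
#' then for each analyte x age x group series (pooled "all" plus the
#' two feeding groups) Dixon outlier screening, method selection and
#' reference-limit estimation with bootstrap confidence intervals
#' ([estimate_series()]). Per-series bootstrap seeds are derived
#' deterministically from `seed` so the whole table is reproducible.
#'
#' @param cohort A cohort tibble ([generate_cohort()] /
#'   [read_cohort()]).
#' @param crp_threshold CRP exclusion threshold in mg/L (default 4);
#'   set to `NULL` if the cohort is already filtered.
#' @param groups Which group columns to estimate (subset of
#'   `c("all", "breastfed", "not_breastfed")`).
#' @inheritParams estimate_series
#' @return A tibble with one row per estimated series: identifiers
#'   (`analyte`, `units`, `age_months`, `group`), the series summary
#'   (`n`, censoring-aware `median`/`q25`/`q75` with censored flags)
#'   and the tidy reference-interval columns (see
#'   [tidy.reference_interval()]). The number of CRP-excluded records
#'   is attached as attribute `"n_crp_excluded"`.
#' @export
#' @examples
#' cohort <- generate_cohort(default_cohort_config(seed = 1))
#' res <- estimate_reference_intervals(cohort, boot_reps = 100, seed = 1)
#' dplyr::select(res, analyte, age_months, group, method, lower, upper)
estimate_reference_intervals <- function(cohort,
                                         crp_threshold = 4,
                                         ci_level = 0.90,
                                         boot_reps = 2000,
                                         seed = NULL,
                                         censoring_fallback = 0.5,
                                         nonparametric_min = 120,
                                         screen_outliers = TRUE,
                                         groups = c("all", "breastfed",
                                                    "not_breastfed")) {
  groups <- match.arg(groups, several.ok = TRUE)
  n_excluded <- 0L
  if (!is.null(crp_threshold) && "crp" %in% names(cohort)) {
    cohort <- exclude_elevated_crp(cohort, crp_threshold)
    n_excluded <- nrow(excluded_records(cohort))
  }
  ages <- sort(unique(cohort$age_months))
  analytes <- intersect(PANEL_ANALYTES, names(cohort))
  grid <- tidyr::expand_grid(analyte = analytes, age_months = ages,
                             group = groups)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    analyte <- grid$analyte[i]
    age <- grid$age_months[i]
    group <- grid$group[i]
    feeding <- if (group == "all") NULL else group
    series <- extract_series(cohort, analyte, age, feeding)
    if (nrow(series) == 0) next
    series_seed <- if (is.null(seed)) NULL else
      (as.numeric(seed) + 7919 * i) %% 2147483629
    ri <- estimate_series(
      series, ci_level = ci_level, boot_reps = boot_reps,
      seed = series_seed, censoring_fallback = censoring_fallback,
      nonparametric_min = nonparametric_min,
      screen_outliers = screen_outliers, analyte = analyte
    )
    qs <- series_quantiles(if (is.null(ri$outliers)) series else
      ri$outliers$kept)
    rows[[i]] <- dplyr::bind_cols(
      tibble(
        analyte = analyte, units = unname(PANEL_UNITS[analyte]),
        age_months = age, group = group, n = nrow(series),
        median = qs$value[2], median_censored = qs$censored[2],
        q25 = qs$value[1], q25_censored = qs$censored[1],
        q75 = qs$value[3], q75_censored = qs$censored[3]
      ),
      tidy(ri)[-1]  # drop duplicate analyte column
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_crp_excluded") <- n_excluded
  attr(out, "ci_level") <- ci_level
  out
}

#' Plot estimated reference intervals
#'
#' Interval plot of the estimated limits (with their confidence
#' intervals) per analyte, age group and feeding group.
#'
#' @param results The tibble returned by
#'   [estimate_reference_intervals()].
#' @return A ggplot object: limits as points, CI ranges as error bars,
#'   faceted by analyte (free y scales), age on the x axis, colour by
#'   group.
#' @export
plot_reference_intervals <- function(results) {
  long <- dplyr::bind_rows(
    dplyr::transmute(
      results, .data$analyte, .data$age_months, .data$group,
      limit = "lower", value = .data$lower,
      ci_lo = .data$lower_ci_lo, ci_hi = .data$lower_ci_hi
    ),
    dplyr::transmute(
      results, .data$analyte, .data$age_months, .data$group,
      limit = "upper", value = .data$upper,
      ci_lo = .data$upper_ci_lo, ci_hi = .data$upper_ci_hi
    )
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = factor(.data$age_months), y = .data$value,
                 colour = .data$group, shape = .data$limit)
  ) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      position = ggplot2::position_dodge(width = 0.5), width = 0.3
    ) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "age (months)", y = "reference limit",
                  colour = "group", shape = "limit")
}
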