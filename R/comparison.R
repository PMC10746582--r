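#' Wilcoxon rank-sum test with censoring-aware tie handling
#'
#' Two-sided Wilcoxon (Mann-Whitney) test between two measurement
#' series. Below-range values enter at their LOQ, so values censored
#' at a common limit form one tied block sharing the bottom mid-rank —
#' the same ordering the interval estimators use. The exact null
#' distribution is enumerated when the smaller group has at most 10
#' values and there are no ties; otherwise the normal approximation
#' with tie and continuity correction is used.
#'
#' @param group_a,group_b Measurement tibbles or numeric vectors.
#' @return A list with `statistic` (Mann-Whitney W for the first
#'   group), `p_value` (two-sided) and `test` (`"exact"` or
#'   `"normal_approximation"`). Swapping the groups leaves the p-value
#'   unchanged, as does any strictly increasing transform of both.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value  # exact 1/3
wilcoxon_rank_sum <- function(group_a, group_b) {
  a <- as_series(group_a, arg = "group_a")$value
  b <- as_series(group_b, arg = "group_b")$value
  if (length(a) == 0 || length(b) == 0) {
    abort("Both groups must be non-empty.")
  }
  has_ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 10 && !has_ties
  res <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  list(
    statistic = unname(res$statistic),
    p_value = min(res$p.value, 1),
    test = if (exact) "exact" else "normal_approximation"
  )
}

# Censoring-aware median (and quartiles) of a measurement series:
# values at the stored LOQ for the censored block; a quantile landing
# at or below the block is flagged censored.
series_quantiles <- function(series, probs = c(0.25, 0.5, 0.75)) {
  series <- sort_series(series)
  q <- rank_percentile(series$value, probs)
  loq <- series_loq(series)
  tibble(prob = probs, value = q,
         censored = !is.na(loq) & q <= loq,
         loq = loq)
}

#' Compare feeding groups for one analyte and age
#'
#' Computes the breastfed and not-breastfed medians (censoring-aware:
#' a median inside the below-range block is reported censored) and the
#' two-sided Wilcoxon rank-sum p-value between the two series. Outlier
#' screening is applied to each series exactly as in the estimation
#' path, so the compared samples match the ones the reference limits
#' are computed from.
#'
#' @param cohort A cohort tibble (after CRP exclusion, typically).
#' @param analyte Panel analyte name.
#' @param age_months 3 or 6.
#' @param screen_outliers Apply [dixon_screen()] to each series first
#'   (default TRUE).
#' @return A one-row tibble: `analyte`, `age_months`, per-group n
#'   (before and after screening), censoring-aware medians with
#'   censored flags, `statistic`, `p_value`, `test` and the display
#'   label `p_label` (two decimals, `"< 0.001"` below that).
#' @export
compare_feeding_groups <- function(cohort, analyte, age_months,
                                   screen_outliers = TRUE) {
  s_bf <- extract_series(cohort, analyte, age_months, "breastfed")
  s_nb <- extract_series(cohort, analyte, age_months, "not_breastfed")
  if (nrow(s_bf) == 0 || nrow(s_nb) == 0) {
    missing <- c("breastfed", "not_breastfed")[c(nrow(s_bf), nrow(s_nb)) == 0]
    abort(sprintf(
      "No %s measurements for %s at %g months.",
      paste(missing, collapse = " or "), analyte, age_months
    ))
  }
  n_bf_raw <- nrow(s_bf); n_nb_raw <- nrow(s_nb)
  if (screen_outliers) {
    if (n_bf_raw >= 3) s_bf <- dixon_screen(s_bf)$kept
    if (n_nb_raw >= 3) s_nb <- dixon_screen(s_nb)$kept
  }
  med_bf <- series_quantiles(s_bf, 0.5)
  med_nb <- series_quantiles(s_nb, 0.5)
  w <- wilcoxon_rank_sum(s_bf, s_nb)
  tibble(
    analyte = analyte, age_months = age_months,
    n_breastfed = n_bf_raw, n_breastfed_used = nrow(s_bf),
    n_not_breastfed = n_nb_raw, n_not_breastfed_used = nrow(s_nb),
    median_breastfed = med_bf$value,
    median_breastfed_censored = med_bf$censored,
    median_not_breastfed = med_nb$value,
    median_not_breastfed_censored = med_nb$censored,
    statistic = w$statistic, p_value = w$p_value, test = w$test,
    p_label = format_p(w$p_value)
  )
}

#' Feeding-group comparisons across the whole panel
#'
#' Runs [compare_feeding_groups()] for every analyte x age present in
#' the cohort. Raw per-analyte p-values are reported by default,
#' mirroring per-analyte reporting practice; Holm adjustment is
#' available as an option.
#'
#' @inheritParams compare_feeding_groups
#' @param adjust `"none"` (default) or `"holm"`; when `"holm"`, a
#'   `p_adjusted` column is added via [stats::p.adjust()].
#' @return A tibble with one row per analyte x age.
#' @export
compare_all_feeding <- function(cohort, screen_outliers = TRUE,
                                adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  ages <- sort(unique(cohort$age_months))
  analytes <- intersect(PANEL_ANALYTES, names(cohort))
  grid <- tidyr::expand_grid(analyte = analytes, age_months = ages)
  out <- purrr::pmap_dfr(grid, function(analyte, age_months) {
    both <- all(vapply(FEEDING_LEVELS, function(f) {
      any(cohort$age_months == age_months & cohort$feeding == f)
    }, logical(1)))
    if (!both) return(NULL)
    compare_feeding_groups(cohort, analyte, age_months,
                           screen_outliers = screen_outliers)
  })
  if (adjust == "holm" && nrow(out)) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
  }
  out
}

#' Format a p-value for reporting
#'
#' Two decimals, three below 0.01, and `"< 0.001"` below that.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
#' @examples
#' format_p(c(0.8612, 0.0062, 0.0004))
format_p <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "< 0.001",
    p < 0.01 ~ sprintf("%.3f", p),
    TRUE ~ sprintf("%.2f", p)
  )
}
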