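#' Modified Dixon (one-third-range) outlier screening
#'
#' Screens an estimation series for outliers with the one-third-of-range
#' rule used in clinical reference-interval work: after sorting, the
#' maximum is deleted when its gap to the next value exceeds one third
#' of the whole range, and symmetrically for the minimum. After any
#' deletion the reduced sample is re-tested; screening stops when no
#' deletion fires or when a further removal would exceed 5% of the
#' original sample size. A zero-range (constant) sample removes
#' nothing. Below-range values participate at their LOQ; since they
#' form a tied block with zero gaps, a censored minimum can never fire.
#'
#' @param x A numeric vector or a measurement tibble (uses `value`).
#' @param max_removal_frac Cap on the removed fraction of the original
#'   n (default 0.05).
#' @return An object of class `dixon_screen`: a list with
#'   `removed_values`, `removed_tail` (`"low"`/`"high"` per removal),
#'   `removed_count`, `surviving_n`, `kept` (the surviving series as a
#'   measurement tibble, sorted) and `n`. With fewer than 3 values the
#'   test is undefined: a warning is raised and nothing is removed.
#' @details The rule is shift- and scale-equivariant (gap/range ratios
#'   are invariant under `a*x + b`, `a > 0`) and idempotent on its own
#'   output. When both tails fire simultaneously the larger gap ratio
#'   is removed first (high tail on a tie).
#' @export
#' @examples
#' dixon_screen(c(1:19, 100))$removed_values
#' dixon_screen(1:20)$removed_count
dixon_screen <- function(x, max_removal_frac = 0.05) {
  series <- sort_series(as_series(x, arg = "x"))
  n0 <- nrow(series)
  removed_values <- numeric(0)
  removed_tail <- character(0)
  if (n0 < 3) {
    warn("Dixon screening is undefined for fewer than 3 values; nothing removed.")
  } else {
    repeat {
      v <- series$value
      n <- length(v)
      rng <- v[n] - v[1]
      if (n < 3 || rng == 0) break
      r_hi <- (v[n] - v[n - 1]) / rng
      r_lo <- (v[2] - v[1]) / rng
      if (max(r_hi, r_lo) <= 1 / 3) break
      if (length(removed_values) + 1 > max_removal_frac * n0) break
      if (r_hi >= r_lo) {
        removed_values <- c(removed_values, v[n])
        removed_tail <- c(removed_tail, "high")
        series <- series[-n, , drop = FALSE]
      } else {
        removed_values <- c(removed_values, v[1])
        removed_tail <- c(removed_tail, "low")
        series <- series[-1, , drop = FALSE]
      }
    }
  }
  structure(
    list(
      removed_values = removed_values,
      removed_tail = removed_tail,
      removed_count = length(removed_values),
      surviving_n = nrow(series),
      kept = series,
      n = n0
    ),
    class = "dixon_screen"
  )
}

#' @export
print.dixon_screen <- function(x, ...) {
  cat(sprintf("Dixon one-third-range screen: n = %d, removed = %d\n",
              x$n, x$removed_count))
  if (x$removed_count) {
    cat("  removed:",
        paste(sprintf("%g (%s)", x$removed_values, x$removed_tail),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy dixon_screen
#' @export
tidy.dixon_screen <- function(x, ...) {
  tibble(
    removed_value = x$removed_values,
    tail = x$removed_tail
  )
}

#' @method glance dixon_screen
#' @export
glance.dixon_screen <- function(x, ...) {
  tibble(n = x$n, removed_count = x$removed_count,
         surviving_n = x$surviving_n)
}

#' Harris-Boyd partition test for subgroup reference intervals
#'
#' Decides whether two subgroups (e.g. sexes, feeding groups) need
#' separate reference intervals. The standardized mean difference
#' `z = |mean1 - mean2| / sqrt(sd1^2/n1 + sd2^2/n2)` is compared with
#' the sample-size-scaled critical value
#' `z* = 3 * sqrt(((n1 + n2)/2) / 120)`; partitioning is also indicated
#' when the subgroup standard deviations differ by more than
#' `sd_ratio_limit` (default 1.5), a standard companion criterion.
#'
#' @param n1,mean1,sd1 Summary statistics of the first subgroup.
#' @param n2,mean2,sd2 Summary statistics of the second subgroup.
#' @param sd_ratio_limit Secondary criterion limit on
#'   `max(sd1, sd2) / min(sd1, sd2)` (ratio is `Inf` if one sd is 0).
#' @return An object of class `harris_boyd`: list with `z`, `z_star`,
#'   `sd_ratio`, `partition` and the inputs. The decision is symmetric
#'   in the two groups and invariant to a common shift/scale.
#' @export
#' @examples
#' harris_boyd(120, 15, 10, 120, 10, 10)  # partition: z > z*
harris_boyd <- function(n1, mean1, sd1, n2, mean2, sd2,
                        sd_ratio_limit = 1.5) {
  if (n1 < 2 || n2 < 2) abort("Harris-Boyd needs n >= 2 in each subgroup.")
  if (sd1 < 0 || sd2 < 0 || (sd1 == 0 && sd2 == 0)) {
    abort("Subgroup sds must be non-negative and not both zero.")
  }
  z <- abs(mean1 - mean2) / sqrt(sd1^2 / n1 + sd2^2 / n2)
  z_star <- 3 * sqrt(((n1 + n2) / 2) / 120)
  sd_ratio <- if (min(sd1, sd2) == 0) Inf else max(sd1, sd2) / min(sd1, sd2)
  structure(
    list(
      z = z, z_star = z_star, sd_ratio = sd_ratio,
      sd_ratio_limit = sd_ratio_limit,
      partition = (z > z_star) || (sd_ratio > sd_ratio_limit),
      n1 = n1, n2 = n2
    ),
    class = "harris_boyd"
  )
}

#' @export
print.harris_boyd <- function(x, ...) {
  cat(sprintf(
    "Harris-Boyd partition test: z = %.3f, z* = %.3f, sd ratio = %.3f (limit %.2f)\n  partition: %s\n",
    x$z, x$z_star, x$sd_ratio, x$sd_ratio_limit,
    if (x$partition) "yes" else "no"
  ))
  invisible(x)
}

#' @method tidy harris_boyd
#' @export
tidy.harris_boyd <- function(x, ...) {
  tibble(
    z = x$z, z_star = x$z_star, sd_ratio = x$sd_ratio,
    sd_ratio_limit = x$sd_ratio_limit, partition = x$partition
  )
}

#' Partition testing on cohort subgroups
#'
#' Runs [harris_boyd()] per analyte and age group between either the
#' feeding groups or the sexes, using the measurement values as stored
#' (below-range values at their LOQ).
#'
#' @param cohort A cohort tibble.
#' @param by `"feeding"` or `"sex"`.
#' @param sd_ratio_limit Passed to [harris_boyd()].
#' @return A tibble with one row per analyte x age: group sizes and the
#'   tidy Harris-Boyd columns.
#' @export
partition_test <- function(cohort, by = c("feeding", "sex"),
                           sd_ratio_limit = 1.5) {
  by <- match.arg(by)
  levels2 <- if (by == "feeding") FEEDING_LEVELS else c("female", "male")
  long <- cohort_measurements(cohort)
  if (by == "sex" && !"sex" %in% names(long)) {
    abort("Cohort has no `sex` column.")
  }
  grid <- dplyr::distinct(long, .data$analyte, .data$age_months)
  purrr::pmap_dfr(grid, function(analyte, age_months) {
    sub <- long[long$analyte == analyte & long$age_months == age_months, ]
    v1 <- sub$value[sub[[by]] == levels2[1]]
    v2 <- sub$value[sub[[by]] == levels2[2]]
    if (length(v1) < 2 || length(v2) < 2) return(NULL)
    hb <- harris_boyd(length(v1), mean(v1), sd(v1),
                      length(v2), mean(v2), sd(v2),
                      sd_ratio_limit = sd_ratio_limit)
    dplyr::bind_cols(
      tibble(analyte = analyte, age_months = age_months,
             n1 = length(v1), n2 = length(v2)),
      tidy(hb)
    )
  })
}
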