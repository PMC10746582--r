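#' Fit a log-normal distribution to a median and interquartile range
#'
#' Published cohort tables summarise skewed analyte distributions as
#' "median (IQR)". A log-normal distribution is determined exactly by
#' those three numbers: its median fixes the log-scale location
#' (`log_median = log(median)`), and the IQR ratio fixes the log-scale
#' spread through `log(q75/q25) = 2 * z75 * log_sigma`, where `z75` is
#' the 75th standard-normal quantile (0.67449).
#'
#' @param median,q25,q75 Positive reals with `q25 < median < q75`
#'   (vectorised; lengths recycled).
#' @return A tibble with columns `log_median` and `log_sigma`.
#' @details The fitted distribution reproduces the given median exactly
#'   and has IQR ratio exactly `q75/q25`; the individual quartiles are
#'   matched exactly only when the summary itself is log-symmetric.
#' @export
#' @examples
#' fit_lognormal_median_iqr(51, 43, 63)  # AST-like summary
fit_lognormal_median_iqr <- function(median, q25, q75) {
  n <- max(length(median), length(q25), length(q75))
  median <- rep_len(as.double(median), n)
  q25 <- rep_len(as.double(q25), n)
  q75 <- rep_len(as.double(q75), n)
  bad <- is.na(median) | is.na(q25) | is.na(q75) |
    q25 <= 0 | !(q25 < median & median < q75)
  if (any(bad)) {
    abort(
      "Invalid summary: need 0 < q25 < median < q75 for every row.",
      class = "infantri_invalid_summary"
    )
  }
  z75 <- qnorm(0.75)
  tibble(
    log_median = log(median),
    log_sigma = log(q75 / q25) / (2 * z75)
  )
}

#' Exact quantiles of a fitted log-normal analyte distribution
#'
#' Closed-form ground truth for parameter-recovery checks: the
#' p-quantile of a log-normal with log-scale location `log_median` and
#' scale `log_sigma` is `exp(log_median + qnorm(p) * log_sigma)`.
#'
#' @param p Probability (or vector of probabilities) strictly in (0, 1).
#' @param log_median,log_sigma Log-scale location and (positive) scale.
#' @return Numeric vector of quantiles.
#' @export
#' @examples
#' lognormal_quantile(c(0.025, 0.5, 0.975), log(51), 0.283)
lognormal_quantile <- function(p, log_median, log_sigma) {
  if (any(is.na(p)) || any(p <= 0 | p >= 1)) {
    abort("`p` must lie strictly in (0, 1).")
  }
  if (any(log_sigma <= 0)) abort("`log_sigma` must be positive.")
  exp(log_median + qnorm(p) * log_sigma)
}

#' Quantiles of a mixture of log-normal components
#'
#' Pooled reference groups (e.g. the "all infants" column combining
#' breastfed and not-breastfed subgroups) follow a finite mixture of the
#' subgroup distributions. The mixture quantile has no closed form and
#' is found by root-finding on the mixture CDF.
#'
#' @param p Probability strictly in (0, 1) (scalar or vector).
#' @param log_median,log_sigma Numeric vectors of component parameters.
#' @param weights Positive component weights (normalised internally).
#' @return Numeric vector of mixture quantiles.
#' @export
#' @examples
#' lognormal_mixture_quantile(0.975, log(c(53, 45)), c(0.28, 0.22),
#'                            weights = c(226, 50))
lognormal_mixture_quantile <- function(p, log_median, log_sigma, weights) {
  if (any(p <= 0 | p >= 1)) abort("`p` must lie strictly in (0, 1).")
  w <- weights / sum(weights)
  cdf <- function(x) sum(w * plnorm(x, meanlog = log_median, sdlog = log_sigma))
  lo <- min(qlnorm(1e-9, log_median, log_sigma))
  hi <- max(qlnorm(1 - 1e-9, log_median, log_sigma))
  vapply(p, function(pp) {
    uniroot(function(x) cdf(x) - pp, lower = lo, upper = hi,
            tol = 1e-10)$root
  }, numeric(1))
}
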