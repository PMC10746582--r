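# Shared fixture builders: everything is generated in code at test time.

# A measurement tibble with n_cens values censored at loq and the rest
# observed at the given values.
make_series <- function(observed, n_cens = 0, loq = NA_real_) {
  tibble::tibble(
    value = c(rep(loq, n_cens), observed),
    censored = c(rep(TRUE, n_cens), rep(FALSE, length(observed))),
    loq = c(rep(loq, n_cens), rep(NA_real_, length(observed)))
  )
}

# A single-group cohort config with one overridden analyte spec;
# other analytes keep their defaults for that group.
one_group_config <- function(n, seed = 1, age = 3, feeding = "breastfed",
                             analyte = NULL, log_median = NULL,
                             log_sigma = NULL, loq = NULL,
                             crp_elevated_prob = 42 / 619) {
  specs <- default_analyte_specs()
  if (!is.null(analyte)) {
    i <- specs$age_months == age & specs$feeding == feeding &
      specs$analyte == analyte
    if (!is.null(log_median)) specs$log_median[i] <- log_median
    if (!is.null(log_sigma)) specs$log_sigma[i] <- log_sigma
    if (!is.null(loq)) specs$loq[i] <- loq
  }
  cohort_config(
    groups = tibble::tibble(
      age_months = age, feeding = feeding, n = as.integer(n),
      crp_elevated_prob = crp_elevated_prob
    ),
    analyte_specs = specs, seed = seed
  )
}

# Independent naive implementation of the rank-based limits: plain
# sort + index arithmetic + interpolation, written without reference
# to the package internals. Used as a brute-force oracle.
naive_rank_limits <- function(x, probs = c(0.025, 0.975)) {
  s <- sort(x)
  n <- length(s)
  sapply(probs, function(p) {
    r <- p * (n + 1)
    if (r <= 1) return(s[1])
    if (r >= n) return(s[n])
    k <- floor(r)
    s[k] + (r - k) * (s[k + 1] - s[k])
  })
}
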