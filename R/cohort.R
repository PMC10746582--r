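#' Default analyte distribution parameters for the synthetic cohort
#'
#' One row per age group x feeding group x analyte, giving the
#' log-normal parameters the generator draws from, the limit of
#' quantitation (LOQ) at which draws are left-censored, and — where the
#' parameters were fit from a published-style "median (IQR)" summary —
#' the summary itself. Groups whose summary quartiles (or median) were
#' themselves below the LOQ cannot be fit from the summary; those rows
#' carry explicit log-scale parameters chosen from the visible upper
#' quantile (`log_sigma = log(q75/median)/z75`) and have `NA` in the
#' summary columns that were censored.
#'
#' @return A tibble with columns `age_months`, `feeding`, `analyte`,
#'   `units`, `loq`, `median`, `q25`, `q75`, `log_median`, `log_sigma`.
#' @seealso [default_cohort_config()], [fit_lognormal_median_iqr()]
#' @export
default_analyte_specs <- function() {
  z75 <- qnorm(0.75)
  # helper rows: fit from full summary
  f <- function(age, feeding, analyte, loq, med, q25, q75) {
    par <- fit_lognormal_median_iqr(med, q25, q75)
    tibble(
      age_months = age, feeding = feeding, analyte = analyte,
      units = unname(PANEL_UNITS[analyte]), loq = loq,
      median = med, q25 = q25, q75 = q75,
      log_median = par$log_median, log_sigma = par$log_sigma
    )
  }
  # helper rows: explicit log-scale parameters (censored summaries);
  # sigma anchored on the visible upper quartile
  e <- function(age, feeding, analyte, loq, med, q75,
                med_visible = med >= loq) {
    tibble(
      age_months = age, feeding = feeding, analyte = analyte,
      units = unname(PANEL_UNITS[analyte]), loq = loq,
      median = if (med_visible) med else NA_real_,
      q25 = NA_real_, q75 = q75,
      log_median = log(med), log_sigma = log(q75 / med) / z75
    )
  }
  dplyr::bind_rows(
    ## 3 months, breastfed (n = 226)
    f(3, "breastfed", "Alb", 10, 41, 39, 43),
    f(3, "breastfed", "ALT", 9, 36, 24, 52),
    f(3, "breastfed", "AST", 5, 53, 43, 65),
    f(3, "breastfed", "ALP", 20, 294, 241, 350),
    f(3, "breastfed", "GGT", 7, 25, 20, 33),
    f(3, "breastfed", "BIL", 3, 7, 4, 10),
    e(3, "breastfed", "BIL_conj", 2, 2, 4),
    ## 3 months, not breastfed (n = 50)
    f(3, "not_breastfed", "Alb", 10, 41, 40, 43),
    f(3, "not_breastfed", "ALT", 9, 30, 11, 42),
    f(3, "not_breastfed", "AST", 5, 45, 38, 51),
    f(3, "not_breastfed", "ALP", 20, 288, 203, 326),
    f(3, "not_breastfed", "GGT", 7, 25, 21, 32),
    e(3, "not_breastfed", "BIL", 3, 4, 7),
    e(3, "not_breastfed", "BIL_conj", 2, 1.5, 3),
    ## 6 months, breastfed (n = 175)
    f(6, "breastfed", "Alb", 10, 43, 41, 45),
    f(6, "breastfed", "ALT", 9, 33, 22, 44),
    f(6, "breastfed", "AST", 5, 56, 48, 67),
    f(6, "breastfed", "ALP", 20, 241, 192, 298),
    f(6, "breastfed", "GGT", 7, 18, 15, 23),
    f(6, "breastfed", "BIL", 3, 5, 4, 8),
    e(6, "breastfed", "BIL_conj", 2, 1.5, 3),
    ## 6 months, not breastfed (n = 98)
    f(6, "not_breastfed", "Alb", 10, 43, 41, 45),
    f(6, "not_breastfed", "ALT", 9, 31, 24, 37),
    f(6, "not_breastfed", "AST", 5, 48, 42, 55),
    f(6, "not_breastfed", "ALP", 20, 286, 232, 328),
    f(6, "not_breastfed", "GGT", 7, 17, 14, 20),
    e(6, "not_breastfed", "BIL", 3, 4, 5),
    e(6, "not_breastfed", "BIL_conj", 2, 1.2, 2)
  )
}

#' Construct a cohort generator configuration
#'
#' @param groups A tibble with one row per (age, feeding) group and
#'   columns `age_months`, `feeding`, `n`, `crp_elevated_prob`; pairs
#'   must be unique and `n >= 0`.
#' @param analyte_specs Per-group analyte parameters as returned by
#'   [default_analyte_specs()]; every group must have one row per panel
#'   analyte.
#' @param seed Integer master seed. Each group draws from its own
#'   substream derived deterministically from the master seed and the
#'   group key, so adding or removing a group leaves the others'
#'   records unchanged.
#' @param crp_threshold CRP level (mg/L) above which a subject counts as
#'   CRP-elevated (acute-phase contamination of the reference sample).
#' @param crp_loq CRP limit of quantitation (mg/L); bulk draws below it
#'   are recorded as below range.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(groups,
                          analyte_specs = default_analyte_specs(),
                          seed = 1L,
                          crp_threshold = 4,
                          crp_loq = 1) {
  groups <- as_tibble(groups)
  stopifnot(
    all(c("age_months", "feeding", "n") %in% names(groups)),
    all(groups$n >= 0)
  )
  if (!"crp_elevated_prob" %in% names(groups)) {
    groups$crp_elevated_prob <- 42 / 619
  }
  if (any(groups$crp_elevated_prob < 0 | groups$crp_elevated_prob > 1)) {
    abort("`crp_elevated_prob` must lie in [0, 1].")
  }
  key <- paste(groups$age_months, groups$feeding)
  if (anyDuplicated(key)) {
    abort("Group (age_months, feeding) pairs must be unique.")
  }
  specs <- as_tibble(analyte_specs)
  for (i in seq_len(nrow(groups))) {
    have <- specs$analyte[specs$age_months == groups$age_months[i] &
                            specs$feeding == groups$feeding[i]]
    missing <- setdiff(PANEL_ANALYTES, have)
    if (groups$n[i] > 0 && length(missing)) {
      abort(sprintf(
        "Group (%s months, %s) lacks analyte spec(s): %s",
        groups$age_months[i], groups$feeding[i],
        paste(missing, collapse = ", ")
      ))
    }
  }
  if (any(specs$loq <= 0) || any(specs$log_sigma <= 0)) {
    abort("Analyte specs need positive `loq` and `log_sigma`.")
  }
  structure(
    list(
      groups = groups, analyte_specs = specs,
      seed = as.integer(seed), crp_threshold = crp_threshold,
      crp_loq = crp_loq
    ),
    class = "cohort_config"
  )
}

#' Default study-shaped cohort configuration
#'
#' Four groups — breastfed and not-breastfed infants at 3 and 6 months
#' with sizes 226, 50, 175 and 98 — with analyte distributions from
#' [default_analyte_specs()] and a CRP contamination probability of
#' 42/619 (about 6.8%) in every group.
#'
#' @inheritParams cohort_config
#' @return A `cohort_config` object.
#' @export
#' @examples
#' cfg <- default_cohort_config(seed = 42)
#' cfg$groups
default_cohort_config <- function(seed = 1L) {
  groups <- tibble(
    age_months = c(3, 3, 6, 6),
    feeding = c("breastfed", "not_breastfed", "breastfed", "not_breastfed"),
    n = c(226L, 50L, 175L, 98L),
    crp_elevated_prob = 42 / 619
  )
  cohort_config(groups, seed = seed)
}

# Deterministic per-group substream seed: a stable string hash folded
# into the master seed, kept below 2^31.
group_seed <- function(master, age_months, feeding) {
  key <- paste0(age_months, ":", feeding)
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483629
  as.integer((as.numeric(master) %% 2147483629 + h * 1000003) %% 2147483629)
}

#' Generate a synthetic infant cohort
#'
#' Draws one record per subject: age group, feeding group, sex
#' (balanced, no sex effect), CRP and the seven-analyte liver panel.
#' Analyte values are log-normal per the group's [default_analyte_specs()]-style
#' parameters; any draw strictly below the analyte's LOQ is recorded as
#' below range (`"<loq"`). CRP is a two-component mixture: with
#' probability `crp_elevated_prob` a uniform draw above the elevation
#' threshold (an acute-phase contaminant), otherwise a uniform draw in
#' (0, threshold], censored at the CRP LOQ.
#'
#' @param config A [cohort_config()] object.
#' @return A tibble with one row per subject and character measurement
#'   columns in laboratory cell notation (see [format_value()]):
#'   `subject_id`, `age_months`, `feeding`, `sex`, `crp`, then one
#'   column per panel analyte. Identical configs (including seed) give
#'   identical cohorts.
#' @seealso [write_cohort()], [cohort_measurements()]
#' @export
#' @examples
#' cohort <- generate_cohort(default_cohort_config(seed = 7))
#' dplyr::count(cohort, age_months, feeding)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- config$groups
  out <- vector("list", nrow(groups))
  for (g in seq_len(nrow(groups))) {
    n <- groups$n[g]
    if (n == 0) next
    age <- groups$age_months[g]
    feeding <- groups$feeding[g]
    specs <- config$analyte_specs[
      config$analyte_specs$age_months == age &
        config$analyte_specs$feeding == feeding, , drop = FALSE
    ]
    out[[g]] <- withr::with_seed(group_seed(config$seed, age, feeding), {
      rec <- tibble(
        subject_id = sprintf(
          "S%d%s%04d", age,
          if (feeding == "breastfed") "B" else "F", seq_len(n)
        ),
        age_months = age,
        feeding = feeding,
        sex = sample(c("female", "male"), n, replace = TRUE)
      )
      elevated <- runif(n) < groups$crp_elevated_prob[g]
      crp <- ifelse(
        elevated,
        runif(n, config$crp_threshold, 5 * config$crp_threshold),
        runif(n, 0, config$crp_threshold)
      )
      crp_cens <- !elevated & crp < config$crp_loq
      rec$crp <- format_value(
        ifelse(crp_cens, config$crp_loq, crp), crp_cens, config$crp_loq
      )
      for (an in PANEL_ANALYTES) {
        sp <- specs[specs$analyte == an, , drop = FALSE]
        x <- rlnorm(n, meanlog = sp$log_median, sdlog = sp$log_sigma)
        cens <- x < sp$loq
        rec[[an]] <- format_value(ifelse(cens, sp$loq, x), cens, sp$loq)
      }
      rec
    })
  }
  dplyr::bind_rows(out)
}

#' Write / read a cohort CSV
#'
#' The on-disk format is plain UTF-8 CSV with a header row, "." as the
#' decimal separator and below-range values serialized exactly as
#' `"<loq"` (no space). `read_cohort()` validates that every
#' measurement cell parses and that `age_months` and `feeding` take the
#' study's values.
#'
#' @param cohort A cohort tibble as produced by [generate_cohort()].
#' @param path File path.
#' @return `write_cohort()` returns `cohort` invisibly; `read_cohort()`
#'   returns the cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(cohort)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character())
  )
  required <- c("subject_id", "age_months", "feeding")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    abort(paste0("Cohort file lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  cohort$age_months <- as.numeric(cohort$age_months)
  if (!all(cohort$age_months %in% c(3, 6))) {
    abort("`age_months` must be 3 or 6 for every record.")
  }
  if (!all(cohort$feeding %in% FEEDING_LEVELS)) {
    abort("`feeding` must be 'breastfed' or 'not_breastfed'.")
  }
  for (col in intersect(c("crp", PANEL_ANALYTES), names(cohort))) {
    parse_value(cohort[[col]][!is.na(cohort[[col]])],
                context = paste("column", col))
  }
  cohort
}
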