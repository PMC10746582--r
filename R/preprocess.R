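#' Exclude subjects with elevated C-reactive protein
#'
#' Acute infection inflates liver biochemistry, so subjects whose CRP is
#' strictly above `threshold` are removed from the reference sample
#' before estimation. Below-range CRP (reported `"<loq"`) counts as
#' non-elevated whenever its LOQ does not exceed the threshold; a
#' censored CRP with LOQ above the threshold is indeterminate and a
#' validation error.
#'
#' @param cohort A cohort tibble (see [generate_cohort()] /
#'   [read_cohort()]) with a `crp` column; every record must have one.
#' @param threshold CRP exclusion threshold in mg/L (default 4; the
#'   boundary is strict, a CRP of exactly `threshold` is kept).
#' @return The kept records, in input order, with the excluded records
#'   attached as attribute `"excluded"` (retrieve with
#'   [excluded_records()]). Filtering the kept set again removes
#'   nothing.
#' @export
#' @examples
#' cohort <- generate_cohort(default_cohort_config(seed = 1))
#' kept <- exclude_elevated_crp(cohort)
#' nrow(excluded_records(kept))
exclude_elevated_crp <- function(cohort, threshold = 4) {
  stopifnot(threshold > 0)
  if (!"crp" %in% names(cohort)) {
    abort("Every record needs a CRP measurement (`crp` column).")
  }
  if (anyNA(cohort$crp) || any(!nzchar(trimws(cohort$crp)))) {
    abort("Every record needs a CRP measurement; found missing `crp`.")
  }
  m <- parse_value(cohort$crp, context = "column crp")
  bad <- m$censored & m$loq > threshold
  if (any(bad)) {
    abort(sprintf(
      "%d record(s) have below-range CRP with LOQ above the threshold (%g): indeterminate exclusion.",
      sum(bad), threshold
    ))
  }
  elevated <- !m$censored & m$value > threshold
  kept <- cohort[!elevated, , drop = FALSE]
  attr(kept, "excluded") <- cohort[elevated, , drop = FALSE]
  attr(kept, "crp_threshold") <- threshold
  kept
}

#' @rdname exclude_elevated_crp
#' @param kept The return value of `exclude_elevated_crp()`.
#' @export
excluded_records <- function(kept) {
  attr(kept, "excluded") %||% kept[0, , drop = FALSE]
}

#' Long-format parsed measurements of a cohort
#'
#' Pivots the per-subject analyte columns into one row per available
#' measurement and parses the laboratory cell notation.
#'
#' @param cohort A cohort tibble.
#' @return A tibble with columns `subject_id`, `age_months`, `feeding`,
#'   `sex` (if present), `analyte`, `value`, `censored`, `loq`. Missing
#'   cells are dropped.
#' @export
cohort_measurements <- function(cohort) {
  analytes <- intersect(PANEL_ANALYTES, names(cohort))
  if (!length(analytes)) abort("Cohort has no panel analyte columns.")
  id_cols <- intersect(c("subject_id", "age_months", "feeding", "sex"),
                       names(cohort))
  long <- tidyr::pivot_longer(
    cohort[c(id_cols, analytes)],
    cols = dplyr::all_of(analytes),
    names_to = "analyte", values_to = "cell"
  )
  long <- long[!is.na(long$cell) & nzchar(trimws(long$cell)), , drop = FALSE]
  parsed <- parse_value(long$cell, context = "panel")
  dplyr::bind_cols(long[setdiff(names(long), "cell")], parsed)
}

#' Extract one estimation series from a cohort
#'
#' Materialises the analyte x age x feeding grouping used throughout the
#' reporting: all measurements of `analyte` for subjects of the given
#' age, optionally restricted to one feeding group. Omitting `feeding`
#' pools both feeding groups (the "all infants" column).
#'
#' @param cohort A cohort tibble.
#' @param analyte One of the panel analytes (see [panel_analytes()]).
#' @param age_months 3 or 6.
#' @param feeding `"breastfed"`, `"not_breastfed"`, or `NULL` (pooled).
#' @return A measurement tibble (`value`, `censored`, `loq`), ordered
#'   with the below-range block first.
#' @export
#' @examples
#' cohort <- generate_cohort(default_cohort_config(seed = 1))
#' series <- extract_series(cohort, "AST", 3)
#' nrow(series)
extract_series <- function(cohort, analyte, age_months, feeding = NULL) {
  if (!analyte %in% PANEL_ANALYTES) {
    abort(sprintf("Unknown analyte '%s'; expected one of: %s",
                  analyte, paste(PANEL_ANALYTES, collapse = ", ")))
  }
  stopifnot(age_months %in% c(3, 6))
  if (!is.null(feeding) && !feeding %in% FEEDING_LEVELS) {
    abort("`feeding` must be 'breastfed', 'not_breastfed', or NULL.")
  }
  rows <- cohort$age_months == age_months
  if (!is.null(feeding)) rows <- rows & cohort$feeding == feeding
  cells <- if (analyte %in% names(cohort)) cohort[[analyte]][rows] else
    character(0)
  cells <- cells[!is.na(cells) & nzchar(trimws(cells))]
  series <- parse_value(cells, context = paste("column", analyte))
  sort_series(as_series(series))
}
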