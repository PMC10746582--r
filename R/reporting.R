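#' Format a reference limit with its confidence interval
#'
#' Renders a limit as `"V (L–H)"` with per-analyte rounding; censored
#' values and CI endpoints render as `"< x"`. Without a CI only the
#' value is printed (direct-percentile rows report no CIs).
#'
#' @param value Limit value.
#' @param censored Is the limit below the measuring range?
#' @param loq Limit of quantitation (used when `censored`, and to flag
#'   censored CI endpoints).
#' @param ci Optional numeric pair `(lo, hi)`.
#' @param decimals Digits after the decimal point (default 0).
#' @param dash Range separator (en dash for text output; pass `"-"`
#'   for ASCII-safe CSV).
#' @return A character scalar.
#' @export
#' @examples
#' format_limit(96.4, FALSE, NA, ci = c(92.1, 101.6))
#' format_limit(9, TRUE, 9, ci = c(9, 9))
format_limit <- function(value, censored, loq = NA, ci = NULL,
                         decimals = 0, dash = "–") {
  stopifnot(decimals >= 0)
  one <- function(v, cens) {
    if (isTRUE(cens)) sprintf("< %.*f", decimals, loq)
    else sprintf("%.*f", decimals, v)
  }
  txt <- one(if (isTRUE(censored)) loq else value, censored)
  if (!is.null(ci) && !anyNA(ci)) {
    lo_cens <- !is.na(loq) && ci[1] <= loq
    hi_cens <- !is.na(loq) && ci[2] <= loq
    # a censored top endpoint reads "(< 9– < 9)": space keeps "<" legible
    txt <- paste0(txt, " (", one(ci[1], lo_cens), dash,
                  if (hi_cens) " " else "", one(ci[2], hi_cens), ")")
  }
  txt
}

format_median_iqr <- function(med, med_cens, q25, q25_cens, q75,
                              q75_cens, loq, decimals = 0,
                              dash = "–") {
  one <- function(v, cens) {
    if (isTRUE(cens)) sprintf("< %.*f", decimals, loq)
    else sprintf("%.*f", decimals, v)
  }
  paste0(one(med, med_cens), " (", one(q25, q25_cens), dash,
         one(q75, q75_cens), ")")
}

#' Build a publication-style reference-interval report
#'
#' Assembles the estimation results (and optional feeding-group
#' comparisons) into a table shaped like a clinical reference-interval
#' publication: one logical row per analyte x age, with per-group
#' columns (all / breastfed / not breastfed) holding n,
#' "median (IQR)", "LL (90% CI)" and "UL (90% CI)", a per-row
#' nutrition p-value when comparisons ran, and footnotes aggregating
#' the outliers removed per cell. When a current-limits table is
#' supplied, each limit is flagged when the current limit lies outside
#' the estimated limit's confidence interval.
#'
#' @param results Tibble from [estimate_reference_intervals()]; the
#'   (analyte, age, group) keys must be unique.
#' @param comparisons Optional tibble from [compare_all_feeding()].
#' @param current_limits Optional tibble with columns `analyte`,
#'   `age_months`, `current_ll`, `current_ul`.
#' @param decimals Named integer vector of per-analyte decimals
#'   (default: 0 for every analyte, matching integer-unit reporting).
#' @return An object of class `ri_report`: list with `rows` (one row
#'   per analyte x age x group, formatted text fields), `footnotes`
#'   (analyte, age, group, outliers removed) and the input `results`.
#' @seealso [render_report()], [write_report()]
#' @export
build_report <- function(results, comparisons = NULL,
                         current_limits = NULL, decimals = NULL) {
  if (!nrow(results)) abort("`results` is empty.")
  key <- paste(results$analyte, results$age_months, results$group)
  if (anyDuplicated(key)) {
    abort(paste0("Duplicate series keys in results: ",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  dec_for <- function(analyte) {
    if (is.null(decimals)) 0L else as.integer(decimals[[analyte]] %||% 0L)
  }
  ord <- order(match(results$analyte, PANEL_ANALYTES),
               results$age_months,
               match(results$group, c("all", "breastfed", "not_breastfed")))
  results <- results[ord, , drop = FALSE]
  rows <- purrr::pmap_dfr(results, function(...) {
    r <- list(...)
    d <- dec_for(r$analyte)
    has_ci <- !is.na(r$lower_ci_lo)
    out <- tibble(
      analyte = r$analyte, units = r$units, age_months = r$age_months,
      group = r$group, n = r$n, method = r$method,
      median_iqr = format_median_iqr(
        r$median, r$median_censored, r$q25, r$q25_censored,
        r$q75, r$q75_censored, r$loq, d
      ),
      ll_text = format_limit(
        r$lower, r$lower_censored, r$loq,
        ci = if (has_ci) c(r$lower_ci_lo, r$lower_ci_hi), decimals = d
      ),
      ul_text = format_limit(
        r$upper, r$upper_censored, r$loq,
        ci = if (!is.na(r$upper_ci_lo)) c(r$upper_ci_lo, r$upper_ci_hi),
        decimals = d
      ),
      outliers_removed = r$outliers_removed
    )
    if (!is.null(current_limits)) {
      cl <- current_limits[current_limits$analyte == r$analyte &
                             current_limits$age_months == r$age_months, ]
      out$ll_outside_current <- if (nrow(cl) && has_ci) {
        cl$current_ll[1] < r$lower_ci_lo | cl$current_ll[1] > r$lower_ci_hi
      } else NA
      out$ul_outside_current <- if (nrow(cl) && has_ci) {
        cl$current_ul[1] < r$upper_ci_lo | cl$current_ul[1] > r$upper_ci_hi
      } else NA
    }
    out
  })
  if (!is.null(comparisons) && nrow(comparisons)) {
    rows <- dplyr::left_join(
      rows,
      dplyr::select(comparisons, "analyte", "age_months",
                    p_nutrition = "p_label"),
      by = c("analyte", "age_months")
    )
  }
  footnotes <- dplyr::filter(
    dplyr::select(rows, "analyte", "age_months", "group",
                  "outliers_removed"),
    .data$outliers_removed > 0
  )
  structure(
    list(rows = rows, footnotes = footnotes, results = results),
    class = "ri_report"
  )
}

#' Render a report as text
#'
#' @param report An `ri_report` from [build_report()].
#' @return A character vector of lines (invisibly printed by
#'   `print.ri_report`).
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "ri_report"))
  rows <- report$rows
  has_p <- "p_nutrition" %in% names(rows)
  header <- c("analyte", "age", "group", "n", "median (IQR)",
              "LL (90% CI)", "UL (90% CI)", if (has_p) "p(nutrition)")
  cells <- cbind(
    rows$analyte, rows$age_months, rows$group, rows$n, rows$median_iqr,
    rows$ll_text, rows$ul_text,
    if (has_p) tidyr::replace_na(rows$p_nutrition, "")
  )
  tab <- rbind(header, cells)
  widths <- apply(nchar(tab, type = "width"), 2, max)
  lines <- apply(tab, 1, function(r) {
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  ")
  })
  lines <- c(lines[1], strrep("-", sum(widths) + 2 * (length(widths) - 1)),
             lines[-1])
  if (nrow(report$footnotes)) {
    fn <- sprintf(
      "%s, %g months, %s: %d outlier(s) removed",
      report$footnotes$analyte, report$footnotes$age_months,
      report$footnotes$group, report$footnotes$outliers_removed
    )
    lines <- c(lines, "", "Outliers:", paste0("  ", fn))
  }
  lines
}

#' @export
print.ri_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Write a report to CSV (and optionally JSON)
#'
#' The CSV holds one row per analyte x age x group with the formatted
#' fields (hyphen range separators, ASCII-safe) plus the numeric
#' results; the JSON mirrors the full structured results.
#'
#' @param report An `ri_report`.
#' @param path CSV output path.
#' @param json_path Optional JSON output path.
#' @return `report`, invisibly.
#' @export
write_report <- function(report, path, json_path = NULL) {
  stopifnot(inherits(report, "ri_report"))
  rows <- report$rows
  for (col in c("median_iqr", "ll_text", "ul_text")) {
    rows[[col]] <- gsub("–", "-", rows[[col]])
  }
  numeric_cols <- dplyr::select(
    report$results, "analyte", "age_months", "group", "method",
    "n_used", "lower", "lower_censored", "lower_ci_lo", "lower_ci_hi",
    "upper", "upper_censored", "upper_ci_lo", "upper_ci_hi"
  )
  out <- dplyr::left_join(rows, numeric_cols,
                          by = c("analyte", "age_months", "group",
                                 "method"))
  readr::write_csv(out, path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(rows = report$rows, footnotes = report$footnotes,
           results = report$results),
      json_path, auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  invisible(report)
}
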