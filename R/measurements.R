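#' Parse laboratory result cells, including below-range values
#'
#' Clinical laboratories report results below the measuring range as
#' `"<x"` (optionally with internal whitespace, e.g. `"< 9"`), where `x`
#' is the limit of quantitation (LOQ). `parse_value()` turns a character
#' vector of such cells into a measurement tibble; left-censored cells
#' get `censored = TRUE` and carry the LOQ both as `loq` and as `value`
#' (the semantic reading of such a row is "result < loq").
#'
#' @param x Character vector of raw cells (`"35"`, `"< 9"`, ...). `NA`
#'   cells propagate as all-`NA` rows (missing measurement).
#' @param context Optional label (e.g. `"row 3, column ALT"`) used in
#'   error messages.
#' @return A tibble with columns `value` (double), `censored` (logical)
#'   and `loq` (double, `NA` unless censored), one row per element.
#' @details Analyte concentrations are strictly positive: zero, negative
#'   or non-numeric payloads are a parse error. `parse_value()` and
#'   [format_value()] round-trip bit-exactly on valid input.
#' @seealso [format_value()]
#' @export
#' @examples
#' parse_value(c("35", "< 9", "<2"))
parse_value <- function(x, context = NULL) {
  x <- as.character(x)
  out <- tibble(
    value = rep(NA_real_, length(x)),
    censored = rep(NA, length(x)),
    loq = rep(NA_real_, length(x))
  )
  miss <- is.na(x) | !nzchar(trimws(x))
  raw <- trimws(x[!miss])
  cens <- startsWith(raw, "<")
  payload <- trimws(sub("^<", "", raw))
  num <- suppressWarnings(as.numeric(payload))
  bad <- is.na(num) | num <= 0
  if (any(bad)) {
    where <- if (is.null(context)) "" else paste0(" (", context, ")")
    abort(
      paste0(
        "Cannot parse measurement value(s)", where, ": ",
        paste(utils::head(unique(raw[bad]), 5), collapse = ", "),
        " -- expected a positive numeral or \"<x\" with positive x."
      ),
      class = "infantri_parse_error"
    )
  }
  out$value[!miss] <- num
  out$censored[!miss] <- cens
  out$loq[!miss] <- ifelse(cens, num, NA_real_)
  out
}

#' Serialize measurements back to laboratory cell notation
#'
#' Inverse of [parse_value()]: censored measurements render as
#' `"<loq"` (no space, `%g`-style formatting of the limit), observed
#' values as their shortest exact decimal representation, so that
#' `parse_value(format_value(...))` reproduces the input exactly.
#'
#' @param value Numeric vector of measurement values.
#' @param censored Logical vector; `TRUE` for below-range results.
#' @param loq Numeric vector of limits of quantitation (used only where
#'   `censored` is `TRUE`).
#' @return Character vector of cells; `NA` values give `NA` cells.
#' @export
#' @examples
#' format_value(c(35, 9), c(FALSE, TRUE), c(NA, 9))
format_value <- function(value, censored, loq = value) {
  n <- length(value)
  censored <- rep_len(censored, n)
  loq <- rep_len(loq, n)
  out <- rep(NA_character_, n)
  ok <- !is.na(value) & !is.na(censored)
  out[ok & censored] <- sprintf("<%g", loq[ok & censored])
  obs <- ok & !censored
  # shortest decimal that parses back to the identical double
  out[obs] <- vapply(value[obs], function(v) {
    s <- sprintf("%.15g", v)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, character(1))
  out
}

# Coerce a numeric vector or data frame into the canonical measurement
# tibble (value, censored, loq), dropping missing values.
as_series <- function(x, arg = "series") {
  if (is.numeric(x)) {
    x <- tibble(value = as.double(x), censored = FALSE, loq = NA_real_)
  } else if (is.data.frame(x)) {
    if (!"value" %in% names(x)) {
      abort(sprintf("`%s` must have a `value` column.", arg))
    }
    x <- tibble(
      value = as.double(x$value),
      censored = if ("censored" %in% names(x)) {
        tidyr::replace_na(as.logical(x$censored), FALSE)
      } else FALSE,
      loq = if ("loq" %in% names(x)) as.double(x$loq) else NA_real_
    )
  } else {
    abort(sprintf("`%s` must be a numeric vector or a data frame.", arg))
  }
  x <- x[!is.na(x$value), , drop = FALSE]
  bad <- x$censored & (is.na(x$loq) | abs(x$value - x$loq) > 1e-12)
  if (any(bad)) x$loq[bad] <- x$value[bad]
  x
}

# Highest LOQ among censored members of a series (NA if none censored).
series_loq <- function(series) {
  if (!any(series$censored)) return(NA_real_)
  max(series$loq[series$censored], na.rm = TRUE)
}

# Sort a measurement tibble by value, censored values first within ties,
# i.e. the below-range block sits at the bottom of the ranking.
sort_series <- function(series) {
  series[order(series$value, !series$censored), , drop = FALSE]
}
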