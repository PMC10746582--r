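#' Read / write a cohort configuration file
#'
#' The configuration format is a flat, TOML-style plain-text file:
#' `key = value` pairs, optionally under `[section]` headers, with `#`
#' comments. Top-level keys are `seed`, `crp_threshold`, `crp_loq`.
#' Each group lives under `[group.<age>.<feeding>]` with keys `n` and
#' `crp_elevated_prob`, and each analyte under
#' `[group.<age>.<feeding>.<analyte>]` with keys `loq` plus either
#' `median`/`q25`/`q75` (fit via [fit_lognormal_median_iqr()]) or
#' explicit `log_median`/`log_sigma`.
#'
#' @param path File path.
#' @param config A [cohort_config()] object.
#' @return `read_cohort_config()` returns a `cohort_config`;
#'   `write_cohort_config()` returns `config` invisibly. The two
#'   functions round-trip.
#' @export
read_cohort_config <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  kv <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) {
      abort(sprintf("Cannot parse config line: %s", ln))
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    kv[[paste0(section, if (nzchar(section)) "." else "", key)]] <-
      if (!is.na(num)) num else val
  }
  keys <- names(kv)
  grp_keys <- grep("^group\\.", keys, value = TRUE)
  parts <- strsplit(grp_keys, ".", fixed = TRUE)
  grp_id <- vapply(parts, function(p) paste(p[2], p[3], sep = "."),
                   character(1))
  groups <- list()
  specs <- list()
  for (id in unique(grp_id)) {
    p <- strsplit(id, ".", fixed = TRUE)[[1]]
    age <- as.numeric(p[1]); feeding <- p[2]
    pre <- paste0("group.", id, ".")
    get <- function(k, default = NULL) kv[[paste0(pre, k)]] %||% default
    groups[[id]] <- tibble(
      age_months = age, feeding = feeding,
      n = as.integer(get("n", 0)),
      crp_elevated_prob = as.numeric(get("crp_elevated_prob", 42 / 619))
    )
    sub_keys <- grep(paste0("^", gsub("\\.", "\\\\.", pre)), keys,
                     value = TRUE)
    ans <- unique(vapply(
      strsplit(sub_keys, ".", fixed = TRUE),
      function(q) if (length(q) >= 5) q[4] else NA_character_,
      character(1)
    ))
    for (an in ans[!is.na(ans)]) {
      apre <- paste0(pre, an, ".")
      aget <- function(k) kv[[paste0(apre, k)]]
      loq <- as.numeric(aget("loq"))
      if (!is.null(aget("log_median")) && !is.null(aget("log_sigma"))) {
        lm <- as.numeric(aget("log_median")); ls <- as.numeric(aget("log_sigma"))
        med <- aget("median"); q25 <- aget("q25"); q75 <- aget("q75")
      } else {
        med <- as.numeric(aget("median"))
        q25 <- as.numeric(aget("q25")); q75 <- as.numeric(aget("q75"))
        par <- fit_lognormal_median_iqr(med, q25, q75)
        lm <- par$log_median; ls <- par$log_sigma
      }
      specs[[paste0(id, ".", an)]] <- tibble(
        age_months = age, feeding = feeding, analyte = an,
        units = unname(PANEL_UNITS[an]) %||% NA_character_, loq = loq,
        median = as.numeric(med %||% NA_real_),
        q25 = as.numeric(q25 %||% NA_real_),
        q75 = as.numeric(q75 %||% NA_real_),
        log_median = lm, log_sigma = ls
      )
    }
  }
  cohort_config(
    groups = dplyr::bind_rows(groups),
    analyte_specs = dplyr::bind_rows(specs),
    seed = as.integer(kv[["seed"]] %||% 1L),
    crp_threshold = as.numeric(kv[["crp_threshold"]] %||% 4),
    crp_loq = as.numeric(kv[["crp_loq"]] %||% 1)
  )
}

#' @rdname read_cohort_config
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  out <- c(
    paste0("seed = ", config$seed),
    paste0("crp_threshold = ", num(config$crp_threshold)),
    paste0("crp_loq = ", num(config$crp_loq)),
    ""
  )
  for (g in seq_len(nrow(config$groups))) {
    row <- config$groups[g, ]
    id <- paste0("group.", row$age_months, ".", row$feeding)
    out <- c(
      out, paste0("[", id, "]"),
      paste0("n = ", row$n),
      paste0("crp_elevated_prob = ", num(row$crp_elevated_prob))
    )
    specs <- config$analyte_specs[
      config$analyte_specs$age_months == row$age_months &
        config$analyte_specs$feeding == row$feeding, , drop = FALSE
    ]
    for (a in seq_len(nrow(specs))) {
      sp <- specs[a, ]
      out <- c(
        out, paste0("[", id, ".", sp$analyte, "]"),
        paste0("loq = ", num(sp$loq)),
        if (!is.na(sp$median)) paste0("median = ", num(sp$median)),
        if (!is.na(sp$q25)) paste0("q25 = ", num(sp$q25)),
        if (!is.na(sp$q75)) paste0("q75 = ", num(sp$q75)),
        paste0("log_median = ", num(sp$log_median)),
        paste0("log_sigma = ", num(sp$log_sigma))
      )
    }
    out <- c(out, "")
  }
  writeLines(out, path, useBytes = FALSE)
  invisible(config)
}
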