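#' Dichotomization rule
#'
#' Describes how one raw variable is collapsed to a 0/1 deprivation
#' indicator. The level coded 1 is always the deprivation-associated level,
#' so that every item relates monotonically (increasing) to the latent
#' trait. Two rule types are supported: `"threshold_lt"` codes numeric
#' values strictly below `threshold` as 1 (so a value exactly at the
#' threshold is non-deprived, matching the "$1500 or more a month" income
#' convention), and `"levels"` codes membership of `deprived` as 1 and of
#' `other` as 0.
#'
#' @param variable raw column name.
#' @param item output item name (defaults to `variable`).
#' @param type `"threshold_lt"` or `"levels"`.
#' @param threshold numeric cut point for `"threshold_lt"`.
#' @param deprived,other character vectors of raw levels for `"levels"`.
#' @return an object of class `dichot_rule`.
#' @export
dichot_rule <- function(variable, item = variable,
                        type = c("levels", "threshold_lt"),
                        threshold = NULL, deprived = NULL, other = NULL) {
  type <- match.arg(type)
  if (type == "threshold_lt" && !is.numeric(threshold))
    stopf("rule for '%s': threshold_lt needs a numeric threshold", variable)
  if (type == "levels" && (is.null(deprived) || is.null(other)))
    stopf("rule for '%s': levels rule needs deprived and other levels", variable)
  structure(list(variable = variable, item = item, type = type,
                 threshold = threshold, deprived = deprived, other = other),
            class = "dichot_rule")
}

#' Default dichotomization rules for the 19 candidate indicators
#'
#' One rule per candidate variable, coding the deprivation-associated level
#' as 1: income below $1500/month, education high school or less,
#' unemployment, not identifying as gay or bisexual, Indigenous status,
#' injection drug use (ever and last 6 months), incarceration history, past
#' psychiatric hospitalization, and the remaining screened candidates.
#'
#' @return named list of [dichot_rule()] objects keyed by item name.
#' @export
ccc_rules <- function() {
  rules <- lapply(raw_item_map(), function(m) {
    if (m$type == "threshold_lt")
      dichot_rule(m$column, m$item, "threshold_lt", threshold = m$threshold)
    else
      dichot_rule(m$column, m$item, "levels", deprived = m$deprived,
                  other = m$other)
  })
  names(rules) <- vapply(rules, `[[`, "", "item")
  rules
}

#' Dichotomize raw variables into deprivation-direction items
#'
#' Applies a list of [dichot_rule()]s to a raw table, producing one
#' 0/1/`NA` column per rule, with 1 always the deprived direction. Raw
#' missing values (`NA` or empty strings) become `NA`; any non-missing raw
#' value not covered by a rule's levels is an error.
#'
#' @param records raw data.frame; must contain every rule's `variable`, and
#'   `id`/`province` columns are carried through if present.
#' @param rules list of [dichot_rule()]s.
#' @return data.frame of items (plus id/province/other carried columns),
#'   with attribute `items` listing the item column names.
#' @export
dichotomize <- function(records, rules) {
  vars <- vapply(rules, `[[`, "", "variable")
  missing_vars <- setdiff(vars, names(records))
  if (length(missing_vars))
    stopf("variables not found in records: %s",
          paste(missing_vars, collapse = ", "))
  carried <- intersect(c("id", "province", "outcome"), names(records))
  out <- records[, carried, drop = FALSE]
  for (r in rules) {
    x <- records[[r$variable]]
    if (is.character(x)) x[!nzchar(trimws(x))] <- NA
    if (r$type == "threshold_lt") {
      x <- suppressWarnings(as.numeric(x))
      v <- ifelse(is.na(x), NA_integer_, as.integer(x < r$threshold))
    } else {
      x <- as.character(x)
      bad <- !is.na(x) & !(x %in% c(r$deprived, r$other))
      if (any(bad))
        stopf("rule '%s': unexpected level(s) %s", r$item,
              paste(unique(x[bad]), collapse = ", "))
      v <- ifelse(is.na(x), NA_integer_, as.integer(x %in% r$deprived))
    }
    out[[r$item]] <- v
  }
  attr(out, "items") <- unname(vapply(rules, `[[`, "", "item"))
  out
}

new_exclusion_report <- function(n_input, n_after_province_filter, n_complete,
                                 excluded_provinces = NULL,
                                 per_item_missing = NULL) {
  structure(list(n_input = n_input,
                 n_after_province_filter = n_after_province_filter,
                 n_complete = n_complete,
                 excluded_provinces = excluded_provinces,
                 per_item_missing = per_item_missing),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Exclusion report: %d -> %d (province filter) -> %d (complete cases)\n",
              x$n_input, x$n_after_province_filter, x$n_complete))
  if (length(x$excluded_provinces))
    cat("  excluded provinces:",
        paste(sprintf("%s (n = %d)", names(x$excluded_provinces),
                      x$excluded_provinces), collapse = ", "), "\n")
  invisible(x)
}

#' Drop provinces too small to support province-level parameters
#'
#' Removes all rows from provinces with fewer than `min_n` participants.
#' The default of 100 reproduces the published exclusion of the two
#' smallest provinces (n = 13 and n = 47).
#'
#' @param data item data.frame with a `province` column.
#' @param min_n minimum province size retained.
#' @return list with `data` (filtered) and `report` (exclusion_report).
#' @export
filter_small_provinces <- function(data, min_n = 100) {
  stopifnot(min_n >= 1)
  sizes <- table(data$province)
  drop <- names(sizes)[sizes < min_n]
  if (length(drop) == length(sizes))
    stopf("all provinces fall below min_n = %d", min_n)
  keep <- !(data$province %in% drop)
  out <- data[keep, , drop = FALSE]
  excl <- as.integer(sizes[drop]); names(excl) <- drop
  rep <- new_exclusion_report(nrow(data), nrow(out), NA_integer_,
                              excluded_provinces = excl)
  list(data = out, report = rep)
}

#' Restrict to complete cases on a set of items
#'
#' Removes every row with a missing value in any of `items` (no
#' imputation), reporting per-item missing counts.
#'
#' @param data item data.frame.
#' @param items character vector of item columns (default: the `items`
#'   attribute).
#' @return list with `data` (complete cases) and `report`.
#' @export
complete_cases <- function(data, items = attr(data, "items")) {
  if (is.null(items)) stopf("items must be given")
  missing_items <- setdiff(items, names(data))
  if (length(missing_items))
    stopf("items not present: %s", paste(missing_items, collapse = ", "))
  sub <- data[, items, drop = FALSE]
  per_item <- vapply(sub, function(v) sum(is.na(v)), 0L)
  ok <- stats::complete.cases(sub)
  if (!any(ok)) stopf("no complete cases remain")
  out <- data[ok, , drop = FALSE]
  attr(out, "items") <- items
  rep <- new_exclusion_report(nrow(data), nrow(data), nrow(out),
                              per_item_missing = per_item)
  list(data = out, report = rep)
}
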