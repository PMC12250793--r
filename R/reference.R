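# Percentile / LMS reference tables.
#
# Long format, one row per (sex, age knot, variable): columns sex,
# age_years, variable, then any of L, M, S, p10, p50, p90. Thresholds are
# linearly interpolated in age between knots; an age outside the tabulated
# range is a coverage error, never a clamp.

REF_COLS <- c("sex", "age_years", "variable")

#' Build a reference provider from a long-format table
#'
#' @param tab data.frame with columns `sex`, `age_years`, `variable` and at
#'   least one of `L`, `M`, `S`, `p10`, `p50`, `p90`.
#' @return an object of class `pedmets_reference`.
#' @export
as_reference <- function(tab) {
  if (!all(REF_COLS %in% names(tab)))
    pm_schema_error("reference table must have columns %s",
                    paste(REF_COLS, collapse = ", "))
  tab$sex <- validate_sex(tab$sex)
  value_cols <- setdiff(names(tab), REF_COLS)
  if (!length(value_cols))
    pm_schema_error("reference table has no value columns")
  tab <- tab[order(tab$variable, tab$sex, tab$age_years), ]
  structure(list(table = tab, value_cols = value_cols),
            class = "pedmets_reference")
}

#' Read a reference table CSV
#'
#' @param path CSV file in the long reference dialect.
#' @return `pedmets_reference` object.
#' @export
read_reference_tables <- function(path) {
  if (!file.exists(path)) pm_schema_error("reference file not found: %s", path)
  as_reference(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a reference object back to CSV
#'
#' @param ref `pedmets_reference`.
#' @param path output CSV path.
#' @export
write_reference_tables <- function(ref, path) {
  utils::write.csv(ref$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up an age-interpolated reference value
#'
#' Linear interpolation between tabulated age knots, separately by sex.
#' Ages outside the tabulated range, or a (variable, statistic) pair the
#' reference does not carry, raise a coverage error.
#'
#' @param ref `pedmets_reference`.
#' @param variable variable name, e.g. "wc", "sbp", "tg", "hdl", "bmi".
#' @param sex "F"/"M", recycled against `age`.
#' @param age ages in years.
#' @param stat which column: "p90", "p10", "p50", "L", "M" or "S".
#' @return numeric vector of thresholds in the measured unit.
#' @export
ref_lookup <- function(ref, variable, sex, age, stat) {
  stopifnot(inherits(ref, "pedmets_reference"))
  if (!stat %in% ref$value_cols)
    pm_coverage_error("reference carries no '%s' column", stat)
  sex <- rep_len(validate_sex(sex), length(age))
  out <- rep(NA_real_, length(age))
  for (s in unique(sex)) {
    sub <- ref$table[ref$table$variable == variable & ref$table$sex == s, ]
    sub <- sub[!is.na(sub[[stat]]), ]
    if (nrow(sub) < 2)
      pm_coverage_error("reference lacks '%s' (%s) curve for sex %s",
                        variable, stat, s)
    idx <- sex == s
    a <- age[idx]
    if (any(a < min(sub$age_years) - 1e-9 | a > max(sub$age_years) + 1e-9))
      pm_coverage_error("age outside reference coverage [%g, %g] for %s/%s",
                        min(sub$age_years), max(sub$age_years), variable, s)
    out[idx] <- stats::approx(sub$age_years, sub[[stat]], xout = a,
                              rule = 1)$y
  }
  out
}

#' @export
print.pedmets_reference <- function(x, ...) {
  cat("<pedmets_reference>", length(unique(x$table$variable)), "variables,",
      "ages", min(x$table$age_years), "-", max(x$table$age_years),
      "| columns:", paste(x$value_cols, collapse = ", "), "\n")
  invisible(x)
}
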