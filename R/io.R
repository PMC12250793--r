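# Cohort CSV I/O with row-level validation.

COHORT_SCHEMA <- c(
  "id", "age_years", "sex", "tanner", "weight_kg", "height_cm", "waist_cm",
  "fm_kg", "ffm_kg", "glucose_mgdl", "insulin_uUml", "hba1c_pct",
  "tc_mgdl", "hdl_mgdl", "tg_mgdl", "sbp_mmhg", "dbp_mmhg",
  "rx_lipid", "rx_bp", "dx_igt_t2dm")

OPTIONAL_COLS <- c("tanner", "fm_kg", "ffm_kg", "hba1c_pct")

#' Cohort CSV schema
#'
#' Column names of the cohort table, in order: one row per subject, header
#' fixed, UTF-8, "." decimal separator. `tanner`, `fm_kg`, `ffm_kg` and
#' `hba1c_pct` may be empty (optional measurements); every other field is
#' required.
#'
#' @return character vector of column names.
#' @export
cohort_schema <- function() COHORT_SCHEMA

validate_rows <- function(tab) {
  n <- nrow(tab)
  errs <- character(0)
  bad <- rep(FALSE, n)
  flag_bad <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    if (any(cond)) {
      errs <<- c(errs, sprintf("row %d: %s", which(cond), msg))
      bad <<- bad | cond
    }
  }
  flag_bad(!tab$sex %in% c("F", "M"), "sex must be F or M")
  flag_bad(is.na(tab$age_years) | tab$age_years < 0 | tab$age_years > 25,
           "age_years outside [0, 25]")
  for (col in setdiff(COHORT_SCHEMA, c("id", "sex", "age_years",
                                       "rx_lipid", "rx_bp", "dx_igt_t2dm"))) {
    required <- !col %in% OPTIONAL_COLS
    v <- suppressWarnings(as.numeric(tab[[col]]))
    flag_bad(if (required) is.na(v) else rep(FALSE, n),
             sprintf("%s missing or unparseable", col))
    flag_bad(!is.na(v) & v <= 0, sprintf("%s must be positive", col))
  }
  for (col in c("rx_lipid", "rx_bp", "dx_igt_t2dm"))
    flag_bad(!tab[[col]] %in% c(0, 1), sprintf("%s must be 0/1", col))
  both <- !is.na(tab$fm_kg) & !is.na(tab$ffm_kg)
  flag_bad(both & tab$fm_kg + tab$ffm_kg > tab$weight_kg * 1.05,
           "fm_kg + ffm_kg exceeds weight_kg by more than 5%")
  list(bad = bad, errors = errs)
}

#' Read and validate a cohort CSV
#'
#' The header must match [cohort_schema()] exactly (a mismatch is a schema
#' error). Rows failing validation (unknown sex, nonpositive measurements,
#' DXA masses exceeding body weight) are rejected, never coerced; rejected
#' row messages are attached as `attr(, "row_errors")` and surfaced as a
#' warning.
#'
#' @param path CSV file path.
#' @return validated cohort data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) pm_schema_error("cohort file not found: %s", path)
  # read everything as character first: "F" must stay a sex, not a logical
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!identical(names(tab), COHORT_SCHEMA))
    pm_schema_error("cohort header mismatch; expected: %s",
                    paste(COHORT_SCHEMA, collapse = ", "))
  for (col in setdiff(COHORT_SCHEMA, c("id", "sex")))
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  v <- validate_rows(tab)
  if (length(v$errors)) {
    warning(sprintf("rejected %d invalid cohort row(s)", sum(v$bad)),
            call. = FALSE)
    tab <- tab[!v$bad, , drop = FALSE]
    rownames(tab) <- NULL
  }
  attr(tab, "row_errors") <- v$errors
  tab
}

#' Write a cohort table as CSV
#'
#' @param cohort cohort data.frame in the package schema.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort[, COHORT_SCHEMA], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
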