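# Anthropometric, body-composition and lipid-ratio indices.
#
# Unit conventions (documented per function): weight kg, height and waist cm
# at the interface; composites that need meters (ABSI, BMFI) convert
# internally. Lipids are mg/dL at the interface; VAI converts to mmol/L.

#' Unit conversions for lipids
#'
#' Fixed enzymatic-assay conversion factors: triglycerides mg/dL / 88.57 =
#' mmol/L; cholesterol (total or HDL) mg/dL / 38.67 = mmol/L.
#'
#' @param x numeric vector in mg/dL (or mmol/L for the inverse functions).
#' @return numeric vector in the other unit.
#' @export
tg_mgdl_to_mmol <- function(x) x / 88.57

#' @rdname tg_mgdl_to_mmol
#' @export
tg_mmol_to_mgdl <- function(x) x * 88.57

#' @rdname tg_mgdl_to_mmol
#' @export
chol_mgdl_to_mmol <- function(x) x / 38.67

#' @rdname tg_mgdl_to_mmol
#' @export
chol_mmol_to_mgdl <- function(x) x * 38.67

#' Body mass index
#'
#' @param weight body weight in kg.
#' @param height standing height in cm.
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' compute_bmi(50, 200) # 12.5
compute_bmi <- function(weight, height) {
  check_positive(weight, "weight")
  check_positive(height, "height")
  weight / (height / 100)^2
}

#' Tri-ponderal mass index
#'
#' Mass over height cubed, proposed as a more age-stable adiposity measure
#' than BMI in adolescents.
#'
#' @inheritParams compute_bmi
#' @return TMI in kg/m^3.
#' @export
compute_tmi <- function(weight, height) {
  check_positive(weight, "weight")
  check_positive(height, "height")
  weight / (height / 100)^3
}

#' Fat-mass and fat-free-mass indices
#'
#' DXA-derived mass over height squared. Missing mass (NA) propagates to an
#' NA index; it is never coerced to zero.
#'
#' @param fat_mass,fat_free_mass DXA mass in kg (NA if not measured).
#' @param height standing height in cm.
#' @return index in kg/m^2.
#' @export
compute_fmi <- function(fat_mass, height) {
  check_positive(fat_mass, "fat_mass")
  check_positive(height, "height")
  fat_mass / (height / 100)^2
}

#' @rdname compute_fmi
#' @export
compute_ffmi <- function(fat_free_mass, height) {
  check_positive(fat_free_mass, "fat_free_mass")
  check_positive(height, "height")
  fat_free_mass / (height / 100)^2
}

#' Body mass fat index
#'
#' BMI x fat-mass fraction x waist circumference in meters. The fat-mass
#' share enters as a fraction in (0,1) and waist in meters: with those units
#' the composite sits on the ~10 scale typical of pediatric cohorts, whereas
#' percent and centimeters would inflate it by 10^4.
#'
#' @param bmi BMI in kg/m^2.
#' @param fm_fraction fat mass as a fraction of body weight, in (0,1).
#' @param waist waist circumference in cm.
#' @return dimensionless composite.
#' @export
compute_bmfi <- function(bmi, fm_fraction, waist) {
  check_positive(bmi, "bmi")
  check_positive(waist, "waist")
  if (any(!is.na(fm_fraction) & (fm_fraction <= 0 | fm_fraction >= 1)))
    pm_domain_error("'fm_fraction' must lie in (0,1); pass a fraction, not a percent")
  bmi * fm_fraction * (waist / 100)
}

#' A body shape index (ABSI)
#'
#' Waist circumference normalized by BMI^(2/3) * height^(1/2), isolating
#' central adiposity from overall size. Waist and height are converted to
#' meters internally, giving values near 0.08 in children.
#'
#' @param waist waist circumference in cm.
#' @param bmi BMI in kg/m^2.
#' @param height standing height in cm.
#' @return dimensionless index.
#' @export
compute_absi <- function(waist, bmi, height) {
  check_positive(waist, "waist")
  check_positive(bmi, "bmi")
  check_positive(height, "height")
  (waist / 100) / (bmi^(2 / 3) * (height / 100)^(1 / 2))
}

#' Visceral adiposity index
#'
#' Sex-specific composite of waist, BMI and lipids, normalized so a healthy
#' reference subject scores ~1. Lipids must be supplied in mmol/L (use
#' [tg_mgdl_to_mmol()] / [chol_mgdl_to_mmol()] to convert). The default
#' parenthesization is the original definition, WC / (c1 + c2 * BMI); the
#' widely reprinted mis-bracketed form WC/c1 + c2 * BMI is available with
#' `literal = TRUE` for sensitivity analysis.
#'
#' @param sex "F" or "M" (recycled).
#' @param waist waist circumference in cm.
#' @param bmi BMI in kg/m^2.
#' @param tg fasting triglycerides in mmol/L.
#' @param hdl HDL cholesterol in mmol/L.
#' @param literal use the mis-bracketed printed form of the waist term.
#' @return dimensionless index.
#' @export
compute_vai <- function(sex, waist, bmi, tg, hdl, literal = FALSE) {
  sex <- validate_sex(sex)
  check_positive(waist, "waist")
  check_positive(bmi, "bmi")
  check_positive(tg, "tg")
  check_positive(hdl, "hdl")
  male <- sex == "M"
  wc_term <- if (literal) {
    ifelse(male, waist / 39.68 + 1.88 * bmi, waist / 36.58 + 1.89 * bmi)
  } else {
    ifelse(male, waist / (39.68 + 1.88 * bmi), waist / (36.58 + 1.89 * bmi))
  }
  lip_term <- ifelse(male, (tg / 1.03) * (1.31 / hdl), (tg / 0.81) * (1.52 / hdl))
  wc_term * lip_term
}

#' Waist-to-height ratio
#'
#' @param waist waist circumference in cm.
#' @param height standing height in cm.
#' @return dimensionless ratio.
#' @export
compute_wthr <- function(waist, height) {
  check_positive(waist, "waist")
  check_positive(height, "height")
  waist / height
}

#' Cardiometabolic index
#'
#' Waist-to-height ratio times the TG/HDL-C ratio.
#'
#' @param wthr waist-to-height ratio.
#' @param tg_hdl triglycerides/HDL-C ratio (same units top and bottom).
#' @return dimensionless index.
#' @export
compute_cmi <- function(wthr, tg_hdl) {
  if (any(!is.na(wthr) & wthr < 0) || any(!is.na(tg_hdl) & tg_hdl < 0))
    pm_domain_error("cmi inputs must be nonnegative")
  wthr * tg_hdl
}

#' Lipid ratios
#'
#' TC/HDL-C and TG/HDL-C. Unit-free provided numerator and denominator share
#' units (conventionally mg/dL).
#'
#' @param total_chol total cholesterol, mg/dL.
#' @param hdl HDL cholesterol, mg/dL.
#' @param tg triglycerides, mg/dL.
#' @return list with elements `tc_hdl` and `tg_hdl`.
#' @export
compute_lipid_ratios <- function(total_chol, hdl, tg) {
  if (any(!is.na(hdl) & hdl <= 0)) pm_domain_error("'hdl' must be strictly positive")
  list(tc_hdl = total_chol / hdl, tg_hdl = tg / hdl)
}

#' HOMA-IR
#'
#' Homeostatic model assessment of insulin resistance, Matthews form:
#' glucose (mg/dL) x insulin (uU/mL) / 405.
#'
#' @param glucose fasting glucose, mg/dL.
#' @param insulin fasting insulin, uU/mL.
#' @return dimensionless index.
#' @export
compute_homa_ir <- function(glucose, insulin) {
  check_positive(glucose, "glucose")
  check_positive(insulin, "insulin")
  glucose * insulin / 405
}

#' BMI standard-deviation score
#'
#' Z-score of BMI against an age- and sex-specific growth reference. With a
#' skew parameter L different from 1 the Cole LMS transform
#' ((bmi/M)^L - 1) / (L * S) is applied with S read as a coefficient of
#' variation; with L = 1 (no skew correction) the plain z-score
#' (bmi - M) / S is used with S read as an absolute SD in BMI units.
#'
#' @param bmi BMI in kg/m^2.
#' @param sex "F" or "M".
#' @param age age in years.
#' @param ref a reference object from [read_reference_tables()] or
#'   [make_reference_tables()] holding a `bmi` variable with L/M/S columns.
#' @return z-score (dimensionless).
#' @export
compute_bmi_sds <- function(bmi, sex, age, ref) {
  sex <- validate_sex(sex)
  L <- ref_lookup(ref, "bmi", sex, age, "L")
  M <- ref_lookup(ref, "bmi", sex, age, "M")
  S <- ref_lookup(ref, "bmi", sex, age, "S")
  lms_zscore(bmi, L, M, S)
}

#' Cole LMS z-score
#'
#' @param x measured value.
#' @param L,M,S Box-Cox power, median and spread. With L = 1 the score is
#'   the plain `(x - M) / S` (S an absolute SD); with L = 0 the log form
#'   `log(x/M) / S`; otherwise the Box-Cox form with S a coefficient of
#'   variation.
#' @return z-score.
#' @export
lms_zscore <- function(x, L, M, S) {
  if (any(M <= 0) || any(S <= 0)) pm_domain_error("LMS parameters M and S must be positive")
  ifelse(abs(L - 1) < 1e-12, (x - M) / S,
    ifelse(abs(L) < 1e-12, log(x / M) / S,
           ((x / M)^L - 1) / (L * S)))
}

validate_sex <- function(sex) {
  sex <- toupper(as.character(sex))
  sex[sex == "FEMALE"] <- "F"
  sex[sex == "MALE"] <- "M"
  if (any(!sex %in% c("F", "M")))
    pm_domain_error("sex must be 'F' or 'M'")
  sex
}

#' Compute the full index panel for a cohort
#'
#' Vectorized over the rows of a validated cohort table (see
#' [read_cohort()] for the schema). Indices whose inputs are absent
#' (DXA masses for FMI/FFMI/BMFI) come back NA, never zero; everything
#' else is computed from the measured fields.
#'
#' @param cohort a cohort data.frame in the package schema.
#' @param ref reference object covering the `bmi` variable (for BMI-SDS);
#'   pass NULL to leave `bmi_sds` NA.
#' @return data.frame: `id` plus bmi, bmi_sds, tmi, bmfi, fmi, ffmi, absi,
#'   vai, wthr, cmi, tc_hdl, tg_hdl, homa_ir.
#' @export
compute_indices <- function(cohort, ref = NULL) {
  with(cohort, {
    bmi  <- compute_bmi(weight_kg, height_cm)
    sds  <- if (is.null(ref)) rep(NA_real_, nrow(cohort)) else
      compute_bmi_sds(bmi, sex, age_years, ref)
    fmi  <- ifelse(is.na(fm_kg), NA_real_, fm_kg / (height_cm / 100)^2)
    ffmi <- ifelse(is.na(ffm_kg), NA_real_, ffm_kg / (height_cm / 100)^2)
    fmfr <- ifelse(is.na(fm_kg), NA_real_, fm_kg / weight_kg)
    bmfi <- ifelse(is.na(fmfr), NA_real_, bmi * fmfr * (waist_cm / 100))
    lips <- compute_lipid_ratios(tc_mgdl, hdl_mgdl, tg_mgdl)
    wthr <- compute_wthr(waist_cm, height_cm)
    data.frame(
      id = id,
      bmi = bmi,
      bmi_sds = sds,
      tmi = compute_tmi(weight_kg, height_cm),
      bmfi = bmfi,
      fmi = fmi,
      ffmi = ffmi,
      absi = compute_absi(waist_cm, bmi, height_cm),
      vai = compute_vai(sex, waist_cm, bmi,
                        tg_mgdl_to_mmol(tg_mgdl), chol_mgdl_to_mmol(hdl_mgdl)),
      wthr = wthr,
      cmi = compute_cmi(wthr, lips$tg_hdl),
      tc_hdl = lips$tc_hdl,
      tg_hdl = lips$tg_hdl,
      homa_ir = compute_homa_ir(glucose_mgdl, insulin_uUml),
      stringsAsFactors = FALSE
    )
  })
}

#' Names of the twelve screening indices
#'
#' The panel columns evaluated as MetS screeners (HOMA-IR is computed but is
#' itself part of the diagnostic rule, so it is not in this list).
#' @return character vector.
#' @export
index_names <- function() {
  c("bmi", "bmi_sds", "tmi", "bmfi", "fmi", "ffmi",
    "absi", "vai", "wthr", "cmi", "tc_hdl", "tg_hdl")
}
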