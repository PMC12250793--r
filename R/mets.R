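# Age-dispatched metabolic syndrome rule engine.
#
# Three criteria sets: IDEFICS for ages [7,10) (all components percentile
# thresholds, diagnosis at >= 3 of 4), IDF for [10,16) (abdominal-obesity
# gate on WC > p90 plus >= 2 of 4 absolute-threshold factors) and IDF for
# 16+ (absolute WC gate by sex, sex-specific HDL cut, treatment flags count
# as factors). Every comparison is strict, exactly as the criteria print
# them: a value sitting on a threshold is non-pathological.

CRITERIA_SETS <- c("IDEFICS", "IDF_10_16", "IDF_16PLUS")

#' Weight-status classification from BMI-SDS
#'
#' Obese above 2.0 BMI-SDS, strictly: a score of exactly 2.0 is classified
#' non-obese (the defining inequalities are "> 2.0" for obese and "< 2.0"
#' for non-obese, leaving the boundary to be assigned; the non-obese
#' reading is used).
#'
#' @param bmi_sds numeric z-scores.
#' @return factor with levels `non_obese`, `obese`.
#' @export
classify_weight_status <- function(bmi_sds) {
  if (any(!is.finite(bmi_sds))) pm_domain_error("bmi_sds must be finite")
  factor(ifelse(bmi_sds > 2.0, "obese", "non_obese"),
         levels = c("non_obese", "obese"))
}

#' Diagnose metabolic syndrome for a cohort
#'
#' Dispatches each subject on age to the applicable criteria set and
#' evaluates the component flags. For IDEFICS, `n_components` counts the
#' four components (WC, BP, lipids with TG/HDL pooled, glucose metabolism
#' with HOMA-IR/glucose pooled) and MetS requires at least three. For both
#' IDF bands, `n_components` counts the four non-WC factors (TG and HDL
#' separately, BP, glucose) and MetS requires the abdominal-obesity gate
#' plus at least two factors.
#'
#' A previously diagnosed IGT/T2DM (`dx_igt_t2dm`) satisfies the glucose
#' component in every band; lipid and BP treatment flags (`rx_lipid`,
#' `rx_bp`) count only in the 16+ band.
#'
#' @param cohort validated cohort data.frame (see [read_cohort()]).
#' @param panel index panel from [compute_indices()] (needed for HOMA-IR in
#'   the IDEFICS band); rows aligned with `cohort`.
#' @param ref `pedmets_reference` carrying wc/sbp/dbp/tg/hdl/homa/glucose
#'   percentile curves (only consulted for subjects under 16).
#' @param treated_lipid how a 16+ subject on lipid treatment with normal
#'   measured lipids is counted: `"single"` (default) adds one lipid
#'   factor; `"both"` marks both the TG and HDL factors.
#' @return data.frame: id, criteria_set, abdominal_obesity, bp_flag,
#'   lipid_tg_flag, lipid_hdl_flag, glucose_flag, n_components, mets.
#' @export
classify_mets <- function(cohort, panel, ref,
                          treated_lipid = c("single", "both")) {
  treated_lipid <- match.arg(treated_lipid)
  n <- nrow(cohort)
  age <- cohort$age_years
  if (any(age < 7)) pm_domain_error("MetS criteria are defined for ages >= 7")
  band <- ifelse(age < 10, "IDEFICS", ifelse(age < 16, "IDF_10_16", "IDF_16PLUS"))

  abdominal <- bp <- tgf <- hdlf <- glu <- logical(n)
  sexM <- validate_sex(cohort$sex) == "M"
  dx <- as.logical(cohort$dx_igt_t2dm)

  i <- band == "IDEFICS"
  if (any(i)) {
    s <- cohort$sex[i]; a <- age[i]
    abdominal[i] <- cohort$waist_cm[i] > ref_lookup(ref, "wc", s, a, "p90")
    bp[i] <- cohort$sbp_mmhg[i] > ref_lookup(ref, "sbp", s, a, "p90") |
             cohort$dbp_mmhg[i] > ref_lookup(ref, "dbp", s, a, "p90")
    tgf[i]  <- cohort$tg_mgdl[i] > ref_lookup(ref, "tg", s, a, "p90")
    hdlf[i] <- cohort$hdl_mgdl[i] < ref_lookup(ref, "hdl", s, a, "p10")
    glu[i] <- panel$homa_ir[i] > ref_lookup(ref, "homa", s, a, "p90") |
              cohort$glucose_mgdl[i] > ref_lookup(ref, "glucose", s, a, "p90") |
              dx[i]
  }

  i <- band == "IDF_10_16"
  if (any(i)) {
    abdominal[i] <- cohort$waist_cm[i] >
      ref_lookup(ref, "wc", cohort$sex[i], age[i], "p90")
    bp[i]   <- cohort$sbp_mmhg[i] > 130 | cohort$dbp_mmhg[i] > 85
    tgf[i]  <- cohort$tg_mgdl[i] > 150
    hdlf[i] <- cohort$hdl_mgdl[i] < 40
    glu[i]  <- cohort$glucose_mgdl[i] > 100 | dx[i]
  }

  i <- band == "IDF_16PLUS"
  if (any(i)) {
    rxl <- as.logical(cohort$rx_lipid[i])
    abdominal[i] <- cohort$waist_cm[i] > ifelse(sexM[i], 94, 80)
    bp[i]  <- cohort$sbp_mmhg[i] > 130 | cohort$dbp_mmhg[i] > 85 |
              as.logical(cohort$rx_bp[i])
    t0 <- cohort$tg_mgdl[i] > 150
    h0 <- cohort$hdl_mgdl[i] < ifelse(sexM[i], 40, 50)
    if (treated_lipid == "both") {
      tgf[i] <- t0 | rxl; hdlf[i] <- h0 | rxl
    } else {
      tgf[i] <- t0 | (rxl & !t0 & !h0); hdlf[i] <- h0
    }
    glu[i] <- cohort$glucose_mgdl[i] > 100 | dx[i]
  }

  idefics <- band == "IDEFICS"
  n_comp <- ifelse(idefics,
                   abdominal + bp + (tgf | hdlf) + glu,
                   tgf + hdlf + bp + glu)
  mets <- ifelse(idefics, n_comp >= 3, abdominal & n_comp >= 2)

  data.frame(id = cohort$id, criteria_set = band,
             abdominal_obesity = abdominal, bp_flag = bp,
             lipid_tg_flag = tgf, lipid_hdl_flag = hdlf, glucose_flag = glu,
             n_components = as.integer(n_comp), mets = as.logical(mets),
             stringsAsFactors = FALSE)
}

one_row <- function(subject, panel, ref, treated_lipid = "single") {
  res <- classify_mets(as.data.frame(subject, stringsAsFactors = FALSE),
                       as.data.frame(panel, stringsAsFactors = FALSE),
                       ref, treated_lipid)
  as.list(res[1, ])
}

#' Single-subject diagnosis under a specific criteria set
#'
#' Thin per-subject wrappers over [classify_mets()] that additionally
#' assert the subject's age lies in the band the criteria set covers.
#'
#' @param subject one-row cohort data.frame or named list.
#' @param panel one-row index panel (list or data.frame); only `homa_ir`
#'   is consulted, and only in the IDEFICS band.
#' @param ref `pedmets_reference`.
#' @param treated_lipid see [classify_mets()].
#' @return named list (one `MetS` result record).
#' @export
diagnose_idefics <- function(subject, panel, ref, treated_lipid = "single") {
  if (subject$age_years < 7 || subject$age_years >= 10)
    pm_domain_error("IDEFICS criteria cover ages [7, 10)")
  one_row(subject, panel, ref, treated_lipid)
}

#' @rdname diagnose_idefics
#' @export
diagnose_idf_10_16 <- function(subject, panel, ref, treated_lipid = "single") {
  if (subject$age_years < 10 || subject$age_years >= 16)
    pm_domain_error("IDF (10-16) criteria cover ages [10, 16)")
  one_row(subject, panel, ref, treated_lipid)
}

#' @rdname diagnose_idefics
#' @export
diagnose_idf_16plus <- function(subject, panel, ref, treated_lipid = "single") {
  if (subject$age_years < 16)
    pm_domain_error("IDF (16+) criteria cover ages >= 16")
  one_row(subject, panel, ref, treated_lipid)
}

#' @rdname diagnose_idefics
#' @export
diagnose_mets <- function(subject, panel, ref, treated_lipid = "single") {
  one_row(subject, panel, ref, treated_lipid)
}
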