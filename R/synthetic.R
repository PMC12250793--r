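# Synthetic PWS-like cohort generator.
#
# Generative model (single latent factor): each subject carries a Bernoulli
# cardiometabolic risk state whose probability rises with BMI-SDS; risk
# carriers have their MetS components (waist, TG, HDL, BP, glucose,
# insulin) shifted jointly by multiplicative effects. All anthropometrics
# and lipids are log-normal around age/sex-specific medians; sexual
# dimorphism is injected only for height, fat-mass percentage, fat-free
# mass and glycemia. Correlation between components arises solely through
# the shared latent state, which keeps population AUCs analyzable.

# Maps the target prevalence of rule-diagnosed MetS to the latent-risk
# rate. Calibrated once by simulation under the default parameters
# (realized prevalence ~ latent_rate / RISK_RATE_SCALE) and frozen.
RISK_RATE_SCALE <- 1.40

#' Default synthetic cohort parameters
#'
#' Defaults emulate a 124-subject pediatric Prader-Willi-like cohort, ages
#' 7-18, 63 males / 61 females, with location/spread structure matching a
#' severely obesity-prone clinical population (overall median BMI ~26
#' kg/m^2, ~56% obese by BMI-SDS > 2, MetS prevalence ~19%, higher among
#' obese subjects). `effects` are the multiplicative component shifts
#' applied to latent-risk carriers; `prevalence` is the target rate of
#' rule-diagnosed MetS.
#'
#' @param n cohort size.
#' @param seed RNG seed.
#' @param prevalence target MetS prevalence (0, 1).
#' @param p_male probability a subject is male.
#' @param age_range recruitment age range in years.
#' @param effects named list of multiplicative shifts for risk carriers:
#'   waist, tg, hdl, glucose, insulin, sbp, dbp.
#' @param risk_slope log-odds increase of the latent risk state per
#'   BMI-SDS unit.
#' @param dx_rate probability of a prior IGT/T2DM diagnosis for risk
#'   carriers / non-carriers (length 2).
#' @return list of class `pedmets_cohort_params`.
#' @export
cohort_params <- function(n = 124, seed = 1, prevalence = 0.194,
                          p_male = 63 / 124, age_range = c(7, 18),
                          effects = list(waist = 1.10, tg = 2.0, hdl = 0.72,
                                         glucose = 1.09, insulin = 1.8,
                                         sbp = 1.05, dbp = 1.10),
                          risk_slope = 0.65,
                          dx_rate = c(0.30, 0.02)) {
  if (n < 2) pm_config_error("n must be >= 2")
  if (prevalence <= 0 || prevalence >= 1)
    pm_config_error("prevalence must lie in (0, 1)")
  needed <- c("waist", "tg", "hdl", "glucose", "insulin", "sbp", "dbp")
  if (!all(needed %in% names(effects)))
    pm_config_error("effects must name %s", paste(needed, collapse = ", "))
  if (any(unlist(effects) <= 0)) pm_config_error("effects must be positive")
  structure(list(n = n, seed = seed, prevalence = prevalence,
                 p_male = p_male, age_range = age_range, effects = effects,
                 risk_slope = risk_slope, dx_rate = dx_rate),
            class = "pedmets_cohort_params")
}

# median curves for the deterministic synthetic references and the
# generator; age in years
ref_curves <- list(
  wc_p90      = function(a, m) ifelse(m, 63 + 2.4 * (a - 7), 62 + 2.2 * (a - 7)),
  wc_p50      = function(a, m) ifelse(m, 56 + 2.1 * (a - 7), 55 + 1.9 * (a - 7)),
  wc_p10      = function(a, m) ifelse(m, 49 + 1.8 * (a - 7), 48 + 1.6 * (a - 7)),
  sbp_p90     = function(a, m) 104 + 1.3 * a + ifelse(m, 1, 0),
  sbp_p50     = function(a, m) 93 + 1.2 * a + ifelse(m, 1, 0),
  sbp_p10     = function(a, m) 83 + 1.1 * a + ifelse(m, 1, 0),
  dbp_p90     = function(a, m) 66 + 0.9 * a,
  dbp_p50     = function(a, m) 55 + 0.85 * a,
  dbp_p10     = function(a, m) 45 + 0.8 * a,
  tg_p90      = function(a, m) 105 + 1.0 * (a - 7),
  tg_p50      = function(a, m) 68 + 0.7 * (a - 7),
  tg_p10      = function(a, m) 42 + 0.4 * (a - 7),
  hdl_p90     = function(a, m) 72 - 0.3 * (a - 7),
  hdl_p50     = function(a, m) 53 - 0.25 * (a - 7),
  hdl_p10     = function(a, m) 38 - 0.2 * (a - 7) - ifelse(m, 1, 0),
  glucose_p90 = function(a, m) 94 + 0.3 * (a - 7) + ifelse(m, 1, 0),
  glucose_p50 = function(a, m) 82 + 0.25 * (a - 7) + ifelse(m, 1, 0),
  glucose_p10 = function(a, m) 71 + 0.2 * (a - 7) + ifelse(m, 1, 0),
  homa_p90    = function(a, m) 2.2 + 0.18 * (a - 7),
  homa_p50    = function(a, m) 1.2 + 0.11 * (a - 7),
  homa_p10    = function(a, m) 0.5 + 0.05 * (a - 7),
  bmi_M       = function(a, m) 13.6 + 0.38 * a
)

#' Synthetic percentile and LMS reference tables
#'
#' Deterministic smooth percentile curves (p10/p50/p90) for waist, blood
#' pressure, lipids, glucose and HOMA-IR, plus an LMS (L = -1, S = 0.13)
#' BMI reference, tabulated at half-year knots over ages 7-18 by sex.
#' These are synthetic stand-ins for external growth-reference
#' publications: ordered, monotone where physiology demands it, and
#' identical for any seed (the argument is accepted for interface
#' symmetry with the stochastic generator).
#'
#' @param seed unused; kept so `make_reference_tables(seed)` mirrors the
#'   other generators' signatures.
#' @return `pedmets_reference` object.
#' @export
make_reference_tables <- function(seed = 1) {
  ages <- seq(7, 18, by = 0.5)
  grid <- expand.grid(sex = c("F", "M"), age_years = ages,
                      stringsAsFactors = FALSE)
  male <- grid$sex == "M"
  rows <- list()
  for (v in c("wc", "sbp", "dbp", "tg", "hdl", "glucose", "homa")) {
    rows[[v]] <- data.frame(
      sex = grid$sex, age_years = grid$age_years, variable = v,
      L = NA_real_, M = NA_real_, S = NA_real_,
      p10 = ref_curves[[paste0(v, "_p10")]](grid$age_years, male),
      p50 = ref_curves[[paste0(v, "_p50")]](grid$age_years, male),
      p90 = ref_curves[[paste0(v, "_p90")]](grid$age_years, male),
      stringsAsFactors = FALSE)
  }
  rows$bmi <- data.frame(
    sex = grid$sex, age_years = grid$age_years, variable = "bmi",
    L = -1, M = ref_curves$bmi_M(grid$age_years, male), S = 0.13,
    p10 = NA_real_, p50 = NA_real_, p90 = NA_real_,
    stringsAsFactors = FALSE)
  as_reference(do.call(rbind, rows))
}

rlnorm_med <- function(n, median, sdlog) median * exp(stats::rnorm(n, 0, sdlog))

#' Simulate a synthetic PWS-like cohort
#'
#' Draws a cohort under the single-latent-factor generative model (see the
#' methods vignette). Height follows a sex-specific growth line with a
#' pubertal plateau; BMI is drawn log-normally around the reference median
#' so that just over half the cohort is obese; the latent risk state is
#' Bernoulli with log-odds increasing in BMI-SDS, and carriers receive the
#' multiplicative component shifts in `params$effects`. Fat and fat-free
#' mass partition body weight exactly.
#'
#' The latent risk state (generator ground truth, not observable
#' clinically) is attached as `attr(cohort, "latent_risk")`.
#'
#' @param params `pedmets_cohort_params` from [cohort_params()].
#' @param ref reference object for the BMI-SDS tilt; defaults to
#'   [make_reference_tables()].
#' @return cohort data.frame in the package CSV schema.
#' @export
simulate_cohort <- function(params = cohort_params(), ref = make_reference_tables()) {
  stopifnot(inherits(params, "pedmets_cohort_params"))
  set.seed(params$seed)
  n <- params$n
  eff <- params$effects

  age <- stats::runif(n, params$age_range[1], params$age_range[2])
  male <- stats::runif(n) < params$p_male
  sex <- ifelse(male, "M", "F")

  # height: linear growth with a plateau; males taller, later plateau
  h50 <- ifelse(male, pmin(118 + 5.2 * (age - 7), 168),
                      pmin(115 + 4.6 * (age - 7), 155))
  height <- h50 * exp(stats::rnorm(n, 0, 0.035))

  # BMI around the reference median; exp(0.349) centres the cohort so that
  # P(BMI-SDS > 2) is a little over one half
  bmi_M <- ref_curves$bmi_M(age, male)
  bmi <- bmi_M * exp(stats::rnorm(n, 0.349, 0.30))
  weight <- bmi * (height / 100)^2
  bmi_sds <- compute_bmi_sds(bmi, sex, age, ref)

  # latent cardiometabolic risk: logistic in BMI-SDS around the obesity cut
  latent_rate <- min(0.95, params$prevalence * RISK_RATE_SCALE)
  p_risk <- stats::plogis(stats::qlogis(latent_rate) +
                          params$risk_slope * (bmi_sds - 2.1))
  risk <- stats::runif(n) < p_risk
  shift <- function(component) ifelse(risk, eff[[component]], 1)

  waist <- pmin(0.58 * exp(stats::rnorm(n, 0, 0.08)) * height * shift("waist"),
                0.95 * height)
  tg  <- rlnorm_med(n, 72, 0.35) * shift("tg")
  hdl <- rlnorm_med(n, 54, 0.20) * shift("hdl")
  tc  <- pmax(rlnorm_med(n, 166, 0.15), hdl * 1.15)
  glucose <- rlnorm_med(n, ifelse(male, 81.5, 78), 0.07) * shift("glucose")
  insulin <- rlnorm_med(n, 9.8, 0.50) * shift("insulin")
  hba1c <- rlnorm_med(n, 5.35, 0.05) * ifelse(risk, 1.03, 1)
  sbp <- (93 + 1.2 * age) * exp(stats::rnorm(n, 0, 0.06)) * shift("sbp")
  dbp <- (55 + 0.85 * age) * exp(stats::rnorm(n, 0, 0.10)) * shift("dbp")

  # body composition: FM% higher in girls, rising with adiposity
  fm_pct <- 46.5 + ifelse(male, -1.4, 2.0) + 1.5 * (bmi_sds - 2.1) +
    stats::rnorm(n, 0, 4)
  fm_pct <- pmin(pmax(fm_pct, 13), 64)
  fm <- fm_pct / 100 * weight
  ffm <- weight - fm

  tanner <- pmin(5L, pmax(1L, as.integer(floor((age - 6) / 2.4)) +
                            sample(0:1, n, replace = TRUE)))
  dx <- stats::runif(n) < ifelse(risk, params$dx_rate[1], params$dx_rate[2])
  rx_bp <- stats::runif(n) < ifelse(risk, 0.08, 0.01)
  rx_lipid <- stats::runif(n) < ifelse(risk, 0.02, 0.004)

  cohort <- data.frame(
    id = sprintf("S%03d", seq_len(n)),
    age_years = round(age, 2), sex = sex, tanner = tanner,
    weight_kg = round(weight, 1), height_cm = round(height, 1),
    waist_cm = round(waist, 1),
    fm_kg = round(fm, 1), ffm_kg = round(ffm, 1),
    glucose_mgdl = round(glucose, 1), insulin_uUml = round(insulin, 1),
    hba1c_pct = round(hba1c, 1),
    tc_mgdl = round(tc, 1), hdl_mgdl = round(hdl, 1), tg_mgdl = round(tg, 1),
    sbp_mmhg = round(sbp, 1), dbp_mmhg = round(dbp, 1),
    rx_lipid = as.integer(rx_lipid), rx_bp = as.integer(rx_bp),
    dx_igt_t2dm = as.integer(dx),
    stringsAsFactors = FALSE)
  attr(cohort, "latent_risk") <- risk
  attr(cohort, "params") <- params
  cohort
}

#' Monte-Carlo population AUC oracle
#'
#' Estimates each index's population AUC for discriminating the latent
#' risk state (the generative ground-truth condition) by simulating one
#' large cohort. With all effect sizes at 1 the indices carry no
#' information about the latent state and every oracle AUC is 0.5 up to
#' Monte-Carlo error.
#'
#' @param params `pedmets_cohort_params`; `params$n` is overridden.
#' @param n_mc Monte-Carlo cohort size.
#' @return named numeric vector of AUCs, one per screening index.
#' @export
true_auc_oracle <- function(params = cohort_params(), n_mc = 1e5) {
  big <- params
  big$n <- n_mc
  cohort <- simulate_cohort(big)
  risk <- attr(cohort, "latent_risk")
  panel <- compute_indices(cohort, make_reference_tables())
  vapply(index_names(),
         function(v) auc_rank(panel[[v]], risk)$auc,
         0)
}
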