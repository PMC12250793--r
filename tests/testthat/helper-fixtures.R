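# Shared fixtures and independent oracles, built in code.

# A complete, valid one-row subject; override fields as needed.
make_subject <- function(...) {
  base <- list(
    id = "S001", age_years = 12, sex = "F", tanner = 3,
    weight_kg = 60, height_cm = 150, waist_cm = 85,
    fm_kg = 28, ffm_kg = 32,
    glucose_mgdl = 80, insulin_uUml = 10, hba1c_pct = 5.3,
    tc_mgdl = 165, hdl_mgdl = 52, tg_mgdl = 80,
    sbp_mmhg = 110, dbp_mmhg = 70,
    rx_lipid = 0L, rx_bp = 0L, dx_igt_t2dm = 0L)
  mods <- list(...)
  base[names(mods)] <- mods
  as.data.frame(base, stringsAsFactors = FALSE)
}

make_cohort <- function(n, ...) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    s <- make_subject(...)
    s$id <- sprintf("S%03d", i)
    s
  }))
}

# Flat reference: every percentile constant in age, so threshold crossings
# in rule tests are unambiguous.
flat_reference <- function() {
  grid <- expand.grid(sex = c("F", "M"), age_years = c(7, 25),
                      stringsAsFactors = FALSE)
  vals <- list(wc = c(90, 70, 50), sbp = c(120, 105, 95),
               dbp = c(80, 65, 55), tg = c(100, 70, 45),
               hdl = c(70, 52, 40), glucose = c(95, 82, 72),
               homa = c(3, 1.5, 0.6))
  tabs <- lapply(names(vals), function(v) {
    data.frame(sex = grid$sex, age_years = grid$age_years, variable = v,
               L = NA_real_, M = NA_real_, S = NA_real_,
               p10 = vals[[v]][3], p50 = vals[[v]][2], p90 = vals[[v]][1],
               stringsAsFactors = FALSE)
  })
  bmi <- data.frame(sex = grid$sex, age_years = grid$age_years,
                    variable = "bmi", L = 1, M = 18, S = 2,
                    p10 = NA_real_, p50 = NA_real_, p90 = NA_real_,
                    stringsAsFactors = FALSE)
  as_reference(do.call(rbind, c(tabs, list(bmi))))
}

# Brute-force AUC: count concordant positive-negative pairs, ties half.
auc_pair_oracle <- function(score, label) {
  pos <- score[as.logical(label)]; neg <- score[!as.logical(label)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Exhaustive Youden scan over all candidate thresholds (observed scores
# plus +Inf), ties toward the lower threshold.
youden_scan_oracle <- function(score, label) {
  label <- as.logical(label)
  cand <- sort(unique(c(score, Inf)))
  best <- list(j = -Inf, thr = Inf)
  for (t in cand) {
    sens <- sum(score >= t & label) / sum(label)
    spec <- sum(score < t & !label) / sum(!label)
    j <- sens + spec - 1
    if (j > best$j + 1e-12) best <- list(j = j, thr = t)
  }
  best
}

# Subjects with each component strictly past / safely inside the flat
# reference thresholds, for truth-table sweeps.
idefics_subject <- function(wc, bp, tg, hdl, glu, homa = FALSE, dx = 0L) {
  make_subject(age_years = 8,
               waist_cm = if (wc) 95 else 70,
               sbp_mmhg = if (bp) 125 else 110, dbp_mmhg = 70,
               tg_mgdl = if (tg) 110 else 70,
               hdl_mgdl = if (hdl) 38 else 52,
               glucose_mgdl = if (glu) 98 else 80,
               insulin_uUml = if (homa) 20 else 8,  # homa 4.8 vs 1.6 at glu 80
               dx_igt_t2dm = dx)
}

idf_subject <- function(age, gate, tg, hdl, bp, glu, ...) {
  make_subject(age_years = age, sex = "F",
               waist_cm = if (gate) {if (age >= 16) 85 else 95} else {if (age >= 16) 75 else 70},
               tg_mgdl = if (tg) 160 else 80,
               hdl_mgdl = if (hdl) {if (age >= 16) 45 else 38} else {if (age >= 16) 55 else 52},
               sbp_mmhg = if (bp) 135 else 110, dbp_mmhg = 70,
               glucose_mgdl = if (glu) 105 else 80, ...)
}

# Truth-table MetS oracles, straight from the written rules.
idefics_oracle <- function(wc, bp, lipid, glu) sum(wc, bp, lipid, glu) >= 3
idf_oracle <- function(gate, tg, hdl, bp, glu) gate && sum(tg, hdl, bp, glu) >= 2
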