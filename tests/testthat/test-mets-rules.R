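# Rule-engine tests against the flat reference (wc p90 = 90, sbp p90 = 120,
# dbp p90 = 80, tg p90 = 100, hdl p10 = 40, glucose p90 = 95, homa p90 = 3).

ref <- flat_reference()

classify1 <- function(subject, ...) {
  pan <- compute_indices(subject, ref)
  classify_mets(subject, pan, ref, ...)[1, ]
}

test_that("weight status boundary is strict at 2.0 SDS", {
  expect_equal(as.character(classify_weight_status(c(3.5, 1.9, 2.0, 2.0001))),
               c("obese", "non_obese", "non_obese", "obese"))
  expect_error(classify_weight_status(NaN), class = "pedmets_domain_error")
})

test_that("age dispatch partitions at 10 and 16, left-closed", {
  for (case in list(c(7, "IDEFICS"), c(9.9, "IDEFICS"), c(10, "IDF_10_16"),
                    c(15.99, "IDF_10_16"), c(16, "IDF_16PLUS"),
                    c(18.9, "IDF_16PLUS"))) {
    s <- make_subject(age_years = as.numeric(case[1]))
    expect_equal(classify1(s)$criteria_set, case[2])
  }
  s <- make_subject(age_years = 6.9)
  expect_error(classify_mets(s, compute_indices(s, ref), ref),
               class = "pedmets_domain_error")
})

test_that("IDEFICS matches the >= 3-of-4 truth table over all combinations", {
  for (b in 0:15) {
    f <- as.logical(bitwAnd(b, c(1, 2, 4, 8)))
    res <- classify1(idefics_subject(f[1], f[2], f[3], f[3], f[4]))
    expect_equal(res$mets, idefics_oracle(f[1], f[2], f[3], f[4]),
                 info = sprintf("combo %d", b))
    expect_equal(res$n_components, sum(f))
  }
  # TG and HDL pool into one lipid component: both flagged counts once
  res <- classify1(idefics_subject(FALSE, FALSE, tg = TRUE, hdl = TRUE, glu = FALSE))
  expect_equal(res$n_components, 1)
  expect_false(res$mets)
  res <- classify1(idefics_subject(TRUE, TRUE, FALSE, FALSE, FALSE, homa = TRUE))
  expect_true(res$glucose_flag)
  expect_true(res$mets)
  # a prior IGT/T2DM diagnosis satisfies the glucose component at all ages
  res <- classify1(idefics_subject(TRUE, TRUE, FALSE, FALSE, FALSE, dx = 1L))
  expect_true(res$glucose_flag && res$mets)
})

test_that("both IDF bands match the gate-plus-2 truth table", {
  for (age in c(12, 17)) {
    for (b in 0:31) {
      f <- as.logical(bitwAnd(b, c(1, 2, 4, 8, 16)))
      res <- classify1(idf_subject(age, f[1], f[2], f[3], f[4], f[5]))
      expect_equal(res$mets, idf_oracle(f[1], f[2], f[3], f[4], f[5]),
                   info = sprintf("age %g combo %d", age, b))
      expect_equal(res$n_components, sum(f[2:5]))
      # gate property: MetS implies abdominal obesity
      if (res$mets) expect_true(res$abdominal_obesity)
    }
  }
})

test_that("IDF boundary and threshold cases from the written criteria", {
  # gate dominates: all four factors without abdominal obesity is negative
  expect_false(classify1(idf_subject(12, FALSE, TRUE, TRUE, TRUE, TRUE))$mets)
  # WC > p90 with TG 160, HDL 38 is exactly two factors -> positive
  res <- classify1(idf_subject(12, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_true(res$mets); expect_equal(res$n_components, 2)
  # glucose 86 is not a raised FPG (threshold is > 100 mg/dL)
  s <- idf_subject(12, TRUE, FALSE, FALSE, FALSE, FALSE)
  s$glucose_mgdl <- 86
  expect_false(classify1(s)$mets)
  # WC exactly at the p90 (or the absolute cut) does not gate: strict ">"
  s <- make_subject(age_years = 12, waist_cm = 90, tg_mgdl = 160, hdl_mgdl = 38)
  expect_false(classify1(s)$mets)
  s <- make_subject(age_years = 17, sex = "M", waist_cm = 94,
                    tg_mgdl = 160, hdl_mgdl = 35)
  res <- classify1(s)
  expect_false(res$abdominal_obesity); expect_false(res$mets)
  # sex-specific 16+ HDL cut: 45 mg/dL flags a female, not a male
  s <- make_subject(age_years = 17, waist_cm = 85, hdl_mgdl = 45)
  expect_true(classify1(s)$lipid_hdl_flag)
  s$sex <- "M"; s$waist_cm <- 96
  expect_false(classify1(s)$lipid_hdl_flag)
})

test_that("treatment flags count as factors only in the 16+ band", {
  # female, WC 81 (> 80 gate), on BP treatment, glucose 101 -> two factors
  s <- make_subject(age_years = 17, waist_cm = 81, rx_bp = 1L,
                    glucose_mgdl = 101, hdl_mgdl = 55, tg_mgdl = 80,
                    sbp_mmhg = 110, dbp_mmhg = 70)
  res <- classify1(s)
  expect_true(res$mets); expect_equal(res$n_components, 2)
  # lipid treatment with normal measured lipids: one lipid factor (default)
  s <- make_subject(age_years = 17, waist_cm = 85, rx_lipid = 1L,
                    tg_mgdl = 80, hdl_mgdl = 55, sbp_mmhg = 135)
  res <- classify1(s)
  expect_true(res$mets); expect_equal(res$n_components, 2)
  # the exposed switch counts treatment toward both lipid factors
  res2 <- classify1(s, treated_lipid = "both")
  expect_equal(res2$n_components, 3)
  # under 16, the same treatment flags do not count
  s <- make_subject(age_years = 12, waist_cm = 95, rx_lipid = 1L, rx_bp = 1L,
                    tg_mgdl = 80, hdl_mgdl = 52, sbp_mmhg = 110)
  res <- classify1(s)
  expect_false(res$mets); expect_equal(res$n_components, 0)
})

test_that("worsening any single component never flips positive to negative", {
  set.seed(21)
  worsen <- list(
    function(s) { s$tg_mgdl <- s$tg_mgdl * 1.5; s },
    function(s) { s$hdl_mgdl <- s$hdl_mgdl * 0.7; s },
    function(s) { s$sbp_mmhg <- s$sbp_mmhg + 20; s },
    function(s) { s$glucose_mgdl <- s$glucose_mgdl + 15; s },
    function(s) { s$waist_cm <- s$waist_cm * 1.2; s })
  for (i in 1:60) {
    s <- make_subject(
      age_years = runif(1, 7, 19),
      waist_cm = runif(1, 60, 110), tg_mgdl = runif(1, 50, 200),
      hdl_mgdl = runif(1, 30, 70), sbp_mmhg = runif(1, 100, 140),
      dbp_mmhg = runif(1, 60, 90), glucose_mgdl = runif(1, 70, 110),
      insulin_uUml = runif(1, 4, 30))
    before <- classify1(s)$mets
    if (before) {
      for (w in worsen) expect_true(classify1(w(s))$mets)
    }
  }
})
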