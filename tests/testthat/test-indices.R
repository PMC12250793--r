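test_that("simple mass/height indices follow their formulas", {
  expect_equal(compute_bmi(50, 200), 12.5)
  expect_equal(compute_bmi(81, 150), 36.0)
  expect_equal(compute_tmi(54, 150), 16.0)
  expect_equal(compute_tmi(100, 200), 12.5)
  expect_equal(compute_tmi(60.1, 149.3), 60.1 / 1.493^3, tolerance = 1e-12)
  expect_equal(compute_fmi(27, 150), 12.0)
  expect_equal(compute_fmi(31.4, 149.3), 31.4 / 1.493^2, tolerance = 1e-12)
  expect_equal(compute_wthr(75, 150), 0.5)
  expect_equal(compute_wthr(86.5, 149.3), 86.5 / 149.3, tolerance = 1e-12)
  expect_equal(compute_homa_ir(90, 9), 2.0)
  expect_equal(compute_homa_ir(405, 1), 1.0)
  expect_equal(compute_homa_ir(80, 11.4), 80 * 11.4 / 405, tolerance = 1e-12)
})

test_that("nonpositive inputs raise domain errors naming the field", {
  expect_error(compute_bmi(60, 0), class = "pedmets_domain_error")
  expect_error(compute_bmi(60, 0), "height")
  expect_error(compute_wthr(0, 150), class = "pedmets_domain_error")
  expect_error(compute_homa_ir(-1, 5), class = "pedmets_domain_error")
  expect_error(compute_lipid_ratios(150, 0, 80), class = "pedmets_domain_error")
})

test_that("composite indices use fraction/meter unit conventions", {
  expect_equal(compute_bmfi(25, 0.40, 100), 10.0)
  expect_equal(compute_bmfi(26.4, 0.465, 86.5), 26.4 * 0.465 * 0.865,
               tolerance = 1e-12)
  # a percent passed where a fraction is expected is caught
  expect_error(compute_bmfi(26.4, 46.5, 86.5), class = "pedmets_domain_error")
  expect_equal(compute_absi(100, 1, 100), 1.0)
  expect_equal(compute_absi(86.5, 26.4, 149.3),
               0.865 / (26.4^(2 / 3) * sqrt(1.493)), tolerance = 1e-12)
})

test_that("VAI normalizing points and parenthesization behave", {
  # at reference lipids the lipid term is 1, leaving the waist term
  expect_equal(compute_vai("M", 93, 28.1, 1.03, 1.31),
               93 / (39.68 + 1.88 * 28.1), tolerance = 1e-12)
  expect_equal(compute_vai("F", 83, 26.2, 0.81, 1.52),
               83 / (36.58 + 1.89 * 26.2), tolerance = 1e-12)
  bmi <- 24; wc <- 39.68 + 1.88 * bmi
  expect_equal(compute_vai("M", wc, bmi, 1.03, 1.31), 1.0, tolerance = 1e-12)
  # the literal mis-bracketed reading is a different, much larger number
  expect_gt(compute_vai("M", 93, 28.1, 1.03, 1.31, literal = TRUE), 10)
  expect_error(compute_vai("X", 90, 25, 1, 1), class = "pedmets_domain_error")
})

test_that("lipid ratios and CMI", {
  r <- compute_lipid_ratios(150, 50, 150)
  expect_equal(r$tc_hdl, 3.0)
  expect_equal(r$tg_hdl, 3.0)
  expect_equal(compute_lipid_ratios(160, 39, 133)$tg_hdl, 133 / 39)
  expect_equal(compute_lipid_ratios(160, 54, 72)$tg_hdl, 72 / 54)
  expect_equal(compute_cmi(0.5, 2.0), 1.0)
  expect_equal(compute_cmi(0, 5), 0)
  expect_error(compute_cmi(-0.1, 1), class = "pedmets_domain_error")
})

test_that("BMI-SDS uses plain z with L = 1 and LMS otherwise", {
  expect_equal(lms_zscore(18, 1, 18, 2), 0)
  expect_equal(lms_zscore(22, 1, 18, 2), 2)
  expect_equal(lms_zscore(16, 0.5, 16, 0.1), 0)
  # LMS by hand: ((x/M)^L - 1)/(L S)
  expect_equal(lms_zscore(20, 0.5, 16, 0.1),
               ((20 / 16)^0.5 - 1) / (0.5 * 0.1), tolerance = 1e-12)
  ref <- flat_reference()
  expect_equal(compute_bmi_sds(18, "F", 12, ref), 0)
  expect_equal(compute_bmi_sds(22, "M", 9, ref), 2)
  expect_error(compute_bmi_sds(20, "F", 30, ref),
               class = "pedmets_coverage_error")
})

test_that("index panel respects missing-data and algebraic invariants", {
  ref <- flat_reference()
  co <- make_cohort(3)
  co$fm_kg[2] <- NA; co$ffm_kg[2] <- NA
  pan <- compute_indices(co, ref)
  expect_true(all(!is.na(pan[1, -1])))
  expect_true(is.na(pan$fmi[2]) && is.na(pan$ffmi[2]) && is.na(pan$bmfi[2]))
  expect_false(any(is.na(pan[2, c("bmi", "tmi", "absi", "vai", "wthr",
                                  "cmi", "tc_hdl", "tg_hdl", "homa_ir")])))
  # cmi = wthr * tg_hdl exactly
  expect_equal(pan$cmi, pan$wthr * pan$tg_hdl, tolerance = 1e-12)
  # fmi + ffmi equals BMI computed from fm + ffm as weight
  ok <- !is.na(pan$fmi)
  expect_equal(pan$fmi[ok] + pan$ffmi[ok],
               compute_bmi(co$fm_kg[ok] + co$ffm_kg[ok], co$height_cm[ok]),
               tolerance = 1e-9)
})

test_that("monotonicity and unit round-trip properties hold under sampling", {
  set.seed(11)
  for (i in 1:50) {
    wc <- runif(1, 50, 120); bmi <- runif(1, 14, 45); h <- runif(1, 110, 180)
    tg <- runif(1, 0.4, 3); hdl <- runif(1, 0.8, 2.5); d <- runif(1, 0.01, 0.5)
    sex <- sample(c("F", "M"), 1)
    expect_gt(compute_vai(sex, wc, bmi, tg + d, hdl),
              compute_vai(sex, wc, bmi, tg, hdl))
    expect_lt(compute_vai(sex, wc, bmi, tg, hdl + d),
              compute_vai(sex, wc, bmi, tg, hdl))
    expect_gt(compute_absi(wc + d, bmi, h), compute_absi(wc, bmi, h))
    # mg/dL -> mmol/L -> mg/dL round-trip leaves VAI unchanged
    tg_mg <- tg * 88.57; hdl_mg <- hdl * 38.67
    v1 <- compute_vai(sex, wc, bmi, tg, hdl)
    v2 <- compute_vai(sex, wc, bmi,
                      tg_mgdl_to_mmol(tg_mmol_to_mgdl(tg)),
                      chol_mgdl_to_mmol(chol_mmol_to_mgdl(hdl)))
    expect_equal(v1, v2, tolerance = 1e-9)
  }
})
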