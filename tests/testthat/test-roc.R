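test_that("ROC operating points sweep from (0,0) to (1,1)", {
  pts <- roc_points(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(pts$sens[1], 0); expect_equal(pts$spec[1], 1)
  expect_equal(pts$sens[nrow(pts)], 1); expect_equal(pts$spec[nrow(pts)], 0)
  # perfect separation passes through (sens 1, spec 1)
  expect_true(any(pts$sens == 1 & pts$spec == 1))
  # monotone in both coordinates as the threshold decreases
  expect_true(all(diff(pts$sens) >= 0))
  expect_true(all(diff(pts$fpr) >= 0))
  # all scores equal: only the trivial endpoints, AUC 1/2
  pts <- roc_points(rep(2, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(nrow(pts), 2)
  expect_equal(auc_rank(rep(2, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(roc_points(1:4, c(1, 1, 1, 1)),
               class = "pedmets_degenerate_error")
})

test_that("rank AUC equals brute-force pair counting on random instances", {
  expect_equal(auc_rank(c(0.1, 0.2, 0.3, 0.4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(auc_rank(1:4, c(0, 1, 0, 1))$auc, 0.75)
  set.seed(31)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    score <- sample(round(rnorm(n), sample(0:1, 1)))  # coarse rounding forces ties
    label <- rbinom(n, 1, 0.4)
    if (sum(label) %in% c(0, n)) label[c(1, n)] <- c(0, 1)
    expect_equal(auc_rank(score, label)$auc, auc_pair_oracle(score, label),
                 tolerance = 1e-12)
    # label inversion maps AUC to 1 - AUC
    expect_equal(auc_rank(score, 1 - label)$auc,
                 1 - auc_rank(score, label)$auc, tolerance = 1e-12)
  }
})

test_that("DeLong AUC interval agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(32)
  score <- c(rnorm(30, 1), rnorm(40)); label <- rep(c(1, 0), c(30, 40))
  ours <- auc_rank(score, label)
  theirs <- pROC::ci.auc(pROC::roc(label, score, quiet = TRUE), method = "delong")
  expect_equal(ours$auc, as.numeric(theirs[2]), tolerance = 1e-9)
  expect_equal(ours$ci, as.numeric(theirs[c(1, 3)]), tolerance = 1e-6)
})

test_that("Youden cutoff equals the exhaustive scan, low threshold on ties", {
  yc <- youden_cutoff(1:4, c(0, 1, 0, 1))
  expect_equal(yc$youden, 0.5); expect_equal(yc$threshold, 2)
  expect_equal(youden_cutoff(c(1, 2, 8, 9), c(0, 0, 1, 1))$youden, 1.0)
  expect_equal(youden_cutoff(rep(3, 4), c(0, 1, 0, 1))$youden, 0.0)
  set.seed(33)
  for (i in 1:40) {
    n <- sample(5:50, 1)
    score <- sample(round(runif(n, 0, 5), 1))
    label <- rbinom(n, 1, 0.5)
    if (sum(label) %in% c(0, n)) label[c(1, n)] <- c(0, 1)
    yc <- youden_cutoff(score, label)
    oracle <- youden_scan_oracle(score, label)
    expect_equal(yc$youden, oracle$j, tolerance = 1e-12)
    expect_equal(yc$threshold, oracle$thr)
    # J = sens + spec - 1 exactly at the reported cutoff
    expect_equal(yc$youden, yc$sens + yc$spec - 1, tolerance = 1e-12)
  }
})

test_that("paired DeLong comparison: symmetry, invariance, oracles", {
  set.seed(34)
  label <- rep(c(1, 0), c(20, 30))
  a <- c(rnorm(20, 1.2), rnorm(30)); b <- a + rnorm(50, 0, 0.8)
  # identical scores: zero difference, p = 1
  same <- delong_compare(a, a, label)
  expect_equal(same$delta, 0); expect_equal(same$p, 1)
  # negation symmetry: AUC of -a is 1 - AUC of a
  flip <- delong_compare(a, -a, label)
  expect_equal(abs(flip$delta), abs(2 * flip$auc_a - 1), tolerance = 1e-12)
  # invariant under a common strictly monotone transform
  r1 <- delong_compare(a, b, label)
  r2 <- delong_compare(exp(a / 2), exp(b / 2), label)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  theirs <- pROC::roc.test(pROC::roc(label, a, quiet = TRUE),
                           pROC::roc(label, b, quiet = TRUE),
                           method = "delong", paired = TRUE)
  expect_equal(r1$p, theirs$p.value, tolerance = 1e-9)
})

test_that("DeLong p agrees with a permutation oracle on a small fixture", {
  set.seed(35)
  label <- rep(c(1, 0), c(12, 18))
  a <- c(rnorm(12, 1), rnorm(18)); b <- c(rnorm(12, 0.4), rnorm(18))
  obs <- delong_compare(a, b, label)
  # permutation: swap the two scores within random subjects (null: the two
  # markers are exchangeable), recompute the AUC difference
  nperm <- 2000
  perm <- replicate(nperm, {
    sw <- runif(30) < 0.5
    aa <- ifelse(sw, b, a); bb <- ifelse(sw, a, b)
    auc_rank(aa, label)$auc - auc_rank(bb, label)$auc
  })
  p_perm <- mean(abs(perm) >= abs(obs$delta))
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / nperm)
  expect_lt(abs(obs$p - p_perm), mc_err + 0.05)
})

test_that("cutoff trend collapses to the global cutoff for a wide window", {
  set.seed(36)
  n <- 120
  age <- runif(n, 7, 18); sex <- sample(c("F", "M"), n, replace = TRUE)
  label <- rbinom(n, 1, 0.3)
  score <- rnorm(n, ifelse(label == 1, 2, 0))
  tr <- cutoff_trend(score, label, age, sex, sexes = "F",
                     window = 40, min_n = 5)
  glob <- youden_cutoff(score[sex == "F"], label[sex == "F"])$threshold
  expect_true(all(tr$cutoff == glob))
  # min_n above the cohort size: every grid point undefined, still emitted
  tr <- cutoff_trend(score, label, age, sex, min_n = 1000)
  expect_true(all(is.na(tr$cutoff)))
  expect_equal(nrow(tr), 2 * length(7:18))
  # age-invariant generative cutoff: trend flat within Monte-Carlo noise
  n <- 4000
  age <- runif(n, 7, 18); sex <- rep("F", n)
  risk <- rbinom(n, 1, 0.3)
  score <- rnorm(n, ifelse(risk == 1, 2.5, 0))
  tr <- cutoff_trend(score, risk, age, sex, sexes = "F", min_n = 50)
  expect_true(all(abs(tr$cutoff - 1.25) < 0.6))
})
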