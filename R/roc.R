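# Empirical ROC analysis, rank-based AUC with DeLong variance, Youden
# cutoff selection and paired AUC comparison. Positivity convention
# throughout: score >= threshold is test-positive (a high index flags
# risk).

check_two_classes <- function(label) {
  label <- as.logical(label)
  if (anyNA(label)) pm_domain_error("labels must be non-missing booleans")
  if (!any(label) || all(label))
    pm_degenerate_error("ROC analysis needs at least one positive and one negative")
  label
}

#' Empirical ROC operating points
#'
#' One operating point per distinct observed score, swept from high to low,
#' plus the all-negative endpoint (threshold +Inf). The lowest score's
#' point is always (sensitivity 1, specificity 0) since every subject then
#' tests positive.
#'
#' @param score numeric index values.
#' @param label logical (or 0/1) MetS status, TRUE = diseased.
#' @return data.frame: threshold, sens, spec, fpr (= 1 - spec), ordered by
#'   decreasing threshold.
#' @export
roc_points <- function(score, label) {
  label <- check_two_classes(label)
  if (anyNA(score)) pm_domain_error("scores must be non-missing")
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  n_pos <- sum(label); n_neg <- sum(!label)
  sens <- vapply(thr, function(t) sum(score >= t & label) / n_pos, 0)
  spec <- vapply(thr, function(t) sum(score < t & !label) / n_neg, 0)
  data.frame(threshold = thr, sens = sens, spec = spec, fpr = 1 - spec)
}

# Placement values: for each positive, the fraction of negatives it beats
# (ties count half); and symmetrically for negatives. Their means are both
# the AUC; their variances give the DeLong variance of the AUC estimate.
placements <- function(score, label) {
  pos <- score[label]; neg <- score[!label]
  v10 <- vapply(pos, function(s) (sum(neg < s) + 0.5 * sum(neg == s)) / length(neg), 0)
  v01 <- vapply(neg, function(s) (sum(pos > s) + 0.5 * sum(pos == s)) / length(pos), 0)
  list(v10 = v10, v01 = v01)
}

#' Rank-based AUC with DeLong confidence interval
#'
#' AUC as the Mann-Whitney concordance probability
#' (concordant + 0.5 ties) / (n_pos * n_neg), computed from ranks; the 95%
#' interval uses the DeLong placement-value variance, clipped to \[0, 1\].
#'
#' @inheritParams roc_points
#' @param conf confidence level.
#' @return list: auc, se, ci (length-2), n_pos, n_neg.
#' @export
auc_rank <- function(score, label, conf = 0.95) {
  label <- check_two_classes(label)
  if (anyNA(score)) pm_domain_error("scores must be non-missing")
  r <- rank(score)
  n_pos <- sum(label); n_neg <- sum(!label)
  auc <- (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  pl <- placements(score, label)
  se <- sqrt(stats::var(pl$v10) / n_pos + stats::var(pl$v01) / n_neg)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * se, 0), 1)
  list(auc = auc, se = se, ci = ci, n_pos = n_pos, n_neg = n_neg)
}

#' Youden-optimal cutoff
#'
#' Maximizes J = sensitivity + specificity - 1 over the empirical operating
#' points. Ties in J are broken toward the lower threshold, the
#' sensitivity-favoring choice for a screening test.
#'
#' @inheritParams roc_points
#' @return list: threshold, youden, sens, spec at the optimum.
#' @export
youden_cutoff <- function(score, label) {
  pts <- roc_points(score, label)
  j <- pts$sens + pts$spec - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.min(pts$threshold[best])]
  list(threshold = pts$threshold[pick], youden = j[pick],
       sens = pts$sens[pick], spec = pts$spec[pick])
}

#' DeLong paired comparison of two AUCs
#'
#' Tests the difference between the AUCs of two scores measured on the same
#' subjects against the same labels, using the paired DeLong variance of
#' the difference. Degenerate case: when both the AUC difference and its
#' variance are zero (e.g. identical scores) the p-value is 1.
#'
#' @param score_a,score_b paired numeric scores.
#' @inheritParams roc_points
#' @return list: auc_a, auc_b, delta, se, z, p (two-sided).
#' @export
delong_compare <- function(score_a, score_b, label) {
  label <- check_two_classes(label)
  if (length(score_a) != length(score_b) || length(score_a) != length(label))
    pm_domain_error("paired comparison needs equal-length score and label vectors")
  pa <- placements(score_a, label); pb <- placements(score_b, label)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  n_pos <- sum(label); n_neg <- sum(!label)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_d <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n_pos +
           (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n_neg
  delta <- auc_a - auc_b
  if (var_d <= 0) {
    z <- if (abs(delta) < 1e-12) 0 else sign(delta) * Inf
  } else {
    z <- delta / sqrt(var_d)
  }
  list(auc_a = auc_a, auc_b = auc_b, delta = delta,
       se = sqrt(max(var_d, 0)), z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Age- and sex-specific cutoff trend
#'
#' Reconstructs how the optimal screening threshold moves with age: at each
#' grid age, the Youden cutoff is recomputed within a sliding age window
#' (half-width `window / 2`) restricted to one sex. Grid points whose
#' window holds fewer than `min_n` subjects, or only one class, are emitted
#' with an NA cutoff rather than dropped.
#'
#' @param score,label,age,sex parallel vectors for the scored cohort.
#' @param sexes which sexes to trace (default both).
#' @param grid ages at which to evaluate; default integer ages spanned by
#'   the cohort.
#' @param window full window width in years (default 4, i.e. +/- 2 years).
#' @param min_n minimum subjects per window (default 10).
#' @return data.frame: sex, age, n, n_pos, cutoff, youden.
#' @export
cutoff_trend <- function(score, label, age, sex, sexes = c("F", "M"),
                         grid = NULL, window = 4, min_n = 10) {
  sex <- validate_sex(sex)
  label <- as.logical(label)
  if (is.null(grid)) grid <- seq(floor(min(age)), ceiling(max(age)))
  if (!length(grid)) pm_degenerate_error("empty age grid")
  out <- do.call(rbind, lapply(sexes, function(s) {
    do.call(rbind, lapply(grid, function(a) {
      idx <- sex == s & abs(age - a) <= window / 2
      n <- sum(idx); npos <- sum(label[idx])
      if (n < min_n || npos == 0 || npos == n)
        return(data.frame(sex = s, age = a, n = n, n_pos = npos,
                          cutoff = NA_real_, youden = NA_real_))
      yc <- youden_cutoff(score[idx], label[idx])
      data.frame(sex = s, age = a, n = n, n_pos = npos,
                 cutoff = yc$threshold, youden = yc$youden)
    }))
  }))
  rownames(out) <- NULL
  out
}
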