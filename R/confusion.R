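# Confusion-matrix screening metrics with confidence intervals.

#' Wald interval for a proportion
#'
#' p +/- z * sqrt(p (1 - p) / n), clipped to \[0, 1\]. Degenerate
#' proportions (0 or 1) collapse to a zero-width interval.
#'
#' @param p observed proportion.
#' @param n denominator count.
#' @param conf confidence level.
#' @return length-2 numeric (lower, upper); NA pair when n = 0.
#' @export
wald_ci <- function(p, n, conf = 0.95) {
  if (is.na(p) || n == 0) return(c(NA_real_, NA_real_))
  if (p < 0 || p > 1) pm_domain_error("proportion outside [0,1]")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  pmin(pmax(p + c(-1, 1) * half, 0), 1)
}

#' Clopper-Pearson interval for a proportion
#'
#' Exact beta-quantile interval; offered as the conservative alternative to
#' [wald_ci()].
#'
#' @param x success count.
#' @param n trial count.
#' @param conf confidence level.
#' @return length-2 numeric (lower, upper).
#' @export
clopper_pearson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

prop_with_ci <- function(x, n, ci_method, conf) {
  if (n == 0) return(list(value = NA_real_, ci = c(NA_real_, NA_real_), n = 0L))
  p <- x / n
  ci <- if (ci_method == "cp") clopper_pearson_ci(x, n, conf) else wald_ci(p, n, conf)
  list(value = p, ci = ci, n = as.integer(n))
}

#' Screening metrics from a 2x2 confusion matrix
#'
#' Sensitivity, specificity, predictive values and likelihood ratios with
#' 95% intervals. Proportion intervals are Wald by default (matching the
#' convention of reporting p +/- 1.96 SE clipped to the unit interval) with
#' Clopper-Pearson as an option; likelihood-ratio intervals use the
#' standard log method. A metric whose denominator is empty (e.g.
#' sensitivity with no diseased subjects) is reported as NA with an NA
#' interval, never silently dropped.
#'
#' @param tp,fn,fp,tn nonnegative integer counts (true/false positives and
#'   negatives).
#' @param ci_method "wald" or "cp" for the four proportions.
#' @param conf confidence level.
#' @return list of metric records, each `list(value, ci, n)`: sens, spec,
#'   ppv, npv, plr, nlr; plus the counts.
#' @export
confusion_metrics <- function(tp, fn, fp, tn, ci_method = c("wald", "cp"),
                              conf = 0.95) {
  ci_method <- match.arg(ci_method)
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    pm_domain_error("confusion counts must be nonnegative integers")
  sens <- prop_with_ci(tp, tp + fn, ci_method, conf)
  spec <- prop_with_ci(tn, tn + fp, ci_method, conf)
  ppv  <- prop_with_ci(tp, tp + fp, ci_method, conf)
  npv  <- prop_with_ci(tn, tn + fn, ci_method, conf)

  z <- stats::qnorm(1 - (1 - conf) / 2)
  lr <- function(num_p, den_p, num_x, num_n, den_x, den_n) {
    # log-method CI for a ratio of two independent proportions
    if (is.na(num_p) || is.na(den_p) || den_p == 0) {
      return(list(value = NA_real_, ci = c(NA_real_, NA_real_)))
    }
    value <- num_p / den_p
    if (num_x == 0 || den_x == 0 || num_x == num_n || den_x == den_n)
      return(list(value = value, ci = c(NA_real_, NA_real_)))
    se_log <- sqrt((1 - num_p) / (num_p * num_n) + (1 - den_p) / (den_p * den_n))
    list(value = value, ci = value * exp(c(-1, 1) * z * se_log))
  }
  plr <- lr(sens$value, 1 - spec$value, tp, tp + fn, fp, tn + fp)
  nlr <- lr(1 - sens$value, spec$value, fn, tp + fn, tn, tn + fp)

  list(sens = sens, spec = spec, ppv = ppv, npv = npv,
       plr = plr, nlr = nlr,
       counts = as.list(counts))
}

#' Confusion counts for a score at a threshold
#'
#' Applies the package positivity convention (score >= threshold is
#' positive) and tabulates against the labels.
#'
#' @inheritParams roc_points
#' @param threshold decision threshold.
#' @return list with tp, fn, fp, tn.
#' @export
confusion_at <- function(score, label, threshold) {
  label <- as.logical(label)
  pos <- score >= threshold
  list(tp = sum(pos & label), fn = sum(!pos & label),
       fp = sum(pos & !label), tn = sum(!pos & !label))
}
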