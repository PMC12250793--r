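# Supporting statistics: correlation, group tests, normality screen,
# outlier screen. Standard machinery is delegated to base R / nortest;
# only the thin contracts (explicit correction argument, exact-vs-normal
# switch, mid-rank Spearman) live here.

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks; two-sided p from
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 df. Constant input is
#' undefined (NA) rather than an error from the correlation routine.
#'
#' @param x,y numeric vectors of equal length >= 3; pairs with any NA are
#'   dropped.
#' @return list: rho, p, n.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) pm_domain_error("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) pm_degenerate_error("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tval), n - 2), n = n)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-tailed comparison of group medians. Exact enumeration is used for
#' small samples (combined n <= 12, no ties); otherwise the tie-corrected
#' normal approximation without continuity correction.
#'
#' @param group_a,group_b numeric vectors (NAs dropped).
#' @return list: statistic (W), p, method.
#' @export
rank_sum_test <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]; group_b <- group_b[!is.na(group_b)]
  if (!length(group_a) || !length(group_b))
    pm_degenerate_error("both groups must be nonempty")
  pooled <- c(group_a, group_b)
  if (length(unique(pooled)) == 1)  # fully tied: no evidence either way
    return(list(statistic = length(group_a) * length(group_b) / 2,
                p = 1, method = "degenerate"))
  ties <- anyDuplicated(pooled) > 0
  exact <- (length(group_a) + length(group_b) <= 12) && !ties
  res <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = FALSE)
  )
  list(statistic = unname(res$statistic), p = res$p.value,
       method = if (exact) "exact" else "normal")
}

#' Chi-square test on a 2x2 table
#'
#' Continuity correction is a required explicit argument: different tables
#' in the source analyses match different conventions, so no silent
#' default is offered.
#'
#' @param a,b,c,d counts, row-wise: (a, b) first row, (c, d) second.
#' @param correction "none" or "yates".
#' @return list: statistic (chi-square), p, df.
#' @export
chi2_2x2 <- function(a, b, c, d, correction) {
  correction <- match.arg(correction, c("none", "yates"))
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(m < 0)) pm_domain_error("counts must be nonnegative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    pm_degenerate_error("2x2 table has an empty margin")
  res <- suppressWarnings(stats::chisq.test(m, correct = correction == "yates"))
  list(statistic = unname(res$statistic), p = res$p.value, df = 1L)
}

#' Kolmogorov-Smirnov normality screen
#'
#' Composite normality test with parameters estimated from the data. The
#' default applies the Lilliefors correction (via nortest); `lilliefors =
#' FALSE` gives the plain one-sample KS against N(mean, sd), whose p-value
#' is anti-conservative when parameters are estimated.
#'
#' @param x numeric vector, n >= 5.
#' @param lilliefors apply the Lilliefors small-sample correction.
#' @return list: D, p, n.
#' @export
ks_normality <- function(x, lilliefors = TRUE) {
  x <- x[!is.na(x)]
  if (length(x) < 5) pm_degenerate_error("normality screen needs n >= 5")
  if (stats::sd(x) == 0) return(list(D = NA_real_, p = NA_real_, n = length(x)))
  res <- if (lilliefors) {
    nortest::lillie.test(x)
  } else {
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  }
  list(D = unname(res$statistic), p = res$p.value, n = length(x))
}

#' Box-plot (Tukey fence) outlier screen
#'
#' Flags values outside \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\] (quartiles type 7).
#' NAs are never flagged.
#'
#' @param x numeric vector, n >= 4.
#' @return logical vector parallel to `x`.
#' @export
tukey_outliers <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 4) pm_degenerate_error("outlier screen needs n >= 4")
  q <- stats::quantile(x[ok], c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  flag <- rep(FALSE, length(x))
  flag[ok] <- x[ok] < q[1] - 1.5 * iqr | x[ok] > q[2] + 1.5 * iqr
  flag
}
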