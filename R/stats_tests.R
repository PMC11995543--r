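## The three comparison tests applied in the analysis: a pooled two-proportion
## z test (line and spectrum comparisons), Welch's unequal-variance t test
## (pCADD means), and a one-sample t test (allele balance vs 0.5). All are
## two-sided.

.test_result <- function(statistic, p_value, df, method) {
  structure(list(statistic = statistic, p_value = p_value, df = df,
                 method = method), class = "dnm_test")
}

#' @export
print.dnm_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, df = %s, p = %s\n", x$method,
              format(x$statistic, digits = 4),
              ifelse(is.na(x$df), "NA", format(x$df, digits = 4)),
              format(x$p_value, digits = 4)))
  invisible(x)
}

#' Two-proportion z test (pooled, no continuity correction)
#'
#' z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2)) with p the pooled proportion;
#' the two-sided p-value comes from the standard normal distribution. When
#' the pooled standard error is zero (all successes or all failures), the
#' statistic is undefined and `NA` is returned.
#'
#' @param x1,n1 Successes and trials in group 1 (`n1 > 0`).
#' @param x2,n2 Successes and trials in group 2 (`n2 > 0`).
#' @return A `dnm_test` result.
#' @export
two_proportion_z_test <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) .stopf("sample sizes must be > 0")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    .stopf("counts must satisfy 0 <= x <= n")
  p_pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  if (se == 0)
    return(.test_result(NA_real_, NA_real_, NA_real_,
                        "two-proportion z test (undefined: zero pooled SE)"))
  z <- (x1 / n1 - x2 / n2) / se
  .test_result(z, 2 * stats::pnorm(-abs(z)), NA_real_,
               "two-proportion z test")
}

#' Welch's unequal-variance two-sample t test
#'
#' @param sample_a,sample_b Numeric vectors of at least two values each, with
#'   nonzero combined variance.
#' @return A `dnm_test` result (Welch-Satterthwaite degrees of freedom).
#' @export
welch_t_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    .stopf("each sample needs at least 2 values")
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0)
    .stopf("both samples have zero variance")
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  .test_result(unname(ht$statistic), ht$p.value, unname(ht$parameter),
               "Welch two-sample t test")
}

#' One-sample t test against a fixed mean
#'
#' @param values Numeric vector of at least two values with nonzero variance.
#' @param mu0 Null mean (e.g. 0.5 for the allele balance of a true
#'   heterozygote).
#' @return A `dnm_test` result.
#' @export
one_sample_t_test <- function(values, mu0) {
  if (length(values) < 2) .stopf("need at least 2 values")
  if (stats::var(values) == 0) .stopf("values have zero variance")
  ht <- stats::t.test(values, mu = mu0)
  .test_result(unname(ht$statistic), ht$p.value, unname(ht$parameter),
               "one-sample t test")
}
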