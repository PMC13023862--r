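#' One-sample t-test with effect size and confidence interval
#'
#' Standard one-sample Student t-test of a numeric vector against `mu0`,
#' reported together with Cohen's d (the standardised mean difference
#' `(mean - mu0)/sd`, identically `t/sqrt(n)`) and the two-sided
#' confidence interval `mean +/- t_crit(df) * sd/sqrt(n)`.
#'
#' @param values Numeric vector, length at least 2, non-constant.
#' @param mu0 Null value (default 0).
#' @param ci_level Confidence level in (0, 1); default 0.95.
#' @return A `group_test_result`: list with `n`, `mean`, `sd`, `t`, `df`,
#'   `p_two_tailed`, `cohens_d`, `ci_level`, `ci_low`, `ci_high`.
#' @examples
#' one_sample_test(c(1, 2, 3))
#' @export
one_sample_test <- function(values, mu0 = 0, ci_level = 0.95) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    stop("`values` must hold at least 2 non-missing numbers", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("`values` are constant; the t statistic is undefined", call. = FALSE)
  }
  if (ci_level <= 0 || ci_level >= 1) {
    stop("`ci_level` must be in (0, 1)", call. = FALSE)
  }
  tt <- stats::t.test(values, mu = mu0, conf.level = ci_level)
  m <- mean(values)
  s <- stats::sd(values)
  structure(
    list(n = length(values), mean = m, sd = s,
         t = unname(tt$statistic), df = length(values) - 1L,
         p_two_tailed = tt$p.value,
         cohens_d = (m - mu0) / s,
         ci_level = ci_level,
         ci_low = unname(tt$conf.int[1L]),
         ci_high = unname(tt$conf.int[2L])),
    class = "group_test_result"
  )
}

#' @rdname one_sample_test
#' @description `one_sample_from_summary()` reconstructs the same result
#'   from summary statistics alone (n, mean, sd), which is how published
#'   group tests are checked when only the summary is printed.
#' @param n Sample size.
#' @param mean Sample mean.
#' @param sd Sample standard deviation (positive).
#' @export
one_sample_from_summary <- function(n, mean, sd, mu0 = 0, ci_level = 0.95) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2", call. = FALSE)
  if (sd <= 0) stop("`sd` must be positive", call. = FALSE)
  if (ci_level <= 0 || ci_level >= 1) {
    stop("`ci_level` must be in (0, 1)", call. = FALSE)
  }
  se <- sd / sqrt(n)
  t_stat <- (mean - mu0) / se
  df <- n - 1L
  t_crit <- stats::qt(1 - (1 - ci_level) / 2, df)
  structure(
    list(n = n, mean = mean, sd = sd,
         t = t_stat, df = df,
         p_two_tailed = 2 * stats::pt(-abs(t_stat), df),
         cohens_d = (mean - mu0) / sd,
         ci_level = ci_level,
         ci_low = mean - t_crit * se,
         ci_high = mean + t_crit * se),
    class = "group_test_result"
  )
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("One-sample t: mean = %.3f (SD = %.3f), t(%d) = %.3f, p = %.4f\n",
              x$mean, x$sd, x$df, x$t, x$p_two_tailed))
  cat(sprintf("  Cohen's d = %.3f, %g%% CI [%.3f, %.3f]\n",
              x$cohens_d, 100 * x$ci_level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Cohen's d from a one-sample t statistic
#'
#' For a one-sample design, `d = t / sqrt(n)` exactly.
#'
#' @param t The t statistic.
#' @param n Sample size (>= 2).
#' @return Cohen's d.
#' @examples
#' cohens_d_from_t(2.635, 36)
#' @export
cohens_d_from_t <- function(t, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2", call. = FALSE)
  t / sqrt(n)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation using average ranks for ties. The p-value uses the
#' Student-t approximation `t = rho * sqrt((n-2)/(1-rho^2))` with n-2
#' degrees of freedom, adequate for the moderate sample sizes this
#' package targets; no exact permutation p is computed.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return A list with `rho` and two-sided `p`.
#' @examples
#' spearman_rho(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("ranks are constant; correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), n - 2)
  }
  list(rho = rho, p = p)
}
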