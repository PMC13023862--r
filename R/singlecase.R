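#' Crawford-Garthwaite modified t-test for a single case
#'
#' Compares one case's score with a normative control sample, treating the
#' controls as a sample rather than a population:
#' \deqn{t = \frac{x - \bar{x}_c}{s_c \sqrt{(n_c + 1)/n_c}}, \quad
#'       df = n_c - 1.}
#' This inflates the denominator relative to a z-score, giving correct
#' Type I error control with modest control samples; as the control sample
#' grows the statistic converges to the z-score. The percentile rank is
#' the point estimate of the case's abnormality — the proportion of the
#' control population expected to score below the case — taken directly
#' from the Student-t CDF at `t` with `df` degrees of freedom.
#'
#' `p_one_tailed` is the lower-tail (deficit-direction) probability
#' \eqn{P(T \le t)}; the two-tailed p is twice the smaller tail.
#'
#' @param case_score The case's score (same units as the norms).
#' @param norms A [normative_sample()] (or list with `mean`, `sd`, `n`).
#' @return A `single_case_result`: list with `case_score`, `t`, `df`,
#'   `p_one_tailed`, `p_two_tailed`, `percentile`, `norms_label`.
#' @examples
#' crawford_t(0.886, normative_sample(0.082, 0.405, 180))
#' @export
crawford_t <- function(case_score, norms) {
  norms <- as_normative_sample(norms)
  if (!is.numeric(case_score) || length(case_score) != 1L ||
      !is.finite(case_score)) {
    stop("`case_score` must be a single finite number", call. = FALSE)
  }
  t_stat <- (case_score - norms$mean) /
    (norms$sd * sqrt((norms$n + 1) / norms$n))
  df <- norms$n - 1L
  p_lower <- stats::pt(t_stat, df)
  structure(
    list(case_score = case_score,
         t = t_stat,
         df = df,
         p_one_tailed = p_lower,
         p_two_tailed = 2 * min(p_lower, 1 - p_lower),
         percentile = 100 * p_lower,
         norms_label = norms$label),
    class = "single_case_result"
  )
}

#' @export
print.single_case_result <- function(x, ...) {
  cat(sprintf("Single case %.3f vs norms%s: t(%d) = %.3f, two-tailed p = %.3f\n",
              x$case_score,
              if (nzchar(x$norms_label)) paste0(" [", x$norms_label, "]") else "",
              x$df, x$t, x$p_two_tailed))
  cat(sprintf("  estimated percentile rank: %.1f\n", x$percentile))
  invisible(x)
}

#' Batch single-case comparisons
#'
#' Runs [crawford_t()] for a set of cases against one normative sample,
#' preserving the input order.
#'
#' @param cases A data frame with columns `participant` and `d` (a named
#'   numeric vector also works, names as participants).
#' @param norms A [normative_sample()].
#' @return A tibble with one row per case: `participant`, `d`, `t`, `df`,
#'   `p_one_tailed`, `p_two_tailed`, `percentile`.
#' @examples
#' batch_case_table(dp_case_dscores(), combined_norms())
#' @export
batch_case_table <- function(cases, norms) {
  norms <- as_normative_sample(norms)
  if (is.numeric(cases)) {
    cases <- tibble::tibble(
      participant = if (is.null(names(cases))) as.character(seq_along(cases))
                    else names(cases),
      d = as.numeric(cases)
    )
  }
  cases <- tibble::as_tibble(cases)
  if (nrow(cases) == 0L) stop("no cases supplied", call. = FALSE)
  if (!all(c("participant", "d") %in% names(cases))) {
    stop("`cases` needs columns `participant` and `d`", call. = FALSE)
  }
  rows <- lapply(cases$d, crawford_t, norms = norms)
  tibble::tibble(
    participant = as.character(cases$participant),
    d = cases$d,
    t = vapply(rows, `[[`, numeric(1), "t"),
    df = vapply(rows, `[[`, integer(1), "df"),
    p_one_tailed = vapply(rows, `[[`, numeric(1), "p_one_tailed"),
    p_two_tailed = vapply(rows, `[[`, numeric(1), "p_two_tailed"),
    percentile = vapply(rows, `[[`, numeric(1), "percentile")
  )
}

#' Count cases significantly below the norm
#'
#' A case counts as significantly below the normative range when its
#' modified t is negative and its one-tailed (deficit-direction) p-value
#' is below `alpha`.
#'
#' @param results A tibble from [batch_case_table()].
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return Integer count.
#' @examples
#' count_below_norm(batch_case_table(dp_case_dscores(), combined_norms()))
#' @export
count_below_norm <- function(results, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  results <- tibble::as_tibble(results)
  if (nrow(results) == 0L) return(0L)
  sum(results$t < 0 & results$p_one_tailed < alpha)
}
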