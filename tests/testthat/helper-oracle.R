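# Independent straight-line transcription of the twelve-step improved
# D-score algorithm, written directly from the published step list and
# kept free of the package's optimised code path.
oracle_dscore <- function(session, variant = "error_penalty") {
  tr <- session$trials
  tr <- tr[tr$latency_ms <= 10000, ]                     # step 2 (trials)
  tr <- tr[tr$block %in% c(3, 4, 6, 7), ]                # step 1
  blocks <- c(3, 4, 6, 7)
  if (variant == "reference") {
    # step 5: correct-latency means; step 7: error -> block mean + 600
    corr_mean <- vapply(blocks, function(b) {
      mean(tr$first_latency_ms[tr$block == b & tr$first_response_correct])
    }, numeric(1))
    v <- ifelse(tr$first_response_correct, tr$first_latency_ms,
                corr_mean[match(tr$block, blocks)] + 600)
  } else {
    v <- tr$latency_ms                                   # implicit penalty
  }
  m <- vapply(blocks, function(b) mean(v[tr$block == b]), numeric(1)) # step 9
  s1 <- stats::sd(v[tr$block %in% c(3, 6)])              # step 6
  s2 <- stats::sd(v[tr$block %in% c(4, 7)])
  q1 <- (m[3] - m[1]) / s1                               # steps 10-11 (B6-B3)
  q2 <- (m[4] - m[2]) / s2                               # (B7-B4)
  (q1 + q2) / 2                                          # step 12
}

# Brute-force log-spaced trapezoid evaluation of the JZS marginal
# integral, independent of the package's adaptive quadrature.
grid_jzs_bf10 <- function(t, n, r = sqrt(2) / 2, n_points = 2e5,
                          g_lo = 1e-10, g_hi = 1e6) {
  nu <- n - 1
  u <- seq(log(g_lo), log(g_hi), length.out = n_points)
  g <- exp(u)
  log_f <- -0.5 * log1p(n * g) -
    (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) +
    log(r) - 0.5 * log(2 * pi) - 1.5 * log(g) - r^2 / (2 * g) + log(g)
  f <- exp(log_f)
  h <- u[2] - u[1]
  num <- h * (sum(f) - (f[1] + f[n_points]) / 2)
  num / (1 + t^2 / nu)^(-(nu + 1) / 2)
}
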