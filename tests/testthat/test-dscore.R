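test_that("slow-trial filtering removes exactly the trials above 10,000 ms", {
  s <- session_from_blocks(list(`3` = c(rep(700, 19), 12000),
                                `4` = rep(700, 40),
                                `6` = rep(900, 20),
                                `7` = rep(900, 40)))
  out <- filter_slow_trials(s)
  expect_equal(out$removed, 1L)
  expect_true(all(out$session$trials$latency_ms <= 10000))

  # boundary is strict: 9,999 ms (and 10,000 itself) survive
  s2 <- session_from_blocks(list(`3` = c(rep(700, 18), 9999, 10000),
                                 `6` = rep(900, 20)))
  out2 <- filter_slow_trials(s2)
  expect_equal(out2$removed, 0L)

  # counting oracle: k injected slow trials are the k removed
  withr::with_seed(7, {
    for (k in c(0, 3, 9)) {
      base <- runif(60, 400, 2000)
      lat <- c(base, runif(k, 10001, 20000))
      s3 <- session_from_blocks(list(`3` = sample(lat)))
      expect_equal(filter_slow_trials(s3)$removed, k)
    }
  })
})

test_that("fast-response exclusion uses a strict 10% threshold", {
  mk <- function(n_fast) {
    session_from_blocks(list(`3` = c(rep(250, n_fast), rep(700, 20 - n_fast)),
                             `4` = rep(700, 20),
                             `6` = rep(900, 20),
                             `7` = rep(900, 20)))
  }
  at_boundary <- check_fast_exclusion(mk(8))    # 8 of 80 = exactly 10%
  expect_equal(at_boundary$fraction, 0.10)
  expect_false(at_boundary$excluded)

  over <- check_fast_exclusion(mk(10))          # 10 of 80 = 12.5%
  expect_equal(over$fraction, 0.125)
  expect_true(over$excluded)

  clean <- check_fast_exclusion(mk(0))
  expect_equal(clean$fraction, 0)
  expect_false(clean$excluded)
})

test_that("fast fraction is assessed after slow-trial removal", {
  # 8 fast of 80 is exactly 10% before removal, but dropping one slow
  # trial shrinks the denominator to 79 and tips the fraction over
  s <- session_from_blocks(list(`3` = c(rep(250, 8), rep(700, 11), 12000),
                                `4` = rep(700, 20),
                                `6` = rep(900, 20),
                                `7` = rep(900, 20)))
  res <- compute_d(s)
  expect_equal(res$fast_trial_fraction, 8 / 79)
  expect_true(res$excluded)
})

test_that("the two-block-pair D matches the closed-form hand computation", {
  s <- session_from_blocks(list(`3` = rep(700, 20), `4` = rep(700, 40),
                                `6` = rep(900, 20), `7` = rep(900, 40)))
  res <- compute_d(s)
  sd1 <- sd(c(rep(700, 20), rep(900, 20)))   # 100 * sqrt(40/39)
  sd2 <- sd(c(rep(700, 40), rep(900, 40)))   # 100 * sqrt(80/79)
  expect_equal(res$pooled_sd_36, sd1)
  expect_equal(res$pooled_sd_47, sd2)
  expect_equal(res$quotient_36, 200 / sd1)
  expect_equal(res$quotient_47, 200 / sd2)
  expect_equal(res$d, (200 / sd1 + 200 / sd2) / 2)
  # published-precision spot values for the same configuration
  expect_equal(round(res$quotient_36, 3), 1.975)
  expect_equal(round(res$quotient_47, 3), 1.987)
  expect_equal(round(res$d, 3), 1.981)
})

test_that("equal block-pair latency multisets give D = 0", {
  withr::with_seed(3, {
    a <- runif(20, 500, 1500)
    b <- runif(40, 500, 1500)
    s <- session_from_blocks(list(`3` = a, `6` = sample(a),
                                  `4` = b, `7` = sample(b)))
    expect_equal(compute_d(s)$d, 0)
  })
})

test_that("variants agree exactly on error-free data and diverge with errors", {
  withr::with_seed(11, {
    blocks <- list(`3` = runif(20, 500, 1200), `4` = runif(40, 500, 1200),
                   `6` = runif(20, 600, 1400), `7` = runif(40, 600, 1400))
    clean <- session_from_blocks(blocks)
    expect_identical(compute_d(clean, "reference")$d,
                     compute_d(clean, "error_penalty")$d)

    # errors only in the incongruent blocks, with corrected-response
    # latencies well above each block's correct mean + 600: the variants
    # must disagree, and moving the same errors to the other pairing
    # (relabelling congruent <-> incongruent) must flip the sign of the
    # disagreement, since only error placement distinguishes the two
    blocks_err <- blocks
    blocks_err$`6`[1:4] <- blocks_err$`6`[1:4] + 3000
    blocks_err$`7`[1:6] <- blocks_err$`7`[1:6] + 3000
    correct <- list(`3` = rep(TRUE, 20), `4` = rep(TRUE, 40),
                    `6` = c(rep(FALSE, 4), rep(TRUE, 16)),
                    `7` = c(rep(FALSE, 6), rep(TRUE, 34)))
    dirty <- session_from_blocks(blocks_err, correct = correct)
    diff_incong <- compute_d(dirty, "error_penalty")$d -
      compute_d(dirty, "reference")$d
    expect_gt(abs(diff_incong), 1e-6)

    mirrored <- swap_pairings(dirty)  # errors now sit in congruent blocks
    diff_cong <- compute_d(mirrored, "error_penalty")$d -
      compute_d(mirrored, "reference")$d
    expect_equal(diff_cong, -diff_incong, tolerance = 1e-9)
  })
})

test_that("both variants match an independent step-by-step transcription", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      n1 <- sample(5:10, 1)
      n2 <- sample(5:10, 1)
      blocks <- list(`3` = runif(n1, 400, 2000), `6` = runif(n1, 400, 2000),
                     `4` = runif(n2, 400, 2000), `7` = runif(n2, 400, 2000))
      correct <- lapply(blocks, function(v) {
        ok <- runif(length(v)) > 0.2
        if (!any(ok)) ok[1] <- TRUE
        ok
      })
      s <- session_from_blocks(blocks, correct = correct)
      expect_equal(compute_d(s, "error_penalty")$d,
                   oracle_dscore(s, "error_penalty"), tolerance = 1e-12)
      expect_equal(compute_d(s, "reference")$d,
                   oracle_dscore(s, "reference"), tolerance = 1e-12)
    }
  })
})

test_that("D is antisymmetric under pairing relabelling and invariant to shift and scale", {
  withr::with_seed(5, {
    blocks <- list(`3` = runif(20, 500, 1200), `4` = runif(40, 500, 1200),
                   `6` = runif(20, 600, 1500), `7` = runif(40, 600, 1500))
    correct <- lapply(blocks, function(v) runif(length(v)) > 0.1)
    s <- session_from_blocks(blocks, correct = correct)
    d0 <- compute_d(s)$d

    expect_equal(compute_d(swap_pairings(s))$d, -d0, tolerance = 1e-12)

    shifted <- s
    shifted$trials$latency_ms <- shifted$trials$latency_ms + 350
    shifted$trials$first_latency_ms <- shifted$trials$first_latency_ms + 350
    expect_equal(compute_d(shifted)$d, d0, tolerance = 1e-9)

    scaled <- s
    scaled$trials$latency_ms <- scaled$trials$latency_ms * 2.5
    scaled$trials$first_latency_ms <- scaled$trials$first_latency_ms * 2.5
    expect_equal(compute_d(scaled)$d, d0, tolerance = 1e-9)
  })
})

test_that("degenerate sessions raise errors instead of returning infinities", {
  flat <- session_from_blocks(list(`3` = rep(700, 20), `4` = rep(700, 40),
                                   `6` = rep(700, 20), `7` = rep(700, 40)))
  expect_error(compute_d(flat), "degenerate|SD")

  missing_block <- session_from_blocks(list(`3` = rep(700, 20),
                                            `6` = rep(900, 20),
                                            `7` = rep(900, 40)))
  expect_error(compute_d(missing_block), "fewer than 2|block")
})

test_that("cohort scoring summarises retained participants and flags exclusions", {
  withr::with_seed(9, {
    mk_clean <- function(shift, id) {
      session_from_blocks(list(`3` = runif(20, 500, 900),
                               `4` = runif(40, 500, 900),
                               `6` = runif(20, 500, 900) + shift,
                               `7` = runif(40, 500, 900) + shift), id = id)
    }
    sessions <- list(mk_clean(50, "A"), mk_clean(100, "B"), mk_clean(150, "C"))
    sc <- score_cohort(sessions)
    expect_equal(sc$norms$mean, mean(sc$results$d))
    expect_equal(sc$norms$sd, sd(sc$results$d))
    expect_equal(sc$norms$n, 3L)

    # one contaminated participant: present in results, absent from norms
    # 15 fast trials of 120 total = 12.5% > 10%
    fast <- session_from_blocks(list(`3` = c(rep(250, 15), runif(5, 500, 900)),
                                     `4` = runif(40, 500, 900),
                                     `6` = runif(20, 550, 950),
                                     `7` = runif(40, 550, 950)), id = "FAST")
    sc2 <- score_cohort(c(sessions, list(fast)))
    expect_equal(nrow(sc2$results), 4L)
    expect_equal(sc2$norms$n, 3L)
    expect_true(sc2$results$excluded[sc2$results$participant_id == "FAST"])
    expect_error(score_cohort(list(fast, fast)), "fewer than 2")
  })
})
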