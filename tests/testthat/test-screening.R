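test_that("PI20 totals apply reverse keying and map onto severity bands", {
  # all "strongly agree": 15 positives at 5 plus 5 reversed to 1
  all5 <- pi20_score(rep(5L, 20))
  expect_equal(all5$total, 15 * 5 + 5 * 1)
  expect_equal(all5$band, "moderate")

  # all "strongly disagree": positives at 1, reversed to 5
  all1 <- pi20_score(rep(1L, 20))
  expect_equal(all1$total, 15 * 1 + 5 * 5)
  expect_equal(all1$band, "none")

  # band boundaries: construct totals of exactly 85 and 84
  rev_idx <- c(3L, 8L, 11L, 15L, 19L)
  items85 <- rep(5L, 20)
  items85[rev_idx] <- 4L            # mapped to 2 each: 75 + 10 = 85
  expect_equal(pi20_score(items85)$total, 85)
  expect_equal(pi20_score(items85)$band, "severe")

  items84 <- items85
  items84[rev_idx[5]] <- 5L         # one mapped 2 -> 1: total 84
  expect_equal(pi20_score(items84)$total, 84)
  expect_equal(pi20_score(items84)$band, "moderate")

  items65 <- rep(4L, 20)
  items65[rev_idx] <- 5L            # 15*4 + 5*1 = 65
  expect_equal(pi20_score(items65)$band, "mild")
  items64 <- items65
  items64[1] <- 3L
  expect_equal(pi20_score(items64)$band, "none")

  expect_error(pi20_score(c(rep(3L, 19), 6L)), "outside the 1..5")
  expect_error(pi20_score(rep(3L, 19)), "20 integer")
})

test_that("the PI20 attainable range is [20, 100], by corner enumeration", {
  rev_idx <- c(3L, 8L, 11L, 15L, 19L)
  # per-item extremes: every combination of {1,5} on the positive side
  # and {1,5} on the reverse side pins the extrema of the total
  totals <- c()
  for (pos in c(1L, 5L)) {
    for (rev in c(1L, 5L)) {
      items <- rep(pos, 20)
      items[rev_idx] <- rev
      totals <- c(totals, pi20_score(items)$total)
    }
  }
  expect_equal(min(totals), 20)   # positives all 1, reverses answered 5
  expect_equal(max(totals), 100)  # positives all 5, reverses answered 1
  # random probes stay inside the corner-delimited range
  withr::with_seed(12, {
    for (i in 1:50) {
      t_rand <- pi20_score(sample(1:5, 20, replace = TRUE))$total
      expect_gte(t_rand, 20)
      expect_lte(t_rand, 100)
    }
  })
})

test_that("CFPT deviation scores are exhaustively bounded by the full reversal", {
  expect_equal(cfpt_trial_score(1:6, 1:6), 0)
  expect_equal(cfpt_trial_score(6:1, 1:6), 18)
  expect_equal(8 * cfpt_trial_score(6:1, 1:6), 144)

  # brute force over all 720 arrangements of 6 faces
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) !anyDuplicated(r)), ]
  expect_equal(nrow(perms), 720L)
  scores <- apply(perms, 1, cfpt_trial_score, correct = 1:6)
  expect_equal(max(scores), 18)
  expect_equal(min(scores), 0)
  expect_equal(sum(scores == 0), 1L)  # only the correct order scores 0

  # symmetry in the two orderings, on a sample of arrangements
  withr::with_seed(6, {
    for (i in 1:25) {
      a <- sample(6)
      b <- sample(6)
      expect_equal(cfpt_trial_score(a, b), cfpt_trial_score(b, a))
    }
  })

  expect_error(cfpt_trial_score(c(1, 1, 2, 3, 4, 5), 1:6), "permutations")
  expect_error(cfpt_trial_score(1:5, 1:5), "6 faces")
})

test_that("famous-faces adjustment removes unknown celebrities from the denominator", {
  expect_equal(fft_adjusted_percent(30, 0), 50)
  expect_equal(fft_adjusted_percent(25, 10), 50)
  expect_equal(fft_adjusted_percent(60, 0), 100)
  expect_error(fft_adjusted_percent(1, 60), "undefined")
  expect_error(fft_adjusted_percent(51, 10), "exceeds")

  # removing an unknown never decreases the percentage when the response
  # was wrong, never increases it when it was correct (small enumeration)
  for (total in c(10L, 20L)) {
    for (u in 0:(total - 2L)) {
      for (correct in 0:(total - u - 1L)) {
        base <- fft_adjusted_percent(correct, u, total)
        expect_gte(fft_adjusted_percent(correct, u + 1L, total), base)
        if (correct > 0L) {
          expect_lte(fft_adjusted_percent(correct - 1L, u + 1L, total), base)
        }
      }
    }
  }
})

test_that("AQ exclusion triggers at 32 and not below", {
  expect_true(aq_excluded(32))
  expect_false(aq_excluded(31))
  expect_false(aq_excluded(0))
  expect_equal(aq_excluded(c(10, 32, 45, 31)),
               c(FALSE, TRUE, TRUE, FALSE))
  expect_error(aq_excluded(-1), "negative")
})

test_that("DP classification needs two impaired objective tasks, CFPT mirrored", {
  norms <- list(cfmt = normative_sample(58, 7, 50),
                cfpt = normative_sample(36, 12, 50),
                fft = normative_sample(85, 10, 50))

  both <- dp_classify(list(cfmt = 58 - 21, cfpt = 36, fft = 85 - 30), norms)
  expect_true(both$is_dp)
  expect_setequal(both$impaired_tasks, c("cfmt", "fft"))

  none <- dp_classify(list(cfmt = 58, cfpt = 36, fft = 85), norms)
  expect_false(none$is_dp)
  expect_equal(none$impaired_tasks, character(0))

  only_one <- dp_classify(list(cfmt = 58 - 21, cfpt = 36, fft = 85), norms)
  expect_false(only_one$is_dp)

  # CFPT runs in the deficit-is-high direction: a deviation score far
  # above the control mean is the impairment
  cfpt_high <- dp_classify(list(cfmt = 58 - 21, cfpt = 36 + 30, fft = 85),
                           norms)
  expect_true(cfpt_high$is_dp)
  expect_setequal(cfpt_high$impaired_tasks, c("cfmt", "cfpt"))
  # ... and a very low CFPT deviation score is good performance, not a hit
  cfpt_low <- dp_classify(list(cfmt = 58, cfpt = 2, fft = 85), norms)
  expect_equal(cfpt_low$impaired_tasks, character(0))

  expect_error(dp_classify(list(cfmt = 30, cfpt = 40, fft = 40),
                           norms[c("cfmt", "cfpt")]), "missing norms")
  expect_error(dp_classify(list(cfmt = 30), norms), "missing score")
})
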