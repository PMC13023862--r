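#' Seven-block IAT design
#'
#' The block layout of the standard seven-block IAT: two single-category
#' practice blocks, a first pair of combined test blocks, a key-reversal
#' practice block, and a second pair of combined test blocks. Blocks 3 and 4
#' carry the congruent face-trait pairing and blocks 6 and 7 the incongruent
#' pairing; block labels are fixed, so only the presentation order differs
#' between counterbalance conditions.
#'
#' @return A tibble with one row per block: `block`, `n_trials`,
#'   `block_function` (`"practice"` or `"test"`) and `pairing`
#'   (`"single_category"`, `"congruent"` or `"incongruent"`).
#' @examples
#' iat_block_design()
#' @export
iat_block_design <- function() {
  tibble::tibble(
    block = 1:7,
    n_trials = c(20L, 20L, 20L, 40L, 20L, 20L, 40L),
    block_function = c("practice", "practice", "test", "test",
                       "practice", "test", "test"),
    pairing = c("single_category", "single_category", "congruent",
                "congruent", "single_category", "incongruent", "incongruent")
  )
}

# Presentation order of block labels for each counterbalance condition.
block_presentation_order <- function(order) {
  switch(order,
         congruent_first = 1:7,
         incongruent_first = c(5L, 2L, 6L, 7L, 1L, 3L, 4L),
         stop("unknown counterbalance order: ", order, call. = FALSE))
}

#' Simulation parameters for trial-level IAT sessions
#'
#' Bundles and validates every knob of the session simulator. Latencies are
#' drawn from a lognormal distribution; the congruency effect is applied as
#' a shift of the log-latency location on congruent test blocks, so
#' `congruency_effect_ms` is the reduction of the median latency, in
#' milliseconds, on those blocks. Error trials keep their first (incorrect)
#' keypress latency and add `error_correction_extra_ms` for the corrective
#' response, mirroring a task that forces correction before proceeding.
#' Fast anticipatory responses replace the base draw with a uniform draw on
#' 100-299 ms so the sub-300 ms participant-exclusion rule can be exercised
#' deterministically.
#'
#' The defaults describe a neurotypical control cohort: 180 participants,
#' counterbalanced 50:50, median latency 800 ms with lognormal spread 0.25,
#' a 5% error rate with a 400 ms correction cost, no anticipatory
#' contamination, and a congruency effect calibrated so that the cohort
#' mean D-score is close to 0.082, the published control-sample mean for
#' this face-trait task.
#'
#' @param base_latency_ms Median latency in ms off congruent blocks; > 300.
#' @param latency_sigma Lognormal scale (log-ms spread); positive.
#' @param congruency_effect_ms Median latency reduction (ms) on congruent
#'   test blocks. May be negative or zero; must be < `base_latency_ms`.
#' @param error_rate Per-trial probability of an incorrect first response.
#' @param error_correction_extra_ms Added latency (ms) from the first wrong
#'   keypress to the corrected response; non-negative.
#' @param fast_responder_rate Per-trial probability of an anticipatory
#'   (< 300 ms) response.
#' @param n_participants Cohort size; at least 1.
#' @param congruent_first_fraction Fraction of the cohort assigned the
#'   congruent-first block order.
#' @param seed Integer base seed; participant `i` uses `seed + i`.
#'
#' @return A validated list of class `simulation_params`.
#' @examples
#' simulation_params(n_participants = 10, seed = 1)
#' @export
simulation_params <- function(base_latency_ms = 800,
                              latency_sigma = 0.25,
                              congruency_effect_ms = 17,
                              error_rate = 0.05,
                              error_correction_extra_ms = 400,
                              fast_responder_rate = 0,
                              n_participants = 180L,
                              congruent_first_fraction = 0.5,
                              seed = 1L) {
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop("`", nm, "` must be a probability in [0, 1]", call. = FALSE)
    }
  }
  chk_prob(error_rate, "error_rate")
  chk_prob(fast_responder_rate, "fast_responder_rate")
  chk_prob(congruent_first_fraction, "congruent_first_fraction")
  if (!is.numeric(base_latency_ms) || length(base_latency_ms) != 1L ||
      !is.finite(base_latency_ms) || base_latency_ms <= 300) {
    stop("`base_latency_ms` must be a single number > 300", call. = FALSE)
  }
  if (!is.numeric(latency_sigma) || length(latency_sigma) != 1L ||
      !is.finite(latency_sigma) || latency_sigma <= 0) {
    stop("`latency_sigma` must be positive", call. = FALSE)
  }
  if (!is.numeric(congruency_effect_ms) || length(congruency_effect_ms) != 1L ||
      !is.finite(congruency_effect_ms) ||
      congruency_effect_ms >= base_latency_ms) {
    stop("`congruency_effect_ms` must be finite and < base_latency_ms",
         call. = FALSE)
  }
  if (!is.numeric(error_correction_extra_ms) ||
      length(error_correction_extra_ms) != 1L ||
      !is.finite(error_correction_extra_ms) || error_correction_extra_ms < 0) {
    stop("`error_correction_extra_ms` must be non-negative", call. = FALSE)
  }
  n_participants <- as.integer(n_participants)
  if (is.na(n_participants) || n_participants < 1L) {
    stop("`n_participants` must be a positive integer", call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer", call. = FALSE)
  structure(
    list(base_latency_ms = base_latency_ms,
         latency_sigma = latency_sigma,
         congruency_effect_ms = congruency_effect_ms,
         error_rate = error_rate,
         error_correction_extra_ms = error_correction_extra_ms,
         fast_responder_rate = fast_responder_rate,
         n_participants = n_participants,
         congruent_first_fraction = congruent_first_fraction,
         seed = seed),
    class = "simulation_params"
  )
}

#' Simulate one trial-level IAT session
#'
#' Generates a full seven-block session for one participant: block sequence
#' in the participant's counterbalance order, lognormal latencies with the
#' congruency effect applied on congruent test blocks, error trials with
#' corrected-response latencies, and optional anticipatory (< 300 ms)
#' responses. The first `round(congruent_first_fraction * n_participants)`
#' participants receive the congruent-first order, the rest the
#' incongruent-first order. Output is fully reproducible given
#' `(params$seed, participant_index)`.
#'
#' @param params A [simulation_params()] object.
#' @param participant_index 1-based participant number within the cohort.
#'
#' @return An `iat_session` object: a list with `participant_id`, `age`,
#'   `order` and a `trials` tibble (one row per trial, in presentation
#'   order) with columns `block`, `trial_index`, `block_function`,
#'   `pairing`, `stimulus_kind`, `first_response_correct`,
#'   `first_latency_ms`, `latency_ms`.
#' @examples
#' s <- generate_session(simulation_params(seed = 42), 1)
#' nrow(s$trials)  # 180 trials across the seven blocks
#' @export
generate_session <- function(params, participant_index) {
  stopifnot(inherits(params, "simulation_params"))
  participant_index <- as.integer(participant_index)
  if (is.na(participant_index) || participant_index < 1L) {
    stop("`participant_index` must be a positive integer", call. = FALSE)
  }
  n_first <- round(params$congruent_first_fraction * params$n_participants)
  order <- if (participant_index <= n_first) "congruent_first" else "incongruent_first"

  design <- iat_block_design()
  withr::with_seed(params$seed + participant_index, {
    age <- sample(18:80, 1L)
    blocks <- block_presentation_order(order)
    trials <- lapply(blocks, function(b) {
      row <- design[design$block == b, ]
      n <- row$n_trials
      congruent_test <- row$pairing == "congruent" && row$block_function == "test"
      mu <- log(params$base_latency_ms -
                  if (congruent_test) params$congruency_effect_ms else 0)
      lat <- stats::rlnorm(n, meanlog = mu, sdlog = params$latency_sigma)
      is_fast <- stats::runif(n) < params$fast_responder_rate
      lat[is_fast] <- stats::runif(sum(is_fast), 100, 299)
      is_err <- !is_fast & stats::runif(n) < params$error_rate
      first_lat <- lat
      lat[is_err] <- lat[is_err] + params$error_correction_extra_ms
      kind <- if (row$pairing == "single_category") {
        if (b == 2L) rep("word", n) else rep("face", n)
      } else {
        rep(c("face", "word"), length.out = n)
      }
      tibble::tibble(
        block = b,
        trial_index = seq_len(n),
        block_function = row$block_function,
        pairing = row$pairing,
        stimulus_kind = kind,
        first_response_correct = !is_err,
        first_latency_ms = first_lat,
        latency_ms = lat
      )
    })
    new_session(
      participant_id = sprintf("P%03d", participant_index),
      age = age,
      order = order,
      trials = dplyr::bind_rows(trials)
    )
  })
}

#' Simulate a cohort of IAT sessions
#'
#' Generates `params$n_participants` sessions with deterministic
#' per-participant seeds (`seed + i`), so cohorts are reproducible and
#' individual sessions can be regenerated in isolation.
#'
#' @param params A [simulation_params()] object.
#' @return A list of `iat_session` objects.
#' @examples
#' cohort <- generate_cohort(simulation_params(n_participants = 3, seed = 7))
#' length(cohort)
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  lapply(seq_len(params$n_participants), function(i) generate_session(params, i))
}

#' Simulate a screening-battery roster
#'
#' Produces a plausible roster of screening scores for a prosopagnosia
#' cohort: CFMT (face memory, max 72), CFPT (face perception deviation
#' score, 0 best), FFT (famous-faces adjusted percent), PI20 self-report
#' total and AQ (autism-spectrum quotient). Exactly `n_high_aq` rows
#' receive an AQ of 32 or more so that AQ-based exclusion has a known
#' outcome; which rows are high-AQ is randomised under `seed`.
#'
#' @param n Number of participants.
#' @param n_high_aq Number of rows with AQ >= 32; between 0 and `n`.
#' @param seed Integer seed.
#' @return A tibble with columns `participant_id`, `age`, `cfmt`, `cfpt`,
#'   `fft`, `pi20`, `aq`.
#' @examples
#' roster <- generate_screening_roster(51, 15, seed = 1)
#' sum(roster$aq >= 32)
#' @export
generate_screening_roster <- function(n, n_high_aq, seed = 1L) {
  n <- as.integer(n)
  n_high_aq <- as.integer(n_high_aq)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer", call. = FALSE)
  if (is.na(n_high_aq) || n_high_aq < 0L || n_high_aq > n) {
    stop("`n_high_aq` must be between 0 and `n`", call. = FALSE)
  }
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  withr::with_seed(as.integer(seed), {
    aq <- sample(4:31, n, replace = TRUE)
    high <- sample.int(n, n_high_aq)
    aq[high] <- sample(32:45, n_high_aq, replace = TRUE)
    tibble::tibble(
      participant_id = sprintf("S%03d", seq_len(n)),
      age = sample(18:81, n, replace = TRUE),
      cfmt = as.integer(clamp(round(stats::rnorm(n, 33, 5)), 0, 72)),
      cfpt = round(clamp(stats::rnorm(n, 28, 4.4), 0, 144), 2),
      fft = round(clamp(stats::rnorm(n, 45, 15), 0, 100), 2),
      pi20 = as.integer(clamp(round(stats::rnorm(n, 80, 7)), 20, 100)),
      aq = as.integer(aq)
    )
  })
}
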