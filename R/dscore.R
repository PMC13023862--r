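#' Remove over-slow trials from a session
#'
#' Drops every trial whose latency to the final (corrected) response
#' exceeds 10,000 ms. This is a trial-level rule; it never removes a
#' participant.
#'
#' @param session An `iat_session`.
#' @param max_latency_ms Cutoff in ms; trials strictly above it are
#'   removed. Default 10,000.
#' @return A list with `session` (the filtered session) and `removed`
#'   (number of trials dropped).
#' @export
filter_slow_trials <- function(session, max_latency_ms = 10000) {
  validate_session(session, check_counts = FALSE)
  keep <- session$trials$latency_ms <= max_latency_ms
  out <- session
  out$trials <- session$trials[keep, ]
  list(session = out, removed = sum(!keep))
}

#' Participant-level fast-response exclusion
#'
#' Computes the fraction of trials with latency below 300 ms. A
#' participant is excluded when strictly more than 10% of their trials are
#' that fast: exactly 10% does not exclude. Applied after slow-trial
#' removal, so the denominator is the retained trial count.
#'
#' @param session An `iat_session` with at least one trial.
#' @param fast_ms Anticipation cutoff in ms (default 300, strict `<`).
#' @param max_fraction Exclusion threshold (default 0.10, strict `>`).
#' @return A list with `fraction` and logical `excluded`.
#' @export
check_fast_exclusion <- function(session, fast_ms = 300, max_fraction = 0.10) {
  validate_session(session, check_counts = FALSE)
  n <- nrow(session$trials)
  if (n == 0L) {
    stop("participant ", session$participant_id,
         ": cannot assess fast-response exclusion on an empty session",
         call. = FALSE)
  }
  frac <- sum(session$trials$latency_ms < fast_ms) / n
  list(fraction = frac, excluded = frac > max_fraction)
}

#' Compute the improved IAT D-score for one session
#'
#' Implements the improved D-score algorithm on the four combined test
#' blocks (3, 4, 6, 7). After removing trials slower than 10,000 ms and
#' flagging participants with > 10% of trials under 300 ms, block means
#' and two pooled SDs are formed, one over all trials of the 20-trial
#' test-block pair (3 and 6) and one over the 40-trial pair (4 and 7);
#' each incongruent-minus-congruent block-mean difference is divided by
#' its pooled SD and the two quotients are averaged. Positive D means
#' faster responding under the congruent face-trait pairing.
#'
#' Two error-trial treatments are available:
#' \describe{
#'   \item{`"reference"`}{block means are first computed over correct
#'     trials only (the first-keypress latencies); each error trial then
#'     contributes its block's correct-trial mean plus 600 ms.}
#'   \item{`"error_penalty"`}{every trial contributes its full latency
#'     from stimulus onset to the final corrected response, so errors
#'     carry their own implicit time penalty. This is the package
#'     default.}
#' }
#' The pooled SDs use the same per-trial values as the block means (the
#' replaced values under `"reference"`, the corrected-response latencies
#' under `"error_penalty"`) with the n-1 sample-SD denominator. On a
#' session with no error trials the two variants agree exactly.
#'
#' @param session An `iat_session`.
#' @param variant `"error_penalty"` (default) or `"reference"`.
#' @return A `dscore_result`: list with `d`, `quotient_36`, `quotient_47`,
#'   `pooled_sd_36`, `pooled_sd_47`, `block_means` (named by block),
#'   `n_trials_removed_slow`, `fast_trial_fraction`, `excluded`,
#'   `variant` and `participant_id`.
#' @examples
#' s <- generate_session(simulation_params(seed = 11), 1)
#' compute_d(s)$d
#' @export
compute_d <- function(session, variant = c("error_penalty", "reference")) {
  variant <- match.arg(variant)
  filt <- filter_slow_trials(session)
  fast <- check_fast_exclusion(filt$session)
  tr <- filt$session$trials
  tr <- tr[tr$block %in% c(3L, 4L, 6L, 7L), ]

  values <- numeric(nrow(tr))
  if (variant == "error_penalty") {
    values <- tr$latency_ms
  } else {
    values <- tr$first_latency_ms
    for (b in c(3L, 4L, 6L, 7L)) {
      in_b <- tr$block == b
      correct_b <- in_b & tr$first_response_correct
      if (sum(correct_b) == 0L) {
        stop("participant ", session$participant_id, ": block ", b,
             " has no correct trials; reference scoring undefined",
             call. = FALSE)
      }
      repl <- mean(tr$first_latency_ms[correct_b]) + 600
      values[in_b & !tr$first_response_correct] <- repl
    }
  }

  block_mean <- function(b) {
    v <- values[tr$block == b]
    if (length(v) < 2L) {
      stop("participant ", session$participant_id, ": block ", b,
           " has fewer than 2 usable trials", call. = FALSE)
    }
    mean(v)
  }
  means <- vapply(c(3L, 4L, 6L, 7L), block_mean, numeric(1))
  names(means) <- c("3", "4", "6", "7")

  sd_36 <- stats::sd(values[tr$block %in% c(3L, 6L)])
  sd_47 <- stats::sd(values[tr$block %in% c(4L, 7L)])
  if (!is.finite(sd_36) || sd_36 <= 0 || !is.finite(sd_47) || sd_47 <= 0) {
    stop("participant ", session$participant_id,
         ": pooled SD is zero or undefined; latencies are degenerate",
         call. = FALSE)
  }

  q36 <- (means[["6"]] - means[["3"]]) / sd_36
  q47 <- (means[["7"]] - means[["4"]]) / sd_47
  structure(
    list(d = (q36 + q47) / 2,
         quotient_36 = q36,
         quotient_47 = q47,
         pooled_sd_36 = sd_36,
         pooled_sd_47 = sd_47,
         block_means = means,
         n_trials_removed_slow = filt$removed,
         fast_trial_fraction = fast$fraction,
         excluded = fast$excluded,
         variant = variant,
         participant_id = session$participant_id),
    class = "dscore_result"
  )
}

#' @export
print.dscore_result <- function(x, ...) {
  cat(sprintf("D-score (%s) for %s: D = %.3f%s\n", x$variant,
              x$participant_id, x$d,
              if (x$excluded) "  [participant excluded: >10% fast trials]" else ""))
  cat(sprintf("  quotients: %.3f (B6-B3), %.3f (B7-B4); slow trials removed: %d\n",
              x$quotient_36, x$quotient_47, x$n_trials_removed_slow))
  invisible(x)
}

#' Score a cohort and build its normative summary
#'
#' Applies [compute_d()] to every session and summarises the non-excluded
#' D-scores as a [normative_sample()] (mean, n-1 sample SD, count
#' retained). Excluded participants remain in the per-participant result
#' table, flagged, so exclusions are auditable rather than silent.
#'
#' @param sessions A list of `iat_session` objects.
#' @param variant Error-trial treatment passed to [compute_d()].
#' @param label Label for the resulting normative sample.
#' @return A list with `results` (tibble: `participant_id`, `d`,
#'   `quotient_36`, `quotient_47`, `fast_trial_fraction`,
#'   `n_trials_removed_slow`, `excluded`) and `norms` (a
#'   `normative_sample` over the retained participants).
#' @examples
#' cohort <- generate_cohort(simulation_params(n_participants = 5, seed = 2))
#' score_cohort(cohort)$norms
#' @export
score_cohort <- function(sessions, variant = c("error_penalty", "reference"),
                         label = "scored cohort") {
  variant <- match.arg(variant)
  res <- lapply(sessions, compute_d, variant = variant)
  results <- tibble::tibble(
    participant_id = vapply(res, `[[`, character(1), "participant_id"),
    d = vapply(res, `[[`, numeric(1), "d"),
    quotient_36 = vapply(res, `[[`, numeric(1), "quotient_36"),
    quotient_47 = vapply(res, `[[`, numeric(1), "quotient_47"),
    fast_trial_fraction = vapply(res, `[[`, numeric(1), "fast_trial_fraction"),
    n_trials_removed_slow = vapply(res, `[[`, integer(1),
                                   "n_trials_removed_slow"),
    excluded = vapply(res, `[[`, logical(1), "excluded")
  )
  kept <- results$d[!results$excluded]
  if (length(kept) < 2L) {
    stop("fewer than 2 non-excluded sessions; cannot summarise a cohort",
         call. = FALSE)
  }
  list(results = results,
       norms = normative_sample(mean(kept), stats::sd(kept), length(kept),
                                label = label))
}
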