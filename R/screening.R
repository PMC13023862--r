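#' Score a PI20 self-report questionnaire
#'
#' The PI20 is a 20-item prosopagnosia index answered on a five-point
#' Likert scale. Fifteen items are scored as given (strongly agree = 5,
#' strongly disagree = 1) and five are reverse-keyed (v -> 6 - v). The
#' total, between 20 and 100, maps onto severity bands: 65-74 mild,
#' 75-84 moderate, 85-100 severe, and no band below 65.
#'
#' @param items Integer vector of 20 responses, each in 1..5.
#' @param reverse_items Positions of the five reverse-keyed items.
#' @return A list with integer `total` and `band` (one of `"none"`,
#'   `"mild"`, `"moderate"`, `"severe"`).
#' @examples
#' pi20_score(rep(5, 20))
#' @export
pi20_score <- function(items, reverse_items = c(3L, 8L, 11L, 15L, 19L)) {
  items <- as.integer(items)
  if (length(items) != 20L || anyNA(items)) {
    stop("`items` must be 20 integer responses", call. = FALSE)
  }
  if (any(items < 1L | items > 5L)) {
    bad <- which(items < 1L | items > 5L)[1L]
    stop("item ", bad, " is outside the 1..5 response scale", call. = FALSE)
  }
  reverse_items <- as.integer(reverse_items)
  if (length(unique(reverse_items)) != 5L ||
      any(reverse_items < 1L | reverse_items > 20L)) {
    stop("`reverse_items` must be 5 distinct positions in 1..20",
         call. = FALSE)
  }
  scored <- items
  scored[reverse_items] <- 6L - scored[reverse_items]
  total <- sum(scored)
  band <- if (total >= 85L) "severe"
          else if (total >= 75L) "moderate"
          else if (total >= 65L) "mild"
          else "none"
  list(total = total, band = band)
}

#' CFPT deviation score for one sorting trial
#'
#' In each face-perception sorting trial the participant orders six
#' comparison faces by similarity to a target. The trial score sums, over
#' faces, the absolute displacement between the participant's position
#' for that face and its correct position; 0 is perfect and the per-trial
#' maximum (a full reversal) is 18, giving 144 over the eight upright
#' trials.
#'
#' @param arrangement The participant's ordering: a permutation (vector
#'   of labels, left to right).
#' @param correct The correct ordering over the same six labels.
#' @return Integer deviation score in 0..18.
#' @examples
#' cfpt_trial_score(6:1, 1:6)  # full reversal -> 18
#' @export
cfpt_trial_score <- function(arrangement, correct) {
  if (length(arrangement) != 6L || length(correct) != 6L) {
    stop("both orderings must have exactly 6 faces", call. = FALSE)
  }
  if (anyDuplicated(arrangement) || anyDuplicated(correct) ||
      !setequal(arrangement, correct)) {
    stop("orderings must be permutations of the same 6 labels",
         call. = FALSE)
  }
  pos_arr <- match(correct, arrangement)
  sum(abs(pos_arr - seq_len(6L)))
}

#' Famous-faces adjusted percent correct
#'
#' Celebrities unknown to a participant (by name or biography) are removed
#' from the denominator before the percent correct is computed, so the
#' score reflects recognition of faces the participant could in principle
#' know: `100 * correct / (total_items - unknown)`.
#'
#' @param correct Number of correctly identified faces.
#' @param unknown Number of celebrities unfamiliar to the participant.
#' @param total_items Total faces presented (default 60).
#' @return Adjusted percent correct in 0..100.
#' @examples
#' fft_adjusted_percent(25, 10)  # 25 of 50 known -> 50
#' @export
fft_adjusted_percent <- function(correct, unknown, total_items = 60L) {
  correct <- as.integer(correct)
  unknown <- as.integer(unknown)
  total_items <- as.integer(total_items)
  if (anyNA(c(correct, unknown, total_items)) || correct < 0L ||
      unknown < 0L || total_items < 1L) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (unknown >= total_items) {
    stop("all items unknown; adjusted percentage is undefined",
         call. = FALSE)
  }
  if (correct > total_items - unknown) {
    stop("`correct` exceeds the number of known items", call. = FALSE)
  }
  100 * correct / (total_items - unknown)
}

#' AQ-based exclusion
#'
#' Participants scoring 32 or more on the Autism-Spectrum Quotient are
#' excluded from a prosopagnosia cohort, since autistic traits are an
#' independent source of face-processing difficulty.
#'
#' @param aq Integer AQ score(s); vectorised.
#' @return Logical: `TRUE` where the participant is excluded.
#' @examples
#' aq_excluded(c(31, 32))
#' @export
aq_excluded <- function(aq) {
  if (any(aq < 0, na.rm = TRUE)) stop("AQ scores cannot be negative",
                                      call. = FALSE)
  aq >= 32
}

#' Apply the AQ exclusion to a screening roster
#'
#' @param roster A data frame with an `aq` column (see
#'   [generate_screening_roster()]).
#' @return The roster restricted to rows with AQ below 32.
#' @examples
#' nrow(apply_aq_exclusion(generate_screening_roster(51, 15, seed = 1)))
#' @export
apply_aq_exclusion <- function(roster) {
  roster <- tibble::as_tibble(roster)
  if (!"aq" %in% names(roster)) {
    stop("roster has no `aq` column", call. = FALSE)
  }
  roster[!aq_excluded(roster$aq), ]
}

#' Classify a screening profile as developmental prosopagnosia
#'
#' A task counts as impaired when the score lies more than 2 control SDs
#' in the deficit direction: below `mean - 2*sd` for the face-memory
#' (CFMT) and famous-faces (FFT) tasks, and above `mean + 2*sd` for the
#' face-perception deviation score (CFPT), where higher is worse. The
#' participant is classified as DP when at least two of the three
#' objective face tasks are impaired.
#'
#' @param profile A list or one-row data frame with numeric `cfmt`,
#'   `cfpt` and `fft` scores.
#' @param task_norms Named list of [normative_sample()] objects for
#'   `cfmt`, `cfpt` and `fft`.
#' @return A list with `impaired_tasks` (character vector) and logical
#'   `is_dp`.
#' @examples
#' norms <- list(cfmt = normative_sample(58, 7, 50),
#'               cfpt = normative_sample(36, 12, 50),
#'               fft = normative_sample(85, 10, 50))
#' dp_classify(list(cfmt = 30, cfpt = 40, fft = 40), norms)
#' @export
dp_classify <- function(profile, task_norms) {
  tasks <- c("cfmt", "cfpt", "fft")
  missing_norms <- setdiff(tasks, names(task_norms))
  if (length(missing_norms) > 0L) {
    stop("missing norms for task(s): ",
         paste(missing_norms, collapse = ", "), call. = FALSE)
  }
  missing_scores <- setdiff(tasks, names(profile))
  if (length(missing_scores) > 0L) {
    stop("profile is missing score(s): ",
         paste(missing_scores, collapse = ", "), call. = FALSE)
  }
  impaired <- character(0)
  for (task in tasks) {
    nm <- as_normative_sample(task_norms[[task]])
    score <- as.numeric(profile[[task]])
    hit <- if (task == "cfpt") score > nm$mean + 2 * nm$sd
           else score < nm$mean - 2 * nm$sd
    if (isTRUE(hit)) impaired <- c(impaired, task)
  }
  list(impaired_tasks = impaired, is_dp = length(impaired) >= 2L)
}
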