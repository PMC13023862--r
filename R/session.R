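#' IAT session objects
#'
#' An `iat_session` holds one participant's ordered trial stream plus the
#' counterbalance order and demographics. `new_session()` constructs and
#' validates one; `validate_session()` checks an existing object against
#' the structural rules of the seven-block design (block labels 1-7, 20
#' trials in blocks 1, 2, 3, 5 and 6, 40 in blocks 4 and 7, latency
#' consistency between the first keypress and the final correct response).
#'
#' @param participant_id Participant identifier (single string).
#' @param age Age in years, or `NA`.
#' @param order `"congruent_first"` or `"incongruent_first"`.
#' @param trials A data frame with one row per trial; see
#'   [generate_session()] for the column set.
#'
#' @return `new_session()` returns a validated `iat_session`;
#'   `validate_session()` returns its input invisibly or throws.
#' @export
new_session <- function(participant_id, age = NA_integer_, order, trials) {
  x <- structure(
    list(participant_id = as.character(participant_id)[1L],
         age = as.integer(age)[1L],
         order = as.character(order)[1L],
         trials = tibble::as_tibble(trials)),
    class = "iat_session"
  )
  validate_session(x)
}

trial_columns <- c("block", "trial_index", "block_function", "pairing",
                   "stimulus_kind", "first_response_correct",
                   "first_latency_ms", "latency_ms")

#' @rdname new_session
#' @param x An `iat_session` object.
#' @param check_counts If `TRUE` (default), enforce the per-block trial
#'   counts of the seven-block design; set to `FALSE` for sessions that
#'   have already been through trial-level filtering.
#' @export
validate_session <- function(x, check_counts = TRUE) {
  if (!inherits(x, "iat_session")) stop("not an iat_session", call. = FALSE)
  id <- x$participant_id
  if (!x$order %in% c("congruent_first", "incongruent_first")) {
    stop("participant ", id, ": unknown counterbalance order '", x$order, "'",
         call. = FALSE)
  }
  tr <- x$trials
  missing_cols <- setdiff(trial_columns, names(tr))
  if (length(missing_cols) > 0L) {
    stop("participant ", id, ": missing trial column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!tr$block %in% 1:7)) {
    bad <- which(!tr$block %in% 1:7)[1L]
    stop("participant ", id, ", row ", bad, ": block ", tr$block[bad],
         " outside 1..7", call. = FALSE)
  }
  if (any(tr$latency_ms <= 0) || any(tr$first_latency_ms <= 0)) {
    stop("participant ", id, ": non-positive latency", call. = FALSE)
  }
  correct <- tr$first_response_correct
  if (any(abs(tr$latency_ms[correct] - tr$first_latency_ms[correct]) > 1e-9)) {
    stop("participant ", id,
         ": correct trials must have latency_ms == first_latency_ms",
         call. = FALSE)
  }
  if (any(tr$latency_ms[!correct] < tr$first_latency_ms[!correct])) {
    stop("participant ", id,
         ": error trials must have latency_ms >= first_latency_ms",
         call. = FALSE)
  }
  expected_fn <- c("practice", "practice", "test", "test",
                   "practice", "test", "test")
  if (any(tr$block_function != expected_fn[tr$block])) {
    stop("participant ", id,
         ": block_function inconsistent with the seven-block design",
         call. = FALSE)
  }
  if (check_counts) {
    design <- iat_block_design()
    counts <- table(factor(tr$block, levels = 1:7))
    if (any(as.integer(counts) != design$n_trials)) {
      stop("participant ", id, ": per-block trial counts ",
           paste(as.integer(counts), collapse = "/"),
           " do not match the design (20/20/20/40/20/20/40)", call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.iat_session <- function(x, ...) {
  cat(sprintf("IAT session %s (%s, age %s): %d trials\n",
              x$participant_id, x$order,
              ifelse(is.na(x$age), "?", x$age), nrow(x$trials)))
  invisible(x)
}
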