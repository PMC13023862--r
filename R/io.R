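#' Read and write trial-level session files
#'
#' Sessions are exchanged as a strict comma-separated table with one row
#' per trial and a fixed header: `participant_id, age, order, block,
#' trial_index, block_function, pairing, stimulus_kind,
#' first_response_correct, first_latency_ms, latency_ms`. Booleans are
#' serialised as `true`/`false`, latencies as milliseconds. On reading,
#' trials are grouped by participant, ordered by `(block, trial_index)`
#' within the participant's presentation order, and every session is
#' validated; violations name the participant and offending value rather
#' than being coerced.
#'
#' @param path Path to a CSV file.
#' @param sessions A list of `iat_session` objects.
#'
#' @return `read_sessions()` returns a list of `iat_session` objects;
#'   `write_sessions()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' cohort <- generate_cohort(simulation_params(n_participants = 2, seed = 3))
#' write_sessions(cohort, f)
#' length(read_sessions(f))
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- names(utils::read.csv(path, nrows = 1L, check.names = FALSE))
  required <- c("participant_id", "age", "order", trial_columns)
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0L) {
    stop("session file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      age = readr::col_integer(),
      order = readr::col_character(),
      block = readr::col_integer(),
      trial_index = readr::col_integer(),
      block_function = readr::col_character(),
      pairing = readr::col_character(),
      stimulus_kind = readr::col_character(),
      first_response_correct = readr::col_logical(),
      first_latency_ms = readr::col_double(),
      latency_ms = readr::col_double()
    ),
    progress = FALSE
  )
  ids <- unique(raw$participant_id)
  lapply(ids, function(id) {
    rows <- raw[raw$participant_id == id, ]
    cb_order <- rows$order[1L]
    trials <- rows[, trial_columns]
    # restore presentation order: blocks in the counterbalance sequence,
    # trials by index within block
    if (cb_order %in% c("congruent_first", "incongruent_first")) {
      seq_blocks <- block_presentation_order(cb_order)
      pos <- match(trials$block, seq_blocks)
      trials <- trials[order(pos, trials$trial_index), ]
    }
    new_session(participant_id = id, age = rows$age[1L],
                order = cb_order, trials = trials)
  })
}

#' @rdname read_sessions
#' @export
write_sessions <- function(sessions, path) {
  if (inherits(sessions, "iat_session")) sessions <- list(sessions)
  if (length(sessions) == 0L) stop("no sessions to write", call. = FALSE)
  rows <- lapply(sessions, function(s) {
    validate_session(s)
    dplyr::bind_cols(
      tibble::tibble(participant_id = s$participant_id, age = s$age,
                     order = s$order),
      s$trials
    )
  })
  out <- dplyr::bind_rows(rows)
  out$first_response_correct <- ifelse(out$first_response_correct,
                                       "true", "false")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write normative-sample files
#'
#' Normative samples travel as small key-value (YAML) files with keys
#' `mean`, `sd`, `n` and optionally `label`. Values are validated on
#' reading: `sd` must be positive and `n` at least 2.
#'
#' @param path Path to a YAML file.
#' @param norms A [normative_sample()] object.
#' @return `read_norms()` returns a `normative_sample`; `write_norms()`
#'   returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_norms(normative_sample(0.082, 0.405, 180, "combined"), f)
#' read_norms(f)
#' @export
read_norms <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # keep bare `n`/`y` keys as strings instead of YAML 1.1 booleans
  x <- yaml::read_yaml(path,
                       handlers = list("bool#yes" = function(v) v,
                                       "bool#no" = function(v) v))
  for (key in c("mean", "sd", "n")) {
    if (is.null(x[[key]])) {
      stop("norms file is missing key '", key, "'", call. = FALSE)
    }
  }
  as_normative_sample(x)
}

#' @rdname read_norms
#' @export
write_norms <- function(norms, path) {
  norms <- as_normative_sample(norms)
  yaml::write_yaml(list(mean = norms$mean, sd = norms$sd, n = norms$n,
                        label = norms$label), path, precision = 12)
  invisible(path)
}

#' Write a single-case results table
#'
#' Renders a batch of single-case comparisons as a tab-separated table
#' with the five columns of the conventional case-report layout:
#' participant, the case's D-score, the Crawford modified t, its (two
#' tailed) p-value and the estimated percentile rank. D, t and p are
#' printed to 3 decimal places and the percentile to 1; full-precision
#' values stay in the in-memory table returned by [batch_case_table()].
#'
#' @param results A data frame from [batch_case_table()] (columns
#'   `participant`, `d`, `t`, `p_two_tailed`, `percentile`).
#' @param path Output path for the TSV file.
#' @return `path`, invisibly.
#' @export
write_case_table <- function(results, path) {
  results <- tibble::as_tibble(results)
  if (nrow(results) == 0L) {
    stop("cannot write an empty case table", call. = FALSE)
  }
  required <- c("participant", "d", "t", "p_two_tailed", "percentile")
  missing_cols <- setdiff(required, names(results))
  if (length(missing_cols) > 0L) {
    stop("case table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    participant = as.character(results$participant),
    d = sprintf("%.3f", results$d),
    t = sprintf("%.3f", results$t),
    p = sprintf("%.3f", results$p_two_tailed),
    percentile = sprintf("%.1f", results$percentile)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Packaged case D-scores and combined norms
#'
#' `dp_case_dscores()` returns the packaged table of 36 published
#' single-case IAT D-scores for a developmental-prosopagnosia cohort;
#' `combined_norms()` returns the matching combined control normative
#' sample (mean 0.082, SD 0.405, N 180). Both are shipped as plain-text
#' fixtures under `inst/extdata/`.
#'
#' @return A tibble with columns `participant` and `d`, or a
#'   `normative_sample`.
#' @examples
#' nrow(dp_case_dscores())
#' combined_norms()
#' @export
dp_case_dscores <- function() {
  path <- system.file("extdata", "dp_case_dscores.tsv", package = "faceiat",
                      mustWork = TRUE)
  readr::read_tsv(path,
                  col_types = readr::cols(participant = readr::col_character(),
                                          d = readr::col_double()),
                  progress = FALSE)
}

#' @rdname dp_case_dscores
#' @export
combined_norms <- function() {
  read_norms(system.file("extdata", "combined_norms.yaml",
                         package = "faceiat", mustWork = TRUE))
}
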