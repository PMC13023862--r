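#' Pipeline configuration
#'
#' Collects and validates everything a pipeline run needs. Exactly one
#' source of trial data may be set: a trial CSV (`trials`) or simulation
#' parameters (`sim_params`). Case-level runs instead read a two-column
#' TSV of D-scores (`cases`) plus a norms file or object (`norms`).
#'
#' @param trials Path to a trial-level session CSV, or `NULL`.
#' @param sim_params A [simulation_params()] object, or `NULL`.
#' @param cases Path to a `participant`/`d` TSV, a data frame, or `NULL`.
#' @param norms Path to a norms YAML file or a [normative_sample()].
#' @param d_variant Error-trial treatment for [compute_d()].
#' @param alpha Single-case significance level; in (0, 1).
#' @param ci_level Group confidence level; in (0, 1).
#' @param bayes_prior_scale Cauchy prior scale for the Bayes factor.
#' @param output_dir Directory for output files (created if needed).
#' @param seed Integer seed used by simulation-backed runs.
#' @param verbose Emit progress/exclusion messages to stderr.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(trials = NULL, sim_params = NULL, cases = NULL,
                            norms = NULL,
                            d_variant = c("error_penalty", "reference"),
                            alpha = 0.05, ci_level = 0.95,
                            bayes_prior_scale = sqrt(2) / 2,
                            output_dir = tempdir(), seed = 1L,
                            verbose = TRUE) {
  d_variant <- match.arg(d_variant)
  if (!is.null(trials) && !is.null(sim_params)) {
    stop("set exactly one of `trials` and `sim_params`", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)",
                                     call. = FALSE)
  if (ci_level <= 0 || ci_level >= 1) stop("`ci_level` must be in (0, 1)",
                                           call. = FALSE)
  if (bayes_prior_scale <= 0) stop("`bayes_prior_scale` must be positive",
                                   call. = FALSE)
  structure(
    list(trials = trials, sim_params = sim_params, cases = cases,
         norms = norms, d_variant = d_variant, alpha = alpha,
         ci_level = ci_level, bayes_prior_scale = bayes_prior_scale,
         output_dir = output_dir, seed = as.integer(seed),
         verbose = isTRUE(verbose)),
    class = "pipeline_config"
  )
}

pipeline_log <- function(config, ...) {
  if (config$verbose) message(...)
  invisible(NULL)
}

resolve_sessions <- function(config) {
  if (!is.null(config$trials)) {
    pipeline_log(config, "reading sessions from ", config$trials)
    read_sessions(config$trials)
  } else if (!is.null(config$sim_params)) {
    pipeline_log(config, "simulating ",
                 config$sim_params$n_participants, " sessions")
    generate_cohort(config$sim_params)
  } else {
    stop("no trial input: set `trials` or `sim_params`", call. = FALSE)
  }
}

resolve_cases <- function(config) {
  if (is.null(config$cases)) {
    stop("no case input: set `cases`", call. = FALSE)
  }
  if (is.character(config$cases)) {
    readr::read_tsv(config$cases,
                    col_types = readr::cols(
                      participant = readr::col_character(),
                      d = readr::col_double()),
                    progress = FALSE)
  } else {
    tibble::as_tibble(config$cases)
  }
}

resolve_norms <- function(config) {
  if (is.null(config$norms)) {
    stop("no normative sample configured", call. = FALSE)
  }
  if (is.character(config$norms)) read_norms(config$norms)
  else as_normative_sample(config$norms)
}

#' Score a cohort of sessions end to end
#'
#' Loads (or simulates) trial-level sessions, computes per-participant
#' D-scores with the configured error-trial variant, logs every
#' participant-level exclusion with its rule, and writes the scored
#' table to `dscores.csv` in the output directory together with a
#' `norms.yaml` summary of the retained participants.
#'
#' @param config A [pipeline_config()] with a trial source set.
#' @return Invisibly, the [score_cohort()] result.
#' @export
run_score <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sessions <- resolve_sessions(config)
  scored <- score_cohort(sessions, variant = config$d_variant)
  excluded <- scored$results[scored$results$excluded, ]
  for (i in seq_len(nrow(excluded))) {
    pipeline_log(config, "excluded ", excluded$participant_id[i],
                 ": fast-trial fraction ",
                 sprintf("%.3f", excluded$fast_trial_fraction[i]),
                 " exceeds 0.10")
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(scored$results,
                   file.path(config$output_dir, "dscores.csv"),
                   progress = FALSE)
  write_norms(scored$norms, file.path(config$output_dir, "norms.yaml"))
  pipeline_log(config, "scored ", nrow(scored$results), " participants (",
               scored$norms$n, " retained)")
  invisible(scored)
}

#' Run batch single-case comparisons
#'
#' Compares each case D-score against the configured normative sample,
#' writes the five-column case table (`case_table.tsv`, fixed decimals)
#' and a full-precision sidecar (`case_table_full.csv`), and reports the
#' number of cases significantly below the norm at the configured alpha.
#'
#' @param config A [pipeline_config()] with `cases` and `norms` set.
#' @return Invisibly, a list with `table` (the full-precision tibble) and
#'   `n_below`.
#' @export
run_singlecase <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cases <- resolve_cases(config)
  norms <- resolve_norms(config)
  tab <- batch_case_table(cases, norms)
  n_below <- count_below_norm(tab, alpha = config$alpha)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_case_table(tab, file.path(config$output_dir, "case_table.tsv"))
  readr::write_csv(tab, file.path(config$output_dir, "case_table_full.csv"),
                   progress = FALSE)
  pipeline_log(config, nrow(tab), " cases compared; ", n_below,
               " significantly below the norm at alpha = ", config$alpha)
  invisible(list(table = tab, n_below = n_below))
}

#' Run group-level inference on case D-scores
#'
#' One-sample t-test of the case D-scores against zero with Cohen's d and
#' confidence interval, the JZS Bayes factor, and the sequential Bayes
#' factor in presentation order. Writes `group_report.yaml` and
#' `sequential_bf.csv` to the output directory.
#'
#' @param config A [pipeline_config()] with `cases` set.
#' @return Invisibly, a list with `test` (a `group_test_result`), `bayes`
#'   (a `bayes_result`) and `sequential` (tibble `k`, `t`, `bf10`).
#' @export
run_group <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cases <- resolve_cases(config)
  test <- one_sample_test(cases$d, mu0 = 0, ci_level = config$ci_level)
  bayes <- jzs_bf10(test$t, test$n, prior_scale = config$bayes_prior_scale)
  seq_tab <- sequential_bf(cases$d, prior_scale = config$bayes_prior_scale)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(
    list(n = test$n, mean = test$mean, sd = test$sd, t = test$t,
         df = test$df, p_two_tailed = test$p_two_tailed,
         cohens_d = test$cohens_d, ci_level = test$ci_level,
         ci_low = test$ci_low, ci_high = test$ci_high,
         bf10 = bayes$bf10, bayes_prior_scale = bayes$prior_scale),
    file.path(config$output_dir, "group_report.yaml"),
    precision = 12
  )
  readr::write_csv(seq_tab,
                   file.path(config$output_dir, "sequential_bf.csv"),
                   progress = FALSE)
  pipeline_log(config, sprintf(
    "group: t(%d) = %.3f, p = %.4f, d = %.3f, BF10 = %.3f",
    test$df, test$t, test$p_two_tailed, test$cohens_d, bayes$bf10))
  invisible(list(test = test, bayes = bayes, sequential = seq_tab))
}

#' Apply screening exclusions to a roster
#'
#' Reads a screening roster (CSV with at least an `aq` column), applies
#' the AQ >= 32 exclusion, logs each excluded participant, and writes the
#' retained roster to `roster_retained.csv`.
#'
#' @param roster Path to a roster CSV or a data frame.
#' @param config A [pipeline_config()] (used for output dir and logging).
#' @return Invisibly, the retained roster tibble.
#' @export
run_screen <- function(roster, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(roster)) {
    roster <- readr::read_csv(roster, show_col_types = FALSE,
                              progress = FALSE)
  }
  roster <- tibble::as_tibble(roster)
  retained <- apply_aq_exclusion(roster)
  dropped <- roster[aq_excluded(roster$aq), ]
  for (i in seq_len(nrow(dropped))) {
    pipeline_log(config, "excluded ", dropped$participant_id[i],
                 ": AQ ", dropped$aq[i], " >= 32")
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(retained,
                   file.path(config$output_dir, "roster_retained.csv"),
                   progress = FALSE)
  pipeline_log(config, nrow(retained), " of ", nrow(roster),
               " participants retained after AQ exclusion")
  invisible(retained)
}
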