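# Build minimal test-block sessions with fully controlled latencies.
#
# `blocks` is a named list ("3", "4", "6", "7") of final-response latency
# vectors; `correct` (same shape, logical) marks first-response accuracy.
# Error trials get first_latency_ms = latency_ms - err_gap_ms. Sessions
# built here deliberately skip practice blocks and need not match the
# full-design trial counts; scoring only consumes the test blocks.
session_from_blocks <- function(blocks, correct = NULL, err_gap_ms = 300,
                                id = "T01", order = "congruent_first") {
  stopifnot(all(names(blocks) %in% c("3", "4", "6", "7")))
  fn <- c(`3` = "test", `4` = "test", `6` = "test", `7` = "test")
  pairing <- c(`3` = "congruent", `4` = "congruent",
               `6` = "incongruent", `7` = "incongruent")
  rows <- lapply(names(blocks), function(b) {
    lat <- as.numeric(blocks[[b]])
    ok <- if (is.null(correct)) rep(TRUE, length(lat)) else correct[[b]]
    first <- ifelse(ok, lat, pmax(lat - err_gap_ms, 1))
    tibble::tibble(
      block = as.integer(b),
      trial_index = seq_along(lat),
      block_function = fn[[b]],
      pairing = pairing[[b]],
      stimulus_kind = rep(c("face", "word"), length.out = length(lat)),
      first_response_correct = ok,
      first_latency_ms = first,
      latency_ms = lat
    )
  })
  structure(
    list(participant_id = id, age = 30L, order = order,
         trials = dplyr::bind_rows(rows)),
    class = "iat_session"
  )
}

# Swap the congruent and incongruent test blocks (3<->6, 4<->7),
# relabelling pairing to match; used for the antisymmetry property.
swap_pairings <- function(session) {
  tr <- session$trials
  map <- c(`3` = 6L, `6` = 3L, `4` = 7L, `7` = 4L)
  is_test <- tr$block %in% c(3L, 4L, 6L, 7L)
  tr$block[is_test] <- map[as.character(tr$block[is_test])]
  tr$pairing[is_test] <- ifelse(tr$block[is_test] %in% c(3L, 4L),
                                "congruent", "incongruent")
  out <- session
  out$trials <- tr[order(match(tr$block, c(3L, 4L, 6L, 7L)),
                         tr$trial_index), ]
  out
}
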