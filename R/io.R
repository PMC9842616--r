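# Long-format trial CSV: schema, validated reader, writer.

trial_columns <- function() {
  c("participant_id", "domain", "frame", "norm_type", "session", "phase",
    "trial_index", "repeat_index", "gamble_value", "certain_value",
    "gamble_prob", "response", "response_type", "feedback")
}

validate_trials <- function(trials, source = "trial data") {
  problems <- character(0)
  add <- function(rows, msg) {
    if (length(rows) > 0) {
      shown <- paste(utils::head(rows, 5), collapse = ", ")
      more <- if (length(rows) > 5) sprintf(" (+%d more)", length(rows) - 5) else ""
      problems <<- c(problems, sprintf("%s at row(s) %s%s", msg, shown, more))
    }
  }
  chk <- function(bad, msg) add(which(bad), msg)

  chk(!trials$gamble_value %in% 10:30, "gamble_value outside 10..30")
  chk(trials$certain_value != 10, "certain_value must be 10")
  chk(trials$gamble_prob != 0.5, "gamble_prob must be 0.5")
  chk(!trials$frame %in% frame_levels(), "unknown frame")
  chk(!trials$domain %in% domain_levels(), "unknown domain")
  chk(!trials$norm_type %in% norm_levels(), "unknown norm_type")
  chk(!trials$phase %in% phase_levels(), "unknown phase")
  chk(!trials$session %in% c("D0", "D3"), "unknown session")
  chk(!trials$response %in% response_levels(), "unknown response")
  chk(!trials$response_type %in% c("own", "guess"), "unknown response_type")
  chk(!trials$feedback %in% c("correct", "incorrect", "none"),
      "unknown feedback")

  defs <- phase_definitions()
  expected_rt <- defs$response_type[match(trials$phase, defs$phase)]
  chk(!is.na(expected_rt) & trials$response_type != expected_rt,
      "response_type inconsistent with phase")
  chk(trials$feedback != "none" & trials$phase != "learning",
      "feedback outside the learning phase")
  expected_sess <- defs$session[match(trials$phase, defs$phase)]
  chk(!is.na(expected_sess) & trials$session != expected_sess,
      "session inconsistent with phase")

  key <- paste(trials$participant_id, trials$session, trials$phase,
               trials$trial_index)
  chk(duplicated(key), "duplicate (participant, session, phase, trial_index)")

  if (length(problems) > 0) {
    stop(sprintf("Invalid %s:\n  - %s", source,
                 paste(problems, collapse = "\n  - ")), call. = FALSE)
  }
  invisible(trials)
}

#' Write / read the long-format trial CSV
#'
#' One row per participant x session x phase x trial. Columns:
#' `participant_id`, `domain`, `frame`, `norm_type`, `session`, `phase`,
#' `trial_index`, `repeat_index`, `gamble_value`, `certain_value`,
#' `gamble_prob`, `response`, `response_type`, `feedback`. Reading
#' validates the schema (ranges, categorical values, phase/feedback
#' consistency, duplicate trials) and reports offending row numbers;
#' write-then-read reproduces the records exactly.
#'
#' @param trials Trial tibble with the columns above.
#' @param path CSV file path (UTF-8, comma-separated, header row).
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns the validated trial tibble.
#' @export
write_trials <- function(trials, path) {
  miss <- setdiff(trial_columns(), names(trials))
  if (length(miss) > 0) {
    stop(sprintf("Trial data missing columns: %s.",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  validate_trials(trials[, trial_columns()], source = "trial data")
  readr::write_csv(trials[, trial_columns()], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  header <- names(readr::read_csv(path, n_max = 0, progress = FALSE,
                                  show_col_types = FALSE))
  miss <- setdiff(trial_columns(), header)
  if (length(miss) > 0) {
    stop(sprintf("`%s` is missing required columns: %s.", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  trials <- readr::read_csv(
    path, progress = FALSE, show_col_types = FALSE,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      domain = readr::col_character(),
      frame = readr::col_character(),
      norm_type = readr::col_character(),
      session = readr::col_character(),
      phase = readr::col_character(),
      trial_index = readr::col_integer(),
      repeat_index = readr::col_integer(),
      gamble_value = readr::col_integer(),
      certain_value = readr::col_integer(),
      gamble_prob = readr::col_double(),
      response = readr::col_character(),
      response_type = readr::col_character(),
      feedback = readr::col_character()
    )
  )
  validate_trials(trials[, trial_columns()], source = sprintf("file `%s`", path))
}
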