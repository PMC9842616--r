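# Parametric gamble task: scenario grids, expected values, and per-phase
# trial schedules for the two-session (day 0 / day 3) design.
#
# Every trial offers a certain option (magnitude 10) against a 50% gamble
# whose magnitude varies parametrically from 10 to 30. Own-choice phases use
# the 11-value grid (step 2); guessing phases use the 21-value grid (step 1).

#' Gamble-value grids used by the task
#'
#' @param response_type `"own"` for own-choice phases (11 values, step 2) or
#'   `"guess"` for norm-guessing phases (21 values, step 1).
#' @return Integer vector of gamble values.
#' @examples
#' value_grid("own")   # 10, 12, ..., 30
#' value_grid("guess") # 10, 11, ..., 30
#' @export
value_grid <- function(response_type = c("own", "guess")) {
  response_type <- match.arg(response_type)
  if (response_type == "own") seq(10L, 30L, by = 2L) else seq(10L, 30L, by = 1L)
}

#' Phase definitions of the two-session design
#'
#' The day-0 session has three phases: `baseline` (own choices), `learning`
#' (guessing the group's choices with feedback) and `ownD0` (own choices
#' again, the transfer phase). The day-3 session re-tests own choices
#' (`ownD3`) and guesses without feedback (`othersD3`).
#'
#' @return A tibble with one row per phase: `phase`, `session`,
#'   `response_type`, `feedback_enabled`, `n_values`.
#' @export
phase_definitions <- function() {
  tibble::tibble(
    phase = phase_levels(),
    session = c("D0", "D0", "D0", "D3", "D3"),
    response_type = c("own", "guess", "own", "own", "guess"),
    feedback_enabled = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    n_values = c(11L, 21L, 11L, 11L, 21L)
  )
}

phase_info <- function(phase) {
  defs <- phase_definitions()
  if (!phase %in% defs$phase) {
    stop(sprintf("Unknown phase `%s`; expected one of: %s.",
                 phase, paste(defs$phase, collapse = ", ")), call. = FALSE)
  }
  as.list(defs[defs$phase == phase, ])
}

#' Build the randomized trial schedule of one phase
#'
#' Enumerates every gamble value of the phase's grid `repeats` times and
#' applies a seeded uniform permutation (no blocking), so two calls with the
#' same seed give identical trial orders.
#'
#' @param phase One of `"baseline"`, `"learning"`, `"ownD0"`, `"ownD3"`,
#'   `"othersD3"`.
#' @param frame `"gain"` or `"loss"`.
#' @param domain `"moral"` (lives) or `"monetary"` (money).
#' @param repeats Number of repetitions per scenario (default 4, as in the
#'   task: 11 x 4 = 44 own-choice trials, 21 x 4 = 84 guessing trials).
#' @param seed Integer seed controlling the trial permutation.
#' @return A tibble with one row per trial: `trial_index`, `repeat_index`
#'   (occurrence number of that gamble value so far), `gamble_value`,
#'   `certain_value` (10), `gamble_prob` (0.5), `frame`, `domain`, `phase`,
#'   `session`, `response_type`, `feedback_enabled`.
#' @examples
#' nrow(build_phase_schedule("baseline", "gain", "moral", seed = 1)) # 44
#' nrow(build_phase_schedule("learning", "loss", "monetary", seed = 1)) # 84
#' @export
build_phase_schedule <- function(phase, frame, domain, repeats = 4L, seed = 1L) {
  info <- phase_info(phase)
  assert_choice(frame, "frame", frame_levels())
  assert_choice(domain, "domain", domain_levels())
  assert_scalar_number(repeats, "repeats", lower = 1)
  assert_scalar_number(seed, "seed")
  repeats <- as.integer(repeats)

  values <- rep(value_grid(info$response_type), times = repeats)
  ord <- withr::with_seed(as.integer(seed), sample.int(length(values)))
  values <- values[ord]

  tibble::tibble(
    trial_index = seq_along(values),
    gamble_value = values,
    repeat_index = stats::ave(values, values, FUN = seq_along),
    certain_value = 10L,
    gamble_prob = 0.5,
    frame = frame,
    domain = domain,
    phase = phase,
    session = info$session,
    response_type = info$response_type,
    feedback_enabled = info$feedback_enabled
  )[, c("trial_index", "repeat_index", "gamble_value", "certain_value",
        "gamble_prob", "frame", "domain", "phase", "session",
        "response_type", "feedback_enabled")]
}

#' Signed expected value of a scenario option
#'
#' Gains count positive and losses negative, so the gamble's signed expected
#' value is `s * 0.5 * gamble_value` and the certain option's is `s * 10`
#' with `s = +1` (gain) or `-1` (loss). The two options have equal expected
#' value at `gamble_value = 20` in both frames.
#'
#' @param gamble_value Gamble magnitude(s) in `[10, 30]`.
#' @param frame `"gain"` or `"loss"` (recycled against `gamble_value`).
#' @param option `"gamble"` or `"certain"`.
#' @return Numeric vector of signed expected values.
#' @examples
#' expected_value(20, "gain", "gamble")   # +10, equal to the certain +10
#' expected_value(20, "loss", "certain")  # -10
#' @export
expected_value <- function(gamble_value, frame, option = c("gamble", "certain")) {
  option <- match.arg(option)
  if (any(gamble_value < 10 | gamble_value > 30)) {
    stop("`gamble_value` must lie in [10, 30].", call. = FALSE)
  }
  if (!all(frame %in% frame_levels())) {
    stop("`frame` must be 'gain' or 'loss'.", call. = FALSE)
  }
  s <- ifelse(frame == "gain", 1, -1)
  if (option == "gamble") s * 0.5 * gamble_value else s * 10
}
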