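# Group-norm feedback schedules for the learning phase.
#
# The "majority" the participant guesses about is synthetic: its per-value
# probability of choosing the gamble is a pilot gambling-rate curve shifted
# by a fixed offset to be systematically more risk-averse (fewer gambles)
# or more risk-seeking (more gambles), then clipped so feedback stays
# probabilistic.

#' Default pilot gambling-rate curves
#'
#' Package-default stand-ins for the pilot study's average gambling rates.
#' Because a pilot sample is drawn from the same population as the
#' participants, the defaults are the logistic curves fitted to the
#' population-average baseline behaviour of the default agent priors:
#' in the gain frame the gambling rate rises with the gamble value
#' (`plogis(0.15 * (v - 24))`, risk aversion at equal expected value) and
#' in the loss frame it falls (`plogis(-0.18 * (v - 24))`, relative risk
#' seeking). The same curves are used for both domains, as the default
#' priors carry no domain effect. These are package defaults for
#' simulation, not empirical pilot values.
#'
#' @param frame `"gain"` or `"loss"`.
#' @param domain `"moral"` or `"monetary"` (same default curve; kept so
#'   user-supplied pilot curves can differ by domain).
#' @return A tibble with columns `gamble_value` (10..30) and `rate`.
#' @export
default_pilot_rates <- function(frame = c("gain", "loss"),
                                domain = c("moral", "monetary")) {
  frame <- match.arg(frame)
  domain <- match.arg(domain)
  v <- value_grid("guess")
  rate <- if (frame == "gain") {
    stats::plogis(0.15 * (v - 24))
  } else {
    stats::plogis(-0.18 * (v - 24))
  }
  tibble::tibble(gamble_value = v, rate = rate)
}

#' Construct a norm feedback schedule from pilot gambling rates
#'
#' Shifts the pilot curve by `offset` toward fewer gambles (`risk_averse`)
#' or more gambles (`risk_seeking`), then clips every probability into
#' `clip` so the realized majority stays probabilistic.
#'
#' @param pilot_rates Tibble/data frame with columns `gamble_value` and
#'   `rate`, covering the full guessing grid 10..30 with rates in `[0, 1]`.
#' @param norm_type `"risk_averse"` or `"risk_seeking"`.
#' @param offset Probability shift magnitude (default 0.20).
#' @param clip Length-2 numeric bounds inside (0, 1) (default `c(0.05, 0.95)`).
#' @return An object of class `norm_schedule`: a tibble with columns
#'   `gamble_value` and `p_majority_gamble`, with attributes `norm_type`,
#'   `offset` and `clip`.
#' @examples
#' pilot <- default_pilot_rates("loss", "monetary")
#' sched <- build_norm_schedule(pilot, "risk_seeking")
#' @export
build_norm_schedule <- function(pilot_rates, norm_type, offset = 0.20,
                                clip = c(0.05, 0.95)) {
  assert_choice(norm_type, "norm_type", norm_levels())
  assert_scalar_number(offset, "offset", lower = 0, upper = 1)
  if (length(clip) != 2L || any(!is.finite(clip)) || clip[1] < 0 ||
      clip[2] > 1 || clip[1] > clip[2]) {
    stop("`clip` must be two ordered probabilities in [0, 1].", call. = FALSE)
  }
  if (!all(c("gamble_value", "rate") %in% names(pilot_rates))) {
    stop("`pilot_rates` needs columns `gamble_value` and `rate`.", call. = FALSE)
  }
  grid <- value_grid("guess")
  missing <- setdiff(grid, pilot_rates$gamble_value)
  if (length(missing) > 0) {
    stop(sprintf("Pilot curve is missing gamble values: %s.",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (any(pilot_rates$rate < 0 | pilot_rates$rate > 1)) {
    stop("Pilot rates must lie in [0, 1].", call. = FALSE)
  }
  pilot <- pilot_rates$rate[match(grid, pilot_rates$gamble_value)]
  shift <- if (norm_type == "risk_seeking") offset else -offset
  p <- pmin(pmax(pilot + shift, clip[1]), clip[2])
  out <- tibble::tibble(gamble_value = grid, p_majority_gamble = p)
  structure(out, class = c("norm_schedule", class(out)),
            norm_type = norm_type, offset = offset, clip = clip)
}

norm_schedule_prob <- function(schedule, gamble_value) {
  idx <- match(gamble_value, schedule$gamble_value)
  if (anyNA(idx)) {
    stop(sprintf("Gamble value(s) off the schedule grid: %s.",
                 paste(unique(gamble_value[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  schedule$p_majority_gamble[idx]
}

#' Sample the majority's choice for one or more trials
#'
#' Bernoulli draw(s) from the schedule's per-value probability that the
#' majority chose the gamble. Uses the ambient RNG stream; seed with
#' [set.seed()] or [withr::with_seed()] for reproducibility.
#'
#' @param schedule A `norm_schedule`.
#' @param gamble_value Gamble value(s) on the schedule grid.
#' @return Character vector in `c("gamble", "certain")`.
#' @export
sample_majority_choice <- function(schedule, gamble_value) {
  p <- norm_schedule_prob(schedule, gamble_value)
  ifelse(stats::runif(length(p)) < p, "gamble", "certain")
}

#' Feedback for a guess about the majority's choice
#'
#' @param guess,majority_choice Character vectors in `c("gamble", "certain")`.
#' @return `"correct"` where they agree, `"incorrect"` otherwise.
#' @export
feedback_for_guess <- function(guess, majority_choice) {
  ok <- all(guess %in% response_levels()) && all(majority_choice %in% response_levels())
  if (!ok) stop("Guesses and majority choices must be 'gamble' or 'certain'.",
                call. = FALSE)
  ifelse(guess == majority_choice, "correct", "incorrect")
}

#' Write / read a norm schedule as CSV
#'
#' The file is a two-column CSV (`gamble_value`, `p_majority_gamble`)
#' preceded by `#`-comment metadata lines recording the norm type, offset
#' and clip bounds.
#'
#' @param schedule A `norm_schedule`.
#' @param path File path.
#' @return `write_norm_schedule()` returns `path` invisibly;
#'   `read_norm_schedule()` returns a `norm_schedule`.
#' @export
write_norm_schedule <- function(schedule, path) {
  meta <- c(
    sprintf("# norm_type: %s", attr(schedule, "norm_type")),
    sprintf("# offset: %s", format(attr(schedule, "offset"))),
    sprintf("# clip: %s %s", format(attr(schedule, "clip")[1]),
            format(attr(schedule, "clip")[2]))
  )
  writeLines(c(meta, "gamble_value,p_majority_gamble",
               paste(schedule$gamble_value,
                     format(schedule$p_majority_gamble, digits = 15),
                     sep = ",")),
             path)
  invisible(path)
}

#' @rdname write_norm_schedule
#' @export
read_norm_schedule <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (length(hit) == 0) return(NULL)
    trimws(sub(paste0("^# ", key, ":"), "", hit[1]))
  }
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  out <- tibble::as_tibble(body)
  clip <- as.numeric(strsplit(get_meta("clip") %||% "0.05 0.95", "\\s+")[[1]])
  structure(out, class = c("norm_schedule", class(out)),
            norm_type = get_meta("norm_type"),
            offset = as.numeric(get_meta("offset") %||% NA_real_),
            clip = clip)
}
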