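# Binary-entropy analysis of choice consistency: repeated identical
# scenarios let us score how often a participant alternates between the
# two options; entropy 0 means perfectly consistent, 1 means coin-flip.

#' Binary entropy of a gamble probability
#'
#' `H(p) = -p * log2(p) - (1 - p) * log2(1 - p)` with the convention
#' `0 * log2(0) = 0`. Valued in `[0, 1]`; 0 iff `p` is 0 or 1, maximal (1)
#' at `p = 0.5`, and symmetric: `H(p) = H(1 - p)`.
#'
#' @param p Probability vector in `[0, 1]` (`NA` passed through).
#' @return Entropy values in `[0, 1]`.
#' @examples
#' binary_entropy(c(0, 0.25, 0.5)) # 0, 0.811..., 1
#' @export
binary_entropy <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("`p` must lie in [0, 1].", call. = FALSE)
  }
  term <- function(q) ifelse(q == 0, 0, -q * log2(q))
  term(p) + term(1 - p)
}

# Paired Wilcoxon signed-rank on differences: zeros dropped, exact
# distribution for n <= 25 without ties, otherwise normal approximation
# with continuity correction.
paired_wilcoxon <- function(d) {
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, n = 0L,
                method = "degenerate (all differences zero)"))
  }
  ties <- any(duplicated(abs(d)))
  use_exact <- n <= 25 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = use_exact, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value, n = n,
       method = if (use_exact) "exact signed rank" else
         "normal approximation with continuity correction")
}

#' Compare choice uncertainty (entropy) between two phases
#'
#' Fits the binary entropy function to each participant's per-scenario
#' gamble probabilities (fraction of gamble choices over the repeats of an
#' identical scenario) in two phases, averages within participant, and
#' compares phases with a two-sided paired Wilcoxon signed-rank test
#' (zero differences dropped; exact for n <= 25 without ties, otherwise
#' normal approximation with continuity correction). A scenario-level
#' pairing (participant x scenario) is also computed and reported.
#'
#' @param trials Long trial tibble containing both phases.
#' @param phase_a,phase_b Phases to compare (defaults `"baseline"` vs
#'   `"ownD0"`, i.e. before vs after norm exposure).
#' @return A list of class `entropy_summary`: `per_scenario` (participant x
#'   phase x gamble value `p_gamble` and `entropy`), `per_participant`
#'   (phase-mean entropies and their difference a - b), `test`
#'   (participant-level Wilcoxon), `scenario_test` (scenario-level
#'   Wilcoxon), `degenerate` flag.
#' @export
entropy_phase_comparison <- function(trials, phase_a = "baseline",
                                     phase_b = "ownD0") {
  for (ph in c(phase_a, phase_b)) {
    if (!ph %in% trials$phase) {
      stop(sprintf("Phase `%s` is absent from the data.", ph), call. = FALSE)
    }
  }
  d <- trials[trials$phase %in% c(phase_a, phase_b), ]
  grids <- tapply(d$gamble_value, d$phase, function(v) sort(unique(v)))
  if (!identical(unname(grids[[phase_a]]), unname(grids[[phase_b]]))) {
    stop("The two phases use different scenario grids.", call. = FALSE)
  }

  per_scenario <- d |>
    dplyr::group_by(.data$participant_id, .data$phase, .data$gamble_value) |>
    dplyr::summarise(n_rep = dplyr::n(),
                     p_gamble = mean(.data$response == "gamble"),
                     .groups = "drop")
  if (any(per_scenario$n_rep < 2)) {
    stop("Entropy needs at least 2 repeats of every scenario.", call. = FALSE)
  }
  per_scenario$entropy <- binary_entropy(per_scenario$p_gamble)

  per_participant <- per_scenario |>
    dplyr::group_by(.data$participant_id, .data$phase) |>
    dplyr::summarise(mean_entropy = mean(.data$entropy), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "phase", values_from = "mean_entropy") |>
    dplyr::rename(entropy_a = dplyr::all_of(phase_a),
                  entropy_b = dplyr::all_of(phase_b)) |>
    dplyr::mutate(diff = .data$entropy_a - .data$entropy_b)

  test <- paired_wilcoxon(per_participant$diff)

  scen_wide <- per_scenario |>
    dplyr::select("participant_id", "phase", "gamble_value", "entropy") |>
    tidyr::pivot_wider(names_from = "phase", values_from = "entropy")
  scenario_test <- paired_wilcoxon(scen_wide[[phase_a]] - scen_wide[[phase_b]])

  structure(list(
    phase_a = phase_a, phase_b = phase_b,
    per_scenario = per_scenario,
    per_participant = per_participant,
    test = test,
    scenario_test = scenario_test,
    degenerate = test$n == 0L
  ), class = "entropy_summary")
}

#' @export
print.entropy_summary <- function(x, ...) {
  cat(sprintf("Entropy comparison %s vs %s: %d participants\n",
              x$phase_a, x$phase_b, nrow(x$per_participant)))
  cat(sprintf("  mean entropy: %.3f vs %.3f\n",
              mean(x$per_participant$entropy_a),
              mean(x$per_participant$entropy_b)))
  if (x$degenerate) {
    cat("  test degenerate: all paired differences are zero\n")
  } else {
    cat(sprintf("  Wilcoxon signed rank (%s): V = %.1f, p = %.3g, n = %d\n",
                x$test$method, x$test$statistic, x$test$p_value, x$test$n))
  }
  invisible(x)
}
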