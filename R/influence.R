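# Conformity-influence metrics: per-value and marginal differences in
# gamble probability between a post-exposure phase and baseline, their
# persistence at day 3, the alignment of peak influence with maximal
# choice uncertainty, and the awareness-conformity correlation.

#' Norm-influence curve for one condition
#'
#' The amount of influence is the difference in gamble probability between
#' a post-exposure phase and baseline, per gamble value and marginalized
#' over the value grid. With a `mixed_logit_fit` the differences are
#' model-based marginal probabilities (random intercept integrated out)
#' with CIs from parametric simulation of the coefficients; with raw trial
#' data they are observed proportions with t-based CIs over participants.
#'
#' @param x A `mixed_logit_fit` or a long trial tibble.
#' @param condition Named list fixing the non-phase factors, e.g.
#'   `list(frame = "gain", norm_type = "risk_averse")` (plus `domain` when
#'   modelled).
#' @param phase_pair Length-2 character: the comparison phase and the
#'   reference phase, default `c("ownD0", "baseline")`.
#' @param n_draws Parametric draws for model-based CIs (default 2000).
#' @param level Confidence level.
#' @param seed Seed for the draws.
#' @return An `influence_estimate`: `per_value` (tibble of `gamble_value`,
#'   `delta`, `ci_low`, `ci_high`), `marginal_delta` with `ci_low`/`ci_high`,
#'   `abs_magnitude`, `condition`, `phase_pair`, `method`.
#' @export
influence_curve <- function(x, condition, phase_pair = c("ownD0", "baseline"),
                            n_draws = 2000, level = 0.95, seed = 1L) {
  stopifnot(length(phase_pair) == 2L)
  if (inherits(x, "mixed_logit_fit")) {
    influence_model(x, condition, phase_pair, n_draws, level, seed)
  } else if (is.data.frame(x)) {
    influence_raw(x, condition, phase_pair, level)
  } else {
    stop("`x` must be a mixed_logit_fit or a trial data frame.", call. = FALSE)
  }
}

influence_model <- function(fit, condition, phase_pair, n_draws, level, seed) {
  values <- value_grid("own")
  cells <- lapply(phase_pair, function(ph) {
    c(condition, list(phase = ph, gamble_value = values))
  })
  Xa <- cell_model_matrix(fit, cells[[1]])
  Xb <- cell_model_matrix(fit, cells[[2]])
  gh <- gh_normal(15)
  p_point <- function(X) { # per-value population-averaged probabilities
    eta <- drop(X %*% fit$coef)
    out <- 0
    for (k in seq_along(gh$z)) {
      out <- out + gh$w[k] * stats::plogis(eta + fit$re_sd * gh$z[k])
    }
    out
  }
  delta <- p_point(Xa) - p_point(Xb)

  draws <- withr::with_seed(as.integer(seed), {
    MASS::mvrnorm(n_draws, fit$coef, fit$vcov)
  })
  p_draws <- function(X) { # values x draws matrix of averaged probabilities
    eta <- X %*% t(draws)
    out <- 0
    for (k in seq_along(gh$z)) {
      out <- out + gh$w[k] * stats::plogis(eta + fit$re_sd * gh$z[k])
    }
    out
  }
  dmat <- p_draws(Xa) - p_draws(Xb)
  lo <- (1 - level) / 2
  per_value_ci <- t(apply(dmat, 1, stats::quantile, probs = c(lo, 1 - lo)))
  marg_draws <- colMeans(dmat)
  marg_ci <- stats::quantile(marg_draws, c(lo, 1 - lo), names = FALSE)

  new_influence(
    per_value = tibble::tibble(gamble_value = values, delta = delta,
                               ci_low = per_value_ci[, 1],
                               ci_high = per_value_ci[, 2]),
    marginal_delta = mean(delta), ci = marg_ci,
    condition = condition, phase_pair = phase_pair, method = "model",
    n = fit$n_subjects
  )
}

influence_raw <- function(trials, condition, phase_pair, level) {
  d <- trials
  for (v in names(condition)) {
    if (v %in% names(d)) d <- d[d[[v]] == condition[[v]], ]
  }
  for (ph in phase_pair) {
    if (!ph %in% d$phase) {
      stop(sprintf("Phase `%s` is absent for this condition.", ph),
           call. = FALSE)
    }
  }
  d <- d[d$phase %in% phase_pair, ]
  pp <- d |>
    dplyr::group_by(.data$participant_id, .data$phase, .data$gamble_value) |>
    dplyr::summarise(p = mean(.data$response == "gamble"), .groups = "drop")

  per_value <- pp |>
    tidyr::pivot_wider(names_from = "phase", values_from = "p") |>
    dplyr::group_by(.data$gamble_value) |>
    dplyr::summarise(
      delta = mean(.data[[phase_pair[1]]] - .data[[phase_pair[2]]]),
      se = stats::sd(.data[[phase_pair[1]]] - .data[[phase_pair[2]]]) /
        sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop")
  qt <- stats::qt(1 - (1 - level) / 2, pmax(per_value$n - 1, 1))
  per_value$ci_low <- per_value$delta - qt * per_value$se
  per_value$ci_high <- per_value$delta + qt * per_value$se

  marg <- pp |>
    dplyr::group_by(.data$participant_id, .data$phase) |>
    dplyr::summarise(p = mean(.data$p), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "phase", values_from = "p") |>
    dplyr::mutate(delta = .data[[phase_pair[1]]] - .data[[phase_pair[2]]])
  m <- mean(marg$delta)
  se <- stats::sd(marg$delta) / sqrt(nrow(marg))
  q <- stats::qt(1 - (1 - level) / 2, max(nrow(marg) - 1, 1))

  new_influence(
    per_value = per_value[, c("gamble_value", "delta", "ci_low", "ci_high")],
    marginal_delta = m, ci = c(m - q * se, m + q * se),
    condition = condition, phase_pair = phase_pair, method = "raw",
    n = nrow(marg)
  )
}

new_influence <- function(per_value, marginal_delta, ci, condition,
                          phase_pair, method, n) {
  structure(list(
    condition = condition, phase_pair = phase_pair,
    per_value = per_value,
    marginal_delta = marginal_delta,
    ci_low = ci[1], ci_high = ci[2],
    abs_magnitude = abs(marginal_delta),
    method = method, n = n
  ), class = "influence_estimate")
}

#' @export
print.influence_estimate <- function(x, ...) {
  cond <- paste(sprintf("%s=%s", names(x$condition),
                        unlist(x$condition)), collapse = ", ")
  cat(sprintf("Norm influence (%s vs %s; %s; %s-based, n = %d)\n",
              x$phase_pair[1], x$phase_pair[2], cond, x$method, x$n))
  cat(sprintf("  marginal delta p(gamble) = %+.3f [%.3f, %.3f]\n",
              x$marginal_delta, x$ci_low, x$ci_high))
  invisible(x)
}

#' Persistence of the conformity effect at day 3
#'
#' The influence curve of the day-3 own choices relative to the day-0
#' baseline ([influence_curve()] with `phase_pair = c("ownD3", "baseline")`).
#'
#' @inheritParams influence_curve
#' @return An `influence_estimate`.
#' @export
persistence <- function(x, condition, n_draws = 2000, level = 0.95,
                        seed = 1L) {
  influence_curve(x, condition, phase_pair = c("ownD3", "baseline"),
                  n_draws = n_draws, level = level, seed = seed)
}

#' Alignment of peak influence with maximal baseline uncertainty
#'
#' Locates the gamble value with the largest absolute influence and the
#' value where the baseline gamble-probability curve crosses 0.5 (the most
#' uncertain choice), by linear interpolation on the value grid, and
#' reports their distance in gamble-value units.
#'
#' @param influence An `influence_estimate`.
#' @param baseline_curve Tibble with `gamble_value` and `p` (baseline
#'   gamble probabilities on the same grid).
#' @return List with `peak_value`, `crossing_value`, `distance`,
#'   `crossing_defined`, `multiple_crossings`.
#' @export
peak_influence_alignment <- function(influence, baseline_curve) {
  pv <- influence$per_value
  peak_value <- pv$gamble_value[which.max(abs(pv$delta))]

  v <- baseline_curve$gamble_value
  p <- baseline_curve$p
  ord <- order(v)
  v <- v[ord]; p <- p[ord]
  f <- p - 0.5
  crossings <- numeric(0)
  for (i in seq_len(length(v) - 1)) {
    if (f[i] == 0) crossings <- c(crossings, v[i])
    if (f[i] * f[i + 1] < 0) {
      crossings <- c(crossings,
                     v[i] + (v[i + 1] - v[i]) * (-f[i]) / (f[i + 1] - f[i]))
    }
  }
  if (f[length(f)] == 0) crossings <- c(crossings, v[length(v)])
  crossings <- unique(crossings)

  if (length(crossings) == 0) {
    return(list(peak_value = peak_value, crossing_value = NA_real_,
                distance = NA_real_, crossing_defined = FALSE,
                multiple_crossings = FALSE))
  }
  crossing <- crossings[which.min(abs(crossings - peak_value))]
  list(peak_value = peak_value, crossing_value = crossing,
       distance = abs(peak_value - crossing), crossing_defined = TRUE,
       multiple_crossings = length(crossings) > 1)
}

#' Per-participant conformity score
#'
#' Signed mean change in gamble probability in the direction of the
#' participant's assigned norm: the participant-mean gamble rate in the
#' comparison phase minus baseline, negated for the risk-averse norm so
#' that positive always means "moved toward the assigned norm".
#'
#' @param trials Long trial tibble (must include `norm_type`).
#' @param phase_pair Comparison and reference phase, default
#'   `c("ownD0", "baseline")`.
#' @return Tibble with `participant_id`, `norm_type`, `conformity`.
#' @export
participant_conformity <- function(trials, phase_pair = c("ownD0", "baseline")) {
  d <- trials[trials$phase %in% phase_pair, ]
  out <- d |>
    dplyr::group_by(.data$participant_id, .data$norm_type, .data$phase) |>
    dplyr::summarise(p = mean(.data$response == "gamble"), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "phase", values_from = "p") |>
    dplyr::mutate(
      delta = .data[[phase_pair[1]]] - .data[[phase_pair[2]]],
      conformity = ifelse(.data$norm_type == "risk_seeking",
                          .data$delta, -.data$delta))
  out[, c("participant_id", "norm_type", "conformity")]
}

#' Awareness-conformity correlation
#'
#' Pearson correlation between self-reported awareness of the norm
#' influence (0-100) and the per-participant conformity score, with
#' `df = n - 2` and a two-sided p-value from the t transform.
#'
#' @param awareness Numeric vector of awareness scores.
#' @param conformity Numeric vector of conformity scores, same order.
#' @return List with `r`, `df`, `p`.
#' @export
awareness_conformity_correlation <- function(awareness, conformity) {
  if (length(awareness) != length(conformity)) {
    stop("`awareness` and `conformity` must have equal length.", call. = FALSE)
  }
  keep <- is.finite(awareness) & is.finite(conformity)
  a <- awareness[keep]; c_ <- conformity[keep]
  n <- length(a)
  if (n < 3) stop("Need at least 3 complete pairs.", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(c_) == 0) {
    stop("Zero variance in awareness or conformity.", call. = FALSE)
  }
  r <- stats::cor(a, c_)
  df <- n - 2L
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * stats::pt(-abs(t), df))
}
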