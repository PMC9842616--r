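# Generative agent model: Prospect-Theory value function, softmax choice
# rule, and the conformity mixture that moves post-learning choice
# probabilities toward the group norm.

#' Prospect-Theory value of an outcome magnitude
#'
#' Canonical power value function: `x^alpha` for gains and `-lam * x^alpha`
#' for losses, with `v(0) = 0`. `alpha < 1` gives diminishing sensitivity to
#' larger amounts (concave gains / convex losses); `lam > 1` gives loss
#' aversion.
#'
#' @param magnitude Non-negative outcome magnitude(s).
#' @param frame `"gain"` or `"loss"` (recycled).
#' @param alpha Curvature exponent, `> 0`.
#' @param lam Loss-aversion multiplier, `> 0` (default 1).
#' @return Numeric utilities (signed).
#' @examples
#' pt_utility(25, "gain", alpha = 0.5)          # 5
#' pt_utility(16, "loss", alpha = 0.5, lam = 2) # -8
#' @export
pt_utility <- function(magnitude, frame, alpha, lam = 1) {
  assert_scalar_number(alpha, "alpha")
  assert_scalar_number(lam, "lam")
  if (alpha <= 0 || lam <= 0) {
    stop("`alpha` and `lam` must be strictly positive.", call. = FALSE)
  }
  if (any(magnitude < 0)) stop("`magnitude` must be >= 0.", call. = FALSE)
  if (!all(frame %in% frame_levels())) {
    stop("`frame` must be 'gain' or 'loss'.", call. = FALSE)
  }
  n <- max(length(magnitude), length(frame))
  u <- rep_len(magnitude, n)^alpha
  sgn <- ifelse(rep_len(frame, n) == "gain", 1, -lam)
  sgn * u
}

#' Construct (and validate) agent preference parameters
#'
#' @param alpha PT curvature exponent (> 0).
#' @param lam Loss-aversion multiplier (> 0).
#' @param tau Choice temperature (inverse noise), `>= 0`; `tau = 0` is pure
#'   bias-driven responding.
#' @param beta0 Latent gamble bias (real); positive values favour the gamble
#'   regardless of utilities.
#' @param w_norm Conformity weight in `[0, 1]`: the mixture weight given to
#'   the norm schedule after learning.
#' @param persist Day-3 retention fraction in `[0, 1]` applied to `w_norm`.
#' @return A named list of class `agent_params`.
#' @export
agent_params <- function(alpha, lam = 1, tau = 1, beta0 = 0,
                         w_norm = 0, persist = 1) {
  assert_scalar_number(alpha, "alpha")
  assert_scalar_number(lam, "lam")
  assert_scalar_number(tau, "tau", lower = 0)
  assert_scalar_number(beta0, "beta0")
  assert_scalar_number(w_norm, "w_norm", lower = 0, upper = 1)
  assert_scalar_number(persist, "persist", lower = 0, upper = 1)
  if (alpha <= 0 || lam <= 0) {
    stop("`alpha` and `lam` must be strictly positive.", call. = FALSE)
  }
  structure(list(alpha = alpha, lam = lam, tau = tau, beta0 = beta0,
                 w_norm = w_norm, persist = persist),
            class = "agent_params")
}

#' Probability of choosing the gamble before any norm influence
#'
#' Softmax (logistic) choice rule on the Prospect-Theory utility difference:
#' `p = logistic(tau * (0.5 * v(gamble_value) - v(10)) + beta0 + norm_shift)`
#' where `v` carries the frame's sign, so in losses larger gambles become
#' less attractive.
#'
#' @param gamble_value Gamble magnitude(s) in `[10, 30]`.
#' @param frame `"gain"` or `"loss"`.
#' @param params An [agent_params()] object (or named list with `alpha`,
#'   `lam`, `tau`, `beta0`).
#' @param norm_shift Additive latent-scale offset (0 before learning).
#' @return Probabilities of choosing the gamble.
#' @examples
#' p <- choice_prob(20, "gain", agent_params(alpha = 0.5, tau = 1))
#' round(p, 4) # 0.2837: concavity implies risk aversion at equal EV
#' @export
choice_prob <- function(gamble_value, frame, params, norm_shift = 0) {
  u_gamble <- pt_utility(gamble_value, frame, params$alpha, params$lam)
  u_certain <- pt_utility(10, frame, params$alpha, params$lam)
  stats::plogis(params$tau * (0.5 * u_gamble - u_certain) +
                  params$beta0 + norm_shift)
}

#' Post-learning choice probability under the conformity mixture
#'
#' After observing the group's choices, the agent's gamble probability is a
#' convex mixture of its own baseline probability and the norm schedule:
#' `p = (1 - w) * p_own + w * p_norm(gamble_value)`, with `w = w_norm` on
#' day 0 and `w = w_norm * persist` on day 3. The mixture form mirrors the
#' behavioural outcome measure (a difference in gamble probability) and
#' keeps `w` identifiable.
#'
#' @param params An [agent_params()] object.
#' @param schedule A [build_norm_schedule()] result.
#' @param gamble_value Value(s) on the schedule grid.
#' @param frame `"gain"` or `"loss"`.
#' @param session `"D0"` or `"D3"`.
#' @return Shifted probabilities of choosing the gamble; always between
#'   `p_own` and `p_norm`.
#' @export
conformity_shift <- function(params, schedule, gamble_value, frame,
                             session = c("D0", "D3")) {
  session <- match.arg(session)
  p_own <- choice_prob(gamble_value, frame, params)
  p_norm <- norm_schedule_prob(schedule, gamble_value)
  w <- if (session == "D0") params$w_norm else params$w_norm * params$persist
  (1 - w) * p_own + w * p_norm
}

#' Default priors over agent parameters
#'
#' Sampling functions for each [agent_params()] field, used by
#' [simulate_cohort()]: `alpha ~ U(0.4, 1.1)`, `lam ~ LogNormal(log 1.5,
#' 0.3)`, `tau ~ Gamma(shape 2, scale 0.5)`, `beta0 ~ N(0, 0.3)`,
#' `w_norm ~ Beta(2, 2)`, `persist ~ Beta(5, 2)`. These are package
#' defaults chosen to reproduce qualitative baseline behaviour (risk
#' aversion in gains, relative risk seeking in losses, heterogeneous
#' conformity with partial day-3 retention), not empirical estimates.
#'
#' Individual entries can be overridden, e.g. with a degenerate prior
#' `function(n) rep(0, n)` to switch conformity off.
#'
#' @param ... Named replacement sampling functions, each `function(n)`.
#' @return Named list of sampling functions.
#' @examples
#' priors <- default_param_priors(w_norm = function(n) rep(0.5, n))
#' @export
default_param_priors <- function(...) {
  priors <- list(
    alpha = function(n) stats::runif(n, 0.4, 1.1),
    lam = function(n) stats::rlnorm(n, log(1.5), 0.3),
    tau = function(n) stats::rgamma(n, shape = 2, scale = 0.5),
    beta0 = function(n) stats::rnorm(n, 0, 0.3),
    w_norm = function(n) stats::rbeta(n, 2, 2),
    persist = function(n) stats::rbeta(n, 5, 2)
  )
  override <- list(...)
  bad <- setdiff(names(override), names(priors))
  if (length(bad) > 0) {
    stop(sprintf("Unknown prior field(s): %s.", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  priors[names(override)] <- override
  priors
}

#' Draw agent parameters from priors
#'
#' @param n Number of agents.
#' @param priors Named list of sampling functions as in
#'   [default_param_priors()]; all six fields must be present.
#' @return A tibble with one row per agent and columns `alpha`, `lam`,
#'   `tau`, `beta0`, `w_norm`, `persist`.
#' @export
draw_agent_params <- function(n, priors = default_param_priors()) {
  fields <- c("alpha", "lam", "tau", "beta0", "w_norm", "persist")
  missing <- setdiff(fields, names(priors))
  if (length(missing) > 0) {
    stop(sprintf("Priors missing for: %s.", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  draws <- lapply(fields, function(f) {
    x <- priors[[f]](n)
    if (!is.numeric(x) || length(x) != n || anyNA(x)) {
      stop(sprintf("Prior for `%s` must return %d finite values.", f, n),
           call. = FALSE)
    }
    x
  })
  names(draws) <- fields
  out <- tibble::as_tibble(draws)
  rng <- list(alpha = c(1e-8, Inf), lam = c(1e-8, Inf), tau = c(0, Inf),
              beta0 = c(-Inf, Inf), w_norm = c(0, 1), persist = c(0, 1))
  for (f in fields) {
    if (any(out[[f]] < rng[[f]][1] | out[[f]] > rng[[f]][2])) {
      stop(sprintf("Prior draws for `%s` violate its admissible range.", f),
           call. = FALSE)
    }
  }
  out
}
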