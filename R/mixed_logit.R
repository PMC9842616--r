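# Random-intercept mixed-effects logit of gamble choices, marginal gamble
# probabilities averaged over the random-effect distribution, and
# multiplicity-adjusted contrasts between design cells.

#' Gauss-Hermite rule for a standard normal integral
#'
#' Nodes and weights such that `sum(w * f(z))` approximates
#' `E[f(Z)]`, `Z ~ N(0, 1)`.
#'
#' @param nodes Number of quadrature nodes (default 15).
#' @return List with `z` (nodes) and `w` (weights summing to 1).
#' @keywords internal
gh_normal <- function(nodes = 15) {
  gh <- pracma::gaussHermite(nodes)
  list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

# Model data: gamble value centred at the equal-EV point (20) and scaled by
# 10, factors with explicit level order, 0/1 response.
build_model_data <- function(trials) {
  need <- c("participant_id", "phase", "frame", "norm_type", "gamble_value",
            "response")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) {
    stop(sprintf("Trial data missing columns: %s.", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  d <- tibble::tibble(
    participant_id = factor(trials$participant_id),
    resp = as.integer(trials$response == "gamble"),
    gv_c = (trials$gamble_value - 20) / 10,
    phase = factor(trials$phase, levels = intersect(phase_levels(),
                                                    unique(trials$phase))),
    frame = factor(trials$frame, levels = intersect(frame_levels(),
                                                    unique(trials$frame))),
    norm_type = factor(trials$norm_type, levels = intersect(norm_levels(),
                                                            unique(trials$norm_type)))
  )
  if ("domain" %in% names(trials)) {
    d$domain <- factor(trials$domain, levels = intersect(domain_levels(),
                                                         unique(trials$domain)))
  }
  d
}

# Full phase x norm x frame (x domain) interaction plus frame-specific
# gamble-value slopes, dropping factors with a single observed level.
default_fixed_formula <- function(data) {
  multi <- function(v) v %in% names(data) && nlevels(data[[v]]) > 1
  value_part <- if (multi("frame")) "gv_c * frame" else "gv_c"
  cond_vars <- Filter(multi, c("phase", "norm_type", "frame", "domain"))
  rhs <- paste(c(value_part,
                 if (length(cond_vars) > 0) paste(cond_vars, collapse = " * ")),
               collapse = " + ")
  stats::as.formula(paste("resp ~", rhs))
}

new_fit <- function(engine, model, fixed_formula, data, coef, vcov, re_sd,
                    loglik, messages = character(0)) {
  used <- intersect(all.vars(fixed_formula), names(data))
  xlevels <- lapply(Filter(is.factor, data[setdiff(used, "participant_id")]),
                    levels)
  structure(list(
    engine = engine, model = model, fixed_formula = fixed_formula,
    coef = coef, vcov = vcov, re_sd = re_sd, loglik = loglik,
    n_obs = nrow(data), n_subjects = nlevels(data$participant_id),
    xlevels = xlevels, messages = messages
  ), class = "mixed_logit_fit")
}

check_model_inputs <- function(data) {
  if (nlevels(data$participant_id) < 2L) {
    stop("Need at least 2 subjects.", call. = FALSE)
  }
  if (length(unique(data$resp)) < 2L) {
    stop("Responses are all identical; the model is not estimable.",
         call. = FALSE)
  }
}

check_separation <- function(coef) {
  if (any(abs(coef) > 15)) {
    warning(sprintf(
      "Possible separation: coefficient(s) %s exceed |15| on the logit scale.",
      paste(names(coef)[abs(coef) > 15], collapse = ", ")), call. = FALSE)
  }
}

#' Fit the random-intercept mixed logit to trial data
#'
#' Logistic regression of gamble choices with a subject-level random
#' intercept integrated out of the likelihood by adaptive Gauss-Hermite
#' quadrature (`nAGQ` nodes, default 15). The default fixed-effect
#' structure is the full phase x norm x frame (x domain) interaction plus
#' frame-specific gamble-value slopes, with the gamble value centred at the
#' equal-expected-value point (20) and scaled by 10. Learning-phase
#' (feedback) trials are excluded by default: the model is about own
#' choices and day-3 guesses.
#'
#' @param trials Long trial tibble (see [read_trials()] for the schema).
#' @param formula Optional fixed-effects formula on the columns `resp`,
#'   `gv_c`, `phase`, `norm_type`, `frame`, `domain`; the random intercept
#'   is added internally.
#' @param nagq Number of adaptive quadrature nodes (>= 1; default 15).
#' @param include_learning Keep learning-phase trials? Default `FALSE`.
#' @return A `mixed_logit_fit`: fixed-effect `coef`, their `vcov` (observed
#'   information), random-intercept `re_sd`, `loglik`, `n_obs`,
#'   `n_subjects`, plus the underlying `model` object.
#' @export
fit_mixed_logit <- function(trials, formula = NULL, nagq = 15,
                            include_learning = FALSE) {
  if (!include_learning && "phase" %in% names(trials)) {
    trials <- trials[trials$phase != "learning", ]
  }
  data <- build_model_data(trials)
  check_model_inputs(data)
  fixed <- formula %||% default_fixed_formula(data)
  full <- stats::update(fixed, . ~ . + (1 | participant_id))

  msgs <- character(0)
  model <- withCallingHandlers(
    lme4::glmer(full, data = data, family = stats::binomial(),
                nAGQ = as.integer(nagq),
                control = lme4::glmerControl(
                  optimizer = "bobyqa",
                  optCtrl = list(maxfun = 1e5))),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  coef <- lme4::fixef(model)
  vcov <- as.matrix(stats::vcov(model))
  re_sd <- sqrt(unname(unlist(lme4::VarCorr(model)))[1])
  check_separation(coef)
  if (any(grepl("failed to converge", msgs))) {
    warning(paste("Mixed logit convergence diagnostics:",
                  paste(unique(msgs), collapse = "; ")), call. = FALSE)
  }
  new_fit("glmer", model, fixed, data, coef, vcov, re_sd,
          as.numeric(stats::logLik(model)), msgs)
}

#' Fit the pooled (no random effect) logit
#'
#' Ordinary logistic regression with the same fixed-effect structure as
#' [fit_mixed_logit()]. Serves as the exact special case of the mixed model
#' at `re_sd = 0` and as a fast engine for large simulation studies.
#'
#' @inheritParams fit_mixed_logit
#' @return A `mixed_logit_fit` with `re_sd = 0` and `engine = "glm"`.
#' @export
fit_pooled_logit <- function(trials, formula = NULL, include_learning = FALSE) {
  if (!include_learning && "phase" %in% names(trials)) {
    trials <- trials[trials$phase != "learning", ]
  }
  data <- build_model_data(trials)
  check_model_inputs(data)
  fixed <- formula %||% default_fixed_formula(data)
  model <- stats::glm(fixed, data = data, family = stats::binomial())
  coef <- stats::coef(model)
  check_separation(coef)
  new_fit("glm", model, fixed, data, coef, as.matrix(stats::vcov(model)),
          0, as.numeric(stats::logLik(model)))
}

#' @export
print.mixed_logit_fit <- function(x, ...) {
  cat(sprintf("%s logit fit: %d obs, %d subjects, re_sd = %.3f, logLik = %.2f\n",
              if (x$engine == "glmer") "Random-intercept" else "Pooled",
              x$n_obs, x$n_subjects, x$re_sd, x$loglik))
  print(round(x$coef, 4))
  invisible(x)
}

#' Tidy coefficient table of a fit
#'
#' @param fit A `mixed_logit_fit`.
#' @param level Confidence level (default 0.95).
#' @return Tibble with `term`, `estimate`, `se`, `ci_low`, `ci_high`, `p`
#'   (Wald).
#' @export
tidy_fit <- function(fit, level = 0.95) {
  se <- sqrt(diag(fit$vcov))
  z <- fit$coef / se
  q <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    term = names(fit$coef), estimate = unname(fit$coef), se = unname(se),
    ci_low = unname(fit$coef - q * se), ci_high = unname(fit$coef + q * se),
    p = unname(2 * stats::pnorm(-abs(z)))
  )
}

# newdata rows for one design cell: the cell's factor levels crossed with
# the phase-appropriate gamble-value grid.
cell_newdata <- function(fit, cell) {
  if (is.null(cell$phase) && "phase" %in% names(fit$xlevels)) {
    stop("`cell` must name a phase.", call. = FALSE)
  }
  for (v in intersect(names(fit$xlevels), names(cell))) {
    if (!cell[[v]] %in% fit$xlevels[[v]]) {
      stop(sprintf("Cannot extrapolate: level `%s` of `%s` was not in the fitted data.",
                   cell[[v]], v), call. = FALSE)
    }
  }
  unset <- setdiff(names(fit$xlevels), names(cell))
  if (length(unset) > 0) {
    stop(sprintf("`cell` must fix: %s.", paste(unset, collapse = ", ")),
         call. = FALSE)
  }
  values <- cell$gamble_value %||% {
    ph <- cell$phase %||% "baseline"
    value_grid(phase_info(ph)$response_type)
  }
  nd <- tibble::tibble(gv_c = (values - 20) / 10)
  for (v in names(fit$xlevels)) {
    nd[[v]] <- factor(cell[[v]], levels = fit$xlevels[[v]])
  }
  nd
}

cell_model_matrix <- function(fit, cell) {
  nd <- cell_newdata(fit, cell)
  stats::model.matrix(stats::delete.response(stats::terms(fit$fixed_formula)),
                      data = nd)
}

# Population-averaged gamble probability for linear predictors `eta`
# (rows) under random-intercept sd `re_sd`; `eta` may be a matrix with one
# column per coefficient draw.
average_over_re <- function(eta, re_sd, gh) {
  if (re_sd == 0) {
    out <- stats::plogis(eta)
  } else {
    out <- 0
    for (k in seq_along(gh$z)) {
      out <- out + gh$w[k] * stats::plogis(eta + re_sd * gh$z[k])
    }
  }
  if (is.matrix(out)) colMeans(out) else mean(out)
}

#' Marginal probability of gambling in a design cell
#'
#' Model-implied probability of choosing the gamble in one condition x
#' phase cell, averaged over the estimated random-intercept distribution
#' (Gauss-Hermite average of the inverse logit) and over the cell's
#' gamble-value grid. The confidence interval is obtained by parametric
#' simulation from the fitted coefficients' joint normal.
#'
#' @param fit A `mixed_logit_fit`.
#' @param cell Named list fixing every factor in the model, e.g.
#'   `list(phase = "baseline", norm_type = "risk_averse", frame = "gain")`;
#'   optionally a `gamble_value` vector to average over (defaults to the
#'   phase's grid).
#' @param nodes Quadrature nodes for the random-intercept average.
#' @param n_draws Coefficient draws for the CI (default 2000).
#' @param level Confidence level.
#' @param seed Seed for the draws.
#' @return Tibble with `M`, `ci_low`, `ci_high`.
#' @export
marginal_gamble_prob <- function(fit, cell, nodes = 15, n_draws = 2000,
                                 level = 0.95, seed = 1L) {
  X <- cell_model_matrix(fit, cell)
  gh <- gh_normal(nodes)
  M <- average_over_re(drop(X %*% fit$coef), fit$re_sd, gh)
  draws <- withr::with_seed(as.integer(seed), {
    MASS::mvrnorm(n_draws, fit$coef, fit$vcov)
  })
  Ms <- average_over_re(X %*% t(draws), fit$re_sd, gh)
  qs <- stats::quantile(Ms, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  tibble::tibble(M = M, ci_low = qs[1], ci_high = qs[2])
}

#' Multiplicity-adjusted contrasts of marginal gamble probabilities
#'
#' Each contrast is a probability-scale difference `M(A) - M(B)` between
#' two design cells. The family is adjusted jointly by a single-step
#' max-|z| procedure: the null distribution of the maximum absolute
#' standardized contrast is obtained by Monte-Carlo sampling from the
#' estimates' joint normal with the fit's covariance, which also yields
#' simultaneous confidence intervals.
#'
#' @param fit A `mixed_logit_fit`.
#' @param contrasts Named list; each element is `list(a = cellA, b = cellB)`
#'   with cells as in [marginal_gamble_prob()].
#' @param n_draws Monte-Carlo draws (default 4000).
#' @param nodes Quadrature nodes.
#' @param level Simultaneous confidence level.
#' @param seed Seed for the draws.
#' @return Tibble with one row per contrast: `contrast`, `estimate`,
#'   `ci_low`, `ci_high`, `statistic` (z), `p_adjusted`.
#' @export
contrast_cells <- function(fit, contrasts, n_draws = 4000, nodes = 15,
                           level = 0.95, seed = 1L) {
  if (is.null(names(contrasts)) || any(names(contrasts) == "")) {
    names(contrasts) <- paste0("c", seq_along(contrasts))
  }
  ev <- tryCatch(min(eigen(fit$vcov, symmetric = TRUE,
                           only.values = TRUE)$values),
                 error = function(e) NA_real_)
  if (!is.finite(ev) || ev < -1e-8 * max(abs(fit$vcov))) {
    stop("Covariance of the estimates is singular or indefinite; contrasts are unavailable.",
         call. = FALSE)
  }
  gh <- gh_normal(nodes)
  Xa <- lapply(contrasts, function(ct) cell_model_matrix(fit, ct$a))
  Xb <- lapply(contrasts, function(ct) cell_model_matrix(fit, ct$b))

  est <- vapply(seq_along(contrasts), function(k) {
    average_over_re(drop(Xa[[k]] %*% fit$coef), fit$re_sd, gh) -
      average_over_re(drop(Xb[[k]] %*% fit$coef), fit$re_sd, gh)
  }, numeric(1))

  draws <- withr::with_seed(as.integer(seed), {
    MASS::mvrnorm(n_draws, fit$coef, fit$vcov)
  })
  cd <- vapply(seq_along(contrasts), function(k) {
    average_over_re(Xa[[k]] %*% t(draws), fit$re_sd, gh) -
      average_over_re(Xb[[k]] %*% t(draws), fit$re_sd, gh)
  }, numeric(n_draws))
  cd <- matrix(cd, nrow = n_draws)

  se <- apply(cd, 2, stats::sd)
  zero <- se < 1e-12
  z <- ifelse(zero, 0, est / se)
  zd <- sweep(cd, 2, colMeans(cd), `-`)
  zd <- sweep(zd, 2, ifelse(zero, 1, se), `/`)
  max_abs <- apply(abs(zd), 1, max)
  p_adj <- vapply(abs(z), function(zk) {
    (1 + sum(max_abs >= zk)) / (1 + n_draws)
  }, numeric(1))
  q <- stats::quantile(max_abs, level, names = FALSE)

  tibble::tibble(
    contrast = names(contrasts),
    estimate = est,
    ci_low = est - q * se,
    ci_high = est + q * se,
    statistic = z,
    p_adjusted = pmin(p_adj, 1)
  )
}
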