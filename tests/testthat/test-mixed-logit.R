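# direct generative sampler for the mixed logit (independent of the
# cohort machinery): eta = b0 + b1 * gv_c + subject intercept
simulate_logit_data <- function(n_subj, n_trials, b0, b1, re_sd, seed) {
  withr::with_seed(seed, {
    u <- rnorm(n_subj, 0, re_sd)
    d <- tidyr::expand_grid(subj = seq_len(n_subj), t = seq_len(n_trials))
    d$gamble_value <- sample(value_grid("own"), nrow(d), replace = TRUE)
    eta <- b0 + b1 * (d$gamble_value - 20) / 10 + u[d$subj]
    tibble::tibble(
      participant_id = sprintf("s%03d", d$subj),
      phase = "baseline", frame = "gain", norm_type = "risk_averse",
      gamble_value = d$gamble_value,
      response = ifelse(runif(nrow(d)) < plogis(eta), "gamble", "certain")
    )
  })
}

test_that("without subject heterogeneity the mixed fit matches pooled logit", {
  sim <- simulate_cohort(12, design = moral_design(),
                         param_priors = degenerate_priors(),
                         seed = 55, phases = c("baseline", "ownD0"))
  mixed <- fit_mixed_logit(sim$trials)
  pooled <- fit_pooled_logit(sim$trials)
  expect_lt(mixed$re_sd, 0.05)
  expect_lt(max(abs(mixed$coef - pooled$coef)), 1e-3)
})

test_that("estimates are stable in the number of quadrature nodes", {
  sim <- tiny_cohort()
  d0 <- sim$trials[sim$trials$phase %in% c("baseline", "ownD0"), ]
  f15 <- fit_mixed_logit(d0, nagq = 15)
  f31 <- fit_mixed_logit(d0, nagq = 31)
  expect_gt(f15$re_sd, 0.1) # heterogeneous agents induce a real intercept sd
  expect_lt(max(abs(f15$coef - f31$coef)), 1e-4)
  expect_lt(abs(f15$re_sd - f31$re_sd), 1e-4)
})

test_that("an intercept-only fit on balanced data is centred at zero", {
  balanced <- tibble::tibble(
    participant_id = rep(sprintf("s%02d", 1:6), each = 40),
    phase = "baseline", frame = "gain", norm_type = "risk_averse",
    gamble_value = rep(20L, 240),
    response = rep(c("gamble", "certain"), 120)
  )
  fit <- fit_mixed_logit(balanced, formula = resp ~ 1)
  expect_lt(abs(fit$coef[["(Intercept)"]]), 1e-3)
  M <- marginal_gamble_prob(fit, list(phase = "baseline", frame = "gain",
                                      norm_type = "risk_averse"))
  expect_equal(M$M, 0.5, tolerance = 1e-3)
  expect_true(M$ci_low <= M$M && M$M <= M$ci_high)
})

test_that("the fitted model improves on the intercept-only model", {
  sim <- signed_cohort()
  d0 <- sim$trials[sim$trials$phase %in% c("baseline", "ownD0") &
                     sim$trials$frame == "gain", ]
  full <- fit_pooled_logit(d0)
  null <- fit_pooled_logit(d0, formula = resp ~ 1)
  expect_gte(full$loglik, null$loglik)
})

test_that("confidence intervals have close to nominal coverage", {
  hits <- 0L
  n_rep <- 25L
  for (r in seq_len(n_rep)) {
    d <- simulate_logit_data(40, 88, b0 = 0.3, b1 = 0.9, re_sd = 1,
                             seed = 1000 + r)
    fit <- fit_mixed_logit(d, formula = resp ~ gv_c)
    ci <- tidy_fit(fit)
    row <- ci[ci$term == "gv_c", ]
    hits <- hits + (row$ci_low <= 0.9 && 0.9 <= row$ci_high)
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("marginal probabilities recover a known cell probability", {
  d <- withr::with_seed(77, tibble::tibble(
    participant_id = rep(sprintf("s%02d", 1:30), each = 88),
    phase = "baseline", frame = "gain", norm_type = "risk_averse",
    gamble_value = sample(value_grid("own"), 2640, replace = TRUE),
    response = ifelse(runif(2640) < 0.3, "gamble", "certain")
  ))
  fit <- fit_pooled_logit(d, formula = resp ~ 1)
  M <- marginal_gamble_prob(fit, list(phase = "baseline", frame = "gain",
                                      norm_type = "risk_averse"))
  expect_lt(abs(M$M - 0.3), 0.02)
})

test_that("marginal probabilities are invariant to reparameterization", {
  sim <- signed_cohort()
  d0 <- sim$trials[sim$trials$phase %in% c("baseline", "ownD0"), ]
  f1 <- fit_pooled_logit(d0)
  f2 <- fit_pooled_logit(d0, formula = resp ~ phase * norm_type * frame +
                           gv_c * frame)
  cell <- list(phase = "ownD0", frame = "loss", norm_type = "risk_seeking")
  expect_equal(marginal_gamble_prob(f1, cell)$M,
               marginal_gamble_prob(f2, cell)$M, tolerance = 1e-8)
})

test_that("unseen cells and degenerate inputs are rejected", {
  sim <- signed_cohort()
  d0 <- sim$trials[sim$trials$phase %in% c("baseline", "ownD0"), ]
  fit <- fit_pooled_logit(d0)
  expect_error(marginal_gamble_prob(fit, list(phase = "ownD3", frame = "gain",
                                              norm_type = "risk_averse")),
               "extrapolate")
  expect_error(marginal_gamble_prob(fit, list(phase = "ownD0")), "must fix")
  all_same <- d0
  all_same$response <- "certain"
  expect_error(fit_mixed_logit(all_same), "identical")
  one_subj <- d0[d0$participant_id == d0$participant_id[1], ]
  expect_error(fit_mixed_logit(one_subj), "2 subjects")
})

test_that("a contrast of a cell with itself is null", {
  sim <- signed_cohort()
  d0 <- sim$trials[sim$trials$phase %in% c("baseline", "ownD0"), ]
  fit <- fit_pooled_logit(d0)
  cell <- list(phase = "baseline", frame = "gain", norm_type = "risk_averse")
  res <- contrast_cells(fit, list(self = list(a = cell, b = cell)))
  expect_equal(res$estimate, 0)
  expect_gt(res$p_adjusted, 0.99)

  # and a real conformity contrast is detected with the right sign
  fam <- list(
    shift = list(a = list(phase = "ownD0", frame = "gain",
                          norm_type = "risk_seeking"),
                 b = list(phase = "baseline", frame = "gain",
                          norm_type = "risk_seeking")))
  res2 <- contrast_cells(fit, fam)
  expect_gt(res2$estimate, 0)
  expect_lt(res2$p_adjusted, 0.05)
  expect_true(res2$ci_low <= res2$estimate & res2$estimate <= res2$ci_high)
})
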