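test_that("influence deltas are antisymmetric in the phase pair", {
  sim <- signed_cohort()
  cond <- list(frame = "loss", norm_type = "risk_averse")
  fwd <- influence_curve(sim$trials, cond)
  rev <- influence_curve(sim$trials, cond,
                         phase_pair = c("baseline", "ownD0"))
  expect_equal(fwd$per_value$delta, -rev$per_value$delta)
  expect_equal(fwd$marginal_delta, -rev$marginal_delta)
  expect_equal(fwd$abs_magnitude, abs(fwd$marginal_delta))
  expect_error(influence_curve(sim$trials, cond,
                               phase_pair = c("othersD3", "baseline")),
               "absent")
})

test_that("influence sign follows the assigned norm", {
  sim <- signed_cohort()
  for (nt in c("risk_averse", "risk_seeking")) {
    for (fr in c("gain", "loss")) {
      ic <- influence_curve(sim$trials, list(frame = fr, norm_type = nt))
      if (nt == "risk_averse") expect_lt(ic$marginal_delta, 0)
      else expect_gt(ic$marginal_delta, 0)
    }
  }
})

test_that("model-based and raw influence agree on a simulated cohort", {
  sim <- signed_cohort()
  d0 <- sim$trials[sim$trials$phase %in% c("baseline", "ownD0"), ]
  fit <- fit_pooled_logit(d0)
  for (cond in list(list(frame = "gain", norm_type = "risk_seeking"),
                    list(frame = "loss", norm_type = "risk_averse"))) {
    m <- influence_curve(fit, cond, seed = 5)
    r <- influence_curve(sim$trials, cond)
    expect_lt(abs(m$marginal_delta - r$marginal_delta),
              (r$ci_high - r$ci_low) / 2)
    expect_true(m$ci_low <= m$marginal_delta &
                  m$marginal_delta <= m$ci_high)
  }
})

test_that("full retention preserves the day-0 effect; zero retention erases it", {
  keep <- simulate_cohort(40, design = moral_design(),
                          param_priors = degenerate_priors(persist = 1),
                          seed = 71, phases = c("baseline", "ownD0", "ownD3"))
  gone <- simulate_cohort(40, design = moral_design(),
                          param_priors = degenerate_priors(persist = 0),
                          seed = 72, phases = c("baseline", "ownD0", "ownD3"))
  cond <- list(frame = "loss", norm_type = "risk_averse")
  d0 <- influence_curve(keep$trials, cond)
  d3_keep <- persistence(keep$trials, cond)
  expect_lt(abs(d3_keep$marginal_delta - d0$marginal_delta),
            (d0$ci_high - d0$ci_low) / 2 + (d3_keep$ci_high - d3_keep$ci_low) / 2)
  d3_gone <- persistence(gone$trials, cond)
  expect_lt(abs(d3_gone$marginal_delta), 0.05)
  expect_gt(abs(d3_keep$marginal_delta), abs(d3_gone$marginal_delta))
})

test_that("peak influence aligns with the baseline 0.5 crossing", {
  # constructed curves: peak and crossing both at 20
  infl <- riskconform:::new_influence(
    per_value = tibble::tibble(gamble_value = value_grid("own"),
                               delta = -dnorm(value_grid("own"), 20, 4),
                               ci_low = NA, ci_high = NA),
    marginal_delta = -0.1, ci = c(-0.15, -0.05),
    condition = list(), phase_pair = c("ownD0", "baseline"),
    method = "raw", n = 10)
  base <- tibble::tibble(gamble_value = value_grid("own"),
                         p = plogis(0.4 * (value_grid("own") - 20)))
  al <- peak_influence_alignment(infl, base)
  expect_equal(al$peak_value, 20L)
  expect_equal(al$crossing_value, 20)
  expect_equal(al$distance, 0)
  expect_true(al$crossing_defined)

  flat <- tibble::tibble(gamble_value = value_grid("own"), p = 0.9)
  al2 <- peak_influence_alignment(infl, flat)
  expect_false(al2$crossing_defined)
  expect_true(is.na(al2$distance))

  # generative mixture: the model-based influence curve peaks near the
  # values where the baseline curve passes 0.5 (maximal uncertainty)
  dists <- unlist(lapply(c(91, 92), function(s) {
    sim <- simulate_cohort(
      60, design = moral_design(),
      param_priors = default_param_priors(w_norm = function(n) rep(0.5, n)),
      seed = s, phases = c("baseline", "ownD0"))
    fit <- fit_pooled_logit(sim$trials)
    sapply(seq_len(4), function(i) {
      cond <- as.list(moral_design()[i, c("frame", "norm_type")])
      ic <- influence_curve(fit, cond, n_draws = 200)
      base_curve <- riskconform:::model_phase_curve(
        fit, c(cond, list(phase = "baseline")))
      peak_influence_alignment(ic, base_curve)$distance
    })
  }))
  expect_lte(mean(dists), 4)
})

test_that("awareness correlates with conformity as constructed", {
  conf <- seq(-0.2, 0.3, length.out = 50)
  exact <- awareness_conformity_correlation(10 + 100 * conf, conf)
  expect_equal(exact$r, 1)
  expect_equal(exact$df, 48L)
  expect_lt(exact$p, 1e-10)

  # independently shuffled pairings are null
  withr::with_seed(21, {
    aw <- runif(360, 0, 100)
    cf <- rnorm(360, 0, 0.1)
    rs <- replicate(40, awareness_conformity_correlation(sample(aw), cf)$r)
    expect_gte(mean(abs(rs) < 0.15), 0.95)
  })
  expect_error(awareness_conformity_correlation(rep(1, 10), rnorm(10)),
               "variance")
  expect_error(awareness_conformity_correlation(1:2, 1:2), "3")
})

test_that("generator defaults produce a positive awareness-conformity link", {
  rs <- sapply(c(1, 2, 3, 4), function(s) {
    sim <- simulate_cohort(30, seed = s, phases = c("baseline", "ownD0"))
    conf <- participant_conformity(sim$trials)
    aw <- sim$agents$awareness[match(conf$participant_id,
                                     sim$agents$participant_id)]
    awareness_conformity_correlation(aw, conf$conformity)$r
  })
  expect_true(all(rs > 0))
})
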