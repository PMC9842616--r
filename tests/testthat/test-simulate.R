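test_that("agents learn the majority's preferences from feedback", {
  pars <- agent_params(alpha = 0.7, lam = 1.5, tau = 1, beta0 = 0,
                       w_norm = 0.5)
  flat95 <- build_norm_schedule(
    tibble::tibble(gamble_value = 10:30, rate = 0.95), "risk_seeking",
    offset = 0)
  # many concatenated learning phases ~ long-run behaviour
  long <- dplyr::bind_rows(lapply(1:30, function(i) {
    build_phase_schedule("learning", "gain", "moral", seed = i)
  }))
  withr::with_seed(9, {
    sim <- simulate_guess_learning(pars, flat95, long, "gain")
    late <- sim$trials$feedback[-seq_len(500)]
    expect_gt(mean(late == "correct"), 0.8)
    expect_gt(sim$accuracy, 0.5) # above chance overall

    # deterministic majority (clip disabled): accuracy approaches 1
    det <- build_norm_schedule(
      tibble::tibble(gamble_value = 10:30, rate = 1), "risk_seeking",
      offset = 0, clip = c(0, 1))
    sim_det <- simulate_guess_learning(pars, det, long, "gain")
    expect_gt(mean(sim_det$trials$feedback[-seq_len(500)] == "correct"), 0.95)

    # zero learning-rate mode: guesses stay at own preference
    frozen <- simulate_guess_learning(pars, flat95, long, "gain",
                                      learn = FALSE)
    expect_equal(frozen$estimates$p_guess,
                 choice_prob(10:30, "gain", pars))
  })
})

test_that("a simulated cohort has the full two-session trial structure", {
  sim <- tiny_cohort()
  expect_equal(nrow(sim$agents), 16L) # 2 per cell x 8 cells
  expect_equal(nrow(sim$trials), 16L * (44L + 84L + 44L + 44L + 84L))
  counts <- table(sim$trials$phase) / 16L
  expect_equal(as.vector(counts[c("baseline", "learning", "ownD0",
                                  "ownD3", "othersD3")]),
               c(44, 84, 44, 44, 84))
  # per participant and session
  per <- dplyr::count(sim$trials, participant_id, session)
  expect_true(all(per$n[per$session == "D0"] == 172L))
  expect_true(all(per$n[per$session == "D3"] == 128L))
  # feedback only in D0 learning; guesses only in guessing phases
  expect_true(all(sim$trials$feedback[sim$trials$phase != "learning"] == "none"))
  expect_true(all(sim$trials$response_type[sim$trials$phase %in%
                                             c("learning", "othersD3")] == "guess"))
  expect_true(all(c("alpha", "lam", "tau", "beta0", "w_norm", "persist",
                    "awareness") %in% names(sim$agents)))
})

test_that("the generator is a pure function of its seed", {
  a <- simulate_cohort(2, seed = 31, phases = c("baseline", "learning"))
  b <- simulate_cohort(2, seed = 31, phases = c("baseline", "learning"))
  c <- simulate_cohort(2, seed = 32, phases = c("baseline", "learning"))
  expect_identical(a$trials, b$trials)
  expect_identical(a$agents, b$agents)
  expect_false(identical(a$trials$response, c$trials$response))
})

test_that("conformity off means no systematic baseline-to-transfer change", {
  sim <- simulate_cohort(20, design = moral_design(),
                         param_priors = degenerate_priors(w_norm = 0),
                         seed = 77, phases = c("baseline", "ownD0"))
  for (i in seq_len(4)) {
    cond <- as.list(moral_design()[i, c("frame", "norm_type")])
    ic <- influence_curve(sim$trials, cond)
    expect_lt(abs(ic$marginal_delta), 0.06)
  }
})

test_that("baseline behaviour carries the framing signature", {
  # alpha < 1 (diminishing sensitivity) and lam > 1 (loss aversion):
  # risk-averse in gains, risk-seeking in losses
  base_rate <- function(alpha, lam, seed) {
    sim <- simulate_cohort(
      25, design = moral_design(),
      param_priors = degenerate_priors(alpha = alpha, lam = lam, tau = 1,
                                       beta0 = 0, w_norm = 0),
      seed = seed, phases = "baseline")
    sapply(c("gain", "loss"), function(fr) {
      d <- sim$trials[sim$trials$frame == fr, ]
      mean(d$response == "gamble")
    })
  }
  strong <- base_rate(alpha = 0.6, lam = 1.8, seed = 5)
  expect_lt(strong["gain"], 0.5)
  expect_gt(strong["loss"], 0.5)
  weak <- base_rate(alpha = 0.95, lam = 1.05, seed = 5)
  expect_lt(abs(weak["loss"] - weak["gain"]),
            abs(strong["loss"] - strong["gain"]))
})

test_that("injected rule-breakers show up for QC", {
  sim <- simulate_cohort(2, seed = 13, phases = c("baseline", "ownD0"),
                         exclusion_injection = list(n_constant = 2,
                                                    n_failed_comprehension = 3,
                                                    n_failed_attention = 1))
  qc <- apply_exclusions(sim$trials, sim$comprehension_flags,
                         sim$attention_flags)
  expect_equal(qc$report$n_constant_response, 2L)
  expect_equal(qc$report$n_failed_comprehension, 3L)
  expect_equal(qc$report$n_failed_attention, 1L)
})
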