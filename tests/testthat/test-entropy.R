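test_that("binary entropy matches its closed form and symmetry", {
  expect_equal(binary_entropy(0.5), 1)
  expect_equal(binary_entropy(0), 0)
  expect_equal(binary_entropy(1), 0)
  expect_equal(binary_entropy(0.25),
               -(0.25 * log2(0.25)) - (0.75 * log2(0.75))) # 0.811278...
  p <- seq(0, 1, by = 0.01)
  H <- binary_entropy(p)
  expect_true(all(H >= 0 & H <= 1))
  expect_equal(H, rev(H)) # H(p) = H(1 - p)
  expect_equal(p[which.max(H)], 0.5)
  expect_true(all(H[p %in% c(0, 1)] == 0) && all(H[!p %in% c(0, 1)] > 0))
  expect_error(binary_entropy(1.2), "\\[0, 1\\]")
  expect_error(binary_entropy(-0.1), "\\[0, 1\\]")
})

# trial fixture where participant i has `k` scenarios at p = 0.25 in one
# phase and everything else at p = 0.5, giving a known entropy difference
fixture_participant <- function(id, k, positive) {
  grid <- value_grid("own")
  make_phase <- function(phase, n_quarter) {
    resp <- unlist(lapply(seq_along(grid), function(j) {
      if (j <= n_quarter) c("gamble", "certain", "certain", "certain")
      else c("gamble", "certain", "gamble", "certain")
    }))
    tibble::tibble(participant_id = id, phase = phase,
                   gamble_value = rep(grid, each = 4), response = resp)
  }
  # positive difference: baseline more uncertain (all p = .5) than transfer
  if (positive) {
    dplyr::bind_rows(make_phase("baseline", 0), make_phase("ownD0", k))
  } else {
    dplyr::bind_rows(make_phase("baseline", k), make_phase("ownD0", 0))
  }
}

test_that("the entropy comparison matches brute-force signed-rank enumeration", {
  cases <- list(c(6, TRUE), c(2, FALSE), c(5, TRUE), c(3, TRUE),
               c(1, FALSE), c(4, TRUE))
  trials <- dplyr::bind_rows(lapply(seq_along(cases), function(i) {
    fixture_participant(sprintf("p%d", i), cases[[i]][1], as.logical(cases[[i]][2]))
  }))
  res <- entropy_phase_comparison(trials)
  # known per-participant differences: (0.1887/11) * k, signed
  d_expected <- (1 - binary_entropy(0.25)) / 11 *
    sapply(cases, function(s) s[1] * ifelse(s[2], 1, -1))
  expect_equal(sort(res$per_participant$diff), sort(d_expected),
               tolerance = 1e-12)
  oracle <- brute_signed_rank(res$per_participant$diff)
  expect_equal(res$test$statistic, oracle$statistic) # V = 18 here
  expect_equal(res$test$p_value, oracle$p_value, tolerance = 1e-12)
  expect_match(res$test$method, "exact")
})

test_that("identical phases give a degenerate (flagged) comparison", {
  one <- fixture_participant("p1", 3, TRUE)
  base <- one[one$phase == "baseline", ]
  dup <- dplyr::bind_rows(base, transform(base, phase = "ownD0"))
  res <- entropy_phase_comparison(dplyr::bind_rows(
    dup, transform(dup, participant_id = "p2")))
  expect_true(res$degenerate)
  expect_true(is.na(res$test$p_value))
})

test_that("norm exposure reduces choice uncertainty in simulated cohorts", {
  design <- tibble::tibble(frame = "gain", norm_type = "risk_averse",
                           domain = "moral")
  sim <- simulate_cohort(
    100, design = design,
    param_priors = default_param_priors(w_norm = function(n) rep(0.6, n)),
    seed = 404, phases = c("baseline", "ownD0"),
    offset = 0.45) # extreme norm pushes post-learning choices toward 0/1
  res <- entropy_phase_comparison(sim$trials)
  expect_gt(mean(res$per_participant$entropy_a),
            mean(res$per_participant$entropy_b))
  expect_lt(res$test$p_value, 0.05)
  expect_match(res$test$method, "normal approximation")
})

test_that("entropy needs repeated scenarios and matching grids", {
  sim1 <- simulate_cohort(2, design = moral_design(), repeats = 1,
                          seed = 6, phases = c("baseline", "ownD0"))
  expect_error(entropy_phase_comparison(sim1$trials), "2 repeats")
  sim2 <- tiny_cohort()
  expect_error(entropy_phase_comparison(sim2$trials, "baseline", "learning"),
               "different scenario grids")
  expect_error(entropy_phase_comparison(sim2$trials, "baseline", "transfer"),
               "absent")
})
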