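# Synthetic cohort generator: full two-session trial datasets with known
# ground-truth preference parameters, for power analysis and parameter /
# effect recovery testing.

#' Simulate the norm-learning (guessing) phase of one agent
#'
#' The agent's guess probability for each gamble value starts at its own
#' choice probability and moves toward the running empirical majority
#' frequency as feedback accumulates. The estimate is a pseudo-count
#' average: own preference contributes `prior_weight` pseudo-observations,
#' the phase-wide (pooled) majority frequency contributes `pool_weight`,
#' and the per-value observed majority counts enter directly, so sparse
#' per-value evidence is shrunk toward the pooled rate.
#'
#' @param params An [agent_params()] object.
#' @param schedule A [build_norm_schedule()] norm schedule.
#' @param trials Learning-phase trial tibble from [build_phase_schedule()].
#' @param frame `"gain"` or `"loss"`.
#' @param prior_weight Pseudo-count on the agent's own preference (default 2).
#' @param pool_weight Pseudo-count on the pooled majority frequency
#'   (default 4).
#' @param learn If `FALSE`, guesses stay at the agent's own choice
#'   probabilities (zero learning-rate mode).
#' @return A list with `trials` (the input rows plus `response` (the guess),
#'   `majority_choice`, `feedback`), `estimates` (final per-value guess
#'   probabilities over the guessing grid) and `accuracy` (proportion of
#'   correct guesses).
#' @export
simulate_guess_learning <- function(params, schedule, trials, frame,
                                    prior_weight = 2, pool_weight = 4,
                                    learn = TRUE) {
  grid <- schedule$gamble_value
  p_own <- choice_prob(grid, frame, params)
  p_sched <- schedule$p_majority_gamble
  idx <- match(trials$gamble_value, grid)
  if (anyNA(idx)) stop("Learning trials contain values off the schedule grid.",
                       call. = FALSE)

  n <- nrow(trials)
  cnt <- numeric(length(grid))
  sum_g <- numeric(length(grid))
  cnt_pool <- 0
  sum_pool <- 0
  guess <- majority <- character(n)
  u_guess <- stats::runif(n)
  u_maj <- stats::runif(n)

  for (t in seq_len(n)) {
    i <- idx[t]
    q <- if (!learn || cnt_pool == 0) {
      p_own[i]
    } else {
      (prior_weight * p_own[i] + pool_weight * (sum_pool / cnt_pool) + sum_g[i]) /
        (prior_weight + pool_weight + cnt[i])
    }
    guess[t] <- if (u_guess[t] < q) "gamble" else "certain"
    maj_gamble <- u_maj[t] < p_sched[i]
    majority[t] <- if (maj_gamble) "gamble" else "certain"
    if (learn) {
      cnt[i] <- cnt[i] + 1
      sum_g[i] <- sum_g[i] + maj_gamble
      cnt_pool <- cnt_pool + 1
      sum_pool <- sum_pool + maj_gamble
    }
  }

  estimates <- if (!learn || cnt_pool == 0) {
    p_own
  } else {
    (prior_weight * p_own + pool_weight * (sum_pool / cnt_pool) + sum_g) /
      (prior_weight + pool_weight + cnt)
  }
  out <- trials
  out$response <- guess
  out$majority_choice <- majority
  out$feedback <- feedback_for_guess(guess, majority)
  list(trials = out,
       estimates = tibble::tibble(gamble_value = grid, p_guess = estimates),
       accuracy = mean(out$feedback == "correct"))
}

#' Default 2 x 2 x 2 study design
#'
#' @return A tibble crossing frame (gain/loss), norm type
#'   (risk-averse/risk-seeking) and domain (moral/monetary).
#' @export
default_design <- function() {
  tidyr::expand_grid(frame = frame_levels(),
                     norm_type = norm_levels(),
                     domain = domain_levels())
}

simulate_participant <- function(id, params, frame, norm_type, domain,
                                 schedule, repeats, phases, seed) {
  records <- list()
  estimates <- NULL

  for (k in seq_along(phases)) {
    ph <- phases[k]
    ph_seed <- derive_seed(seed, k)
    sched <- build_phase_schedule(ph, frame, domain, repeats = repeats,
                                  seed = ph_seed)
    withr::with_seed(derive_seed(ph_seed, 1), {
      if (ph %in% c("baseline", "ownD0", "ownD3")) {
        p <- if (ph == "baseline") {
          choice_prob(sched$gamble_value, frame, params)
        } else {
          conformity_shift(params, schedule, sched$gamble_value, frame,
                           session = if (ph == "ownD0") "D0" else "D3")
        }
        sched$response <- ifelse(stats::runif(nrow(sched)) < p,
                                 "gamble", "certain")
        sched$feedback <- "none"
      } else if (ph == "learning") {
        sim <- simulate_guess_learning(params, schedule, sched, frame)
        sched <- sim$trials[, setdiff(names(sim$trials), "majority_choice")]
        estimates <- sim$estimates
      } else { # othersD3: guesses from the learned estimates, no feedback
        q <- if (is.null(estimates)) {
          choice_prob(sched$gamble_value, frame, params)
        } else {
          estimates$p_guess[match(sched$gamble_value, estimates$gamble_value)]
        }
        sched$response <- ifelse(stats::runif(nrow(sched)) < q,
                                 "gamble", "certain")
        sched$feedback <- "none"
      }
    })
    records[[k]] <- sched
  }

  out <- dplyr::bind_rows(records)
  out$participant_id <- id
  out$norm_type <- norm_type
  out
}

#' Simulate a full two-session cohort with known ground truth
#'
#' Generates `n_per_cell` participants in every cell of the design (default
#' 2 x 2 x 2: frame x norm type x domain), each with the full phase
#' structure: 44-trial baseline, 84-trial learning with feedback, 44-trial
#' transfer (ownD0) on day 0, and 44-trial own-choice retest plus 84-trial
#' no-feedback guessing on day 3. Agent parameters are drawn from
#' `param_priors`; conformity follows the probability-mixture model of
#' [conformity_shift()]. A self-reported awareness score (0-100) is
#' generated as a noisy monotone function of the realized conformity weight.
#'
#' Optional rule-breakers can be injected for QC testing: constant
#' responders (same answer on every trial) and participants who fail
#' comprehension or attention checks.
#'
#' @param n_per_cell Participants per design cell (>= 1).
#' @param design Tibble of design cells with columns `frame`, `norm_type`,
#'   `domain` (default [default_design()]).
#' @param pilot_rates `NULL` for [default_pilot_rates()], or a function
#'   `(frame, domain)` returning a pilot-rate tibble.
#' @param param_priors Named list of prior sampling functions
#'   ([default_param_priors()]).
#' @param exclusion_injection Optional list with any of `n_constant`,
#'   `n_failed_comprehension`, `n_failed_attention` (counts, default 0).
#' @param seed Master integer seed; every participant and phase uses a
#'   deterministically derived substream.
#' @param repeats Scenario repetitions per phase (default 4).
#' @param phases Character subset of phases to simulate (default all five).
#' @param offset,clip Norm-schedule construction parameters
#'   (see [build_norm_schedule()]).
#' @param awareness_pars List `a`, `b`, `sd` of the awareness link
#'   `100 * plogis(a + b * w_norm + N(0, sd))`; defaults calibrated so the
#'   population awareness-conformity correlation is about 0.2 and the mean
#'   reported awareness sits in the thirties on the 0-100 scale.
#' @return A list of class `cohort_sim`: `trials` (long tibble, one row per
#'   trial), `agents` (true parameters, condition, awareness per
#'   participant), `comprehension_flags` (`participant_id`, `q1`..`q4`
#'   correctness), `attention_flags` (`participant_id`, `passed`),
#'   `schedules` (norm schedule per cell), and `seed`.
#' @examples
#' sim <- simulate_cohort(2, seed = 7)
#' nrow(sim$trials) # 16 participants x (44 + 84 + 44 + 44 + 84) trials
#' @export
simulate_cohort <- function(n_per_cell, design = default_design(),
                            pilot_rates = NULL,
                            param_priors = default_param_priors(),
                            exclusion_injection = NULL,
                            seed = 1L, repeats = 4L,
                            phases = phase_levels(),
                            offset = 0.20, clip = c(0.05, 0.95),
                            awareness_pars = list(a = -2.2, b = 3, sd = 0.8)) {
  assert_scalar_number(n_per_cell, "n_per_cell", lower = 1)
  if (!all(phases %in% phase_levels())) {
    stop("`phases` must be a subset of the five design phases.", call. = FALSE)
  }
  if (!all(c("frame", "norm_type", "domain") %in% names(design))) {
    stop("`design` needs columns frame, norm_type, domain.", call. = FALSE)
  }
  inj <- list(n_constant = 0L, n_failed_comprehension = 0L,
              n_failed_attention = 0L)
  inj[names(exclusion_injection)] <- exclusion_injection
  pilot_fun <- pilot_rates %||% default_pilot_rates

  n_cells <- nrow(design)
  n_total <- n_cells * as.integer(n_per_cell)
  cell_of <- rep(seq_len(n_cells), length.out = n_total)
  ids <- sprintf("p%04d", seq_len(n_total))

  schedules <- lapply(seq_len(n_cells), function(j) {
    build_norm_schedule(pilot_fun(design$frame[j], design$domain[j]),
                        design$norm_type[j], offset = offset, clip = clip)
  })

  agents <- withr::with_seed(derive_seed(seed, 0), {
    draw_agent_params(n_total, param_priors)
  })
  agents <- dplyr::bind_cols(
    tibble::tibble(participant_id = ids),
    design[cell_of, ],
    agents
  )

  trial_list <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    j <- cell_of[i]
    pars <- agent_params(agents$alpha[i], agents$lam[i], agents$tau[i],
                         agents$beta0[i], agents$w_norm[i], agents$persist[i])
    trial_list[[i]] <- simulate_participant(
      ids[i], pars, design$frame[j], design$norm_type[j], design$domain[j],
      schedules[[j]], repeats = repeats, phases = phases,
      seed = derive_seed(seed, c(1, i))
    )
  }
  trials <- dplyr::bind_rows(trial_list)
  col_order <- c("participant_id", "domain", "frame", "norm_type", "session",
                 "phase", "trial_index", "repeat_index", "gamble_value",
                 "certain_value", "gamble_prob", "response", "response_type",
                 "feedback")
  trials <- trials[, col_order]

  # Injected rule-breakers occupy the first participant slots (spread over
  # cells because conditions are assigned round-robin).
  take <- function(from, k) if (k > 0) ids[seq(from, length.out = k)] else character(0)
  const_ids <- take(1, inj$n_constant)
  comp_ids <- take(1 + inj$n_constant, inj$n_failed_comprehension)
  attn_ids <- take(1 + inj$n_constant + inj$n_failed_comprehension,
                   inj$n_failed_attention)
  if (length(attn_ids) > 0 && (1 + inj$n_constant + inj$n_failed_comprehension +
                               inj$n_failed_attention - 1) > n_total) {
    stop("More injected rule-breakers than participants.", call. = FALSE)
  }
  if (length(const_ids) > 0) {
    trials$response[trials$participant_id %in% const_ids] <- "gamble"
  }

  flags <- withr::with_seed(derive_seed(seed, 2), {
    # honest participants get at most one wrong comprehension answer
    one_wrong <- stats::runif(n_total) < 0.15
    wrong_pos <- sample.int(4, n_total, replace = TRUE)
    q <- matrix(TRUE, n_total, 4)
    q[cbind(which(one_wrong), wrong_pos[one_wrong])] <- FALSE
    fail_rows <- match(comp_ids, ids)
    for (r in fail_rows) { # injected failures: exactly two wrong
      q[r, ] <- TRUE
      q[r, sample.int(4, 2)] <- FALSE
    }
    noise <- stats::rnorm(n_total, 0, awareness_pars$sd)
    list(q = q, noise = noise)
  })
  comprehension_flags <- tibble::tibble(
    participant_id = ids,
    q1 = flags$q[, 1], q2 = flags$q[, 2], q3 = flags$q[, 3], q4 = flags$q[, 4]
  )
  attention_flags <- tibble::tibble(
    participant_id = ids,
    passed = !(ids %in% attn_ids)
  )
  agents$awareness <- 100 * stats::plogis(
    awareness_pars$a + awareness_pars$b * agents$w_norm + flags$noise
  )

  structure(list(trials = trials, agents = agents,
                 comprehension_flags = comprehension_flags,
                 attention_flags = attention_flags,
                 schedules = stats::setNames(
                   schedules,
                   apply(design, 1, paste, collapse = ".")),
                 design = design, seed = as.integer(seed)),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d participants, %d trials, %d design cells (seed %d)\n",
              nrow(x$agents), nrow(x$trials), nrow(x$design), x$seed))
  invisible(x)
}
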