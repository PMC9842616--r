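# Independent oracles used by several test files.

# Exact paired signed-rank test by enumerating every sign assignment.
brute_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_null <- as.vector(signs %*% r)
  p <- 2 * min(mean(v_null <= v_obs), mean(v_null >= v_obs))
  list(statistic = v_obs, p_value = min(1, p))
}

# Null trial generator for contrast calibration: gamble-value and frame
# effects only, no phase/norm/condition effect, no subject heterogeneity.
simulate_null_trials <- function(n_per_cell, n_rep_seed) {
  withr::with_seed(n_rep_seed, {
    cells <- tidyr::expand_grid(frame = c("gain", "loss"),
                                norm_type = c("risk_averse", "risk_seeking"))
    subj <- tidyr::expand_grid(cell = seq_len(4), s = seq_len(n_per_cell))
    d <- tidyr::expand_grid(i = seq_len(nrow(subj)),
                            phase = c("baseline", "ownD0"),
                            rep = seq_len(4), gv = value_grid("own"))
    d$frame <- cells$frame[subj$cell[d$i]]
    d$norm_type <- cells$norm_type[subj$cell[d$i]]
    slope <- ifelse(d$frame == "gain", 1.2, -1.2)
    p <- plogis(-0.3 + slope * (d$gv - 20) / 10)
    tibble::tibble(
      participant_id = sprintf("s%03d", d$i),
      phase = d$phase, frame = d$frame, norm_type = d$norm_type,
      gamble_value = d$gv,
      response = ifelse(runif(nrow(d)) < p, "gamble", "certain")
    )
  })
}
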