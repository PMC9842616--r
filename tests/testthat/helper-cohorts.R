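# Shared fixtures, built in code and cached for the test run.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, builder(), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# priors with every parameter pinned (no between-agent heterogeneity)
degenerate_priors <- function(alpha = 0.7, lam = 1.5, tau = 1, beta0 = 0,
                              w_norm = 0.5, persist = 0.8) {
  default_param_priors(
    alpha = function(n) rep(alpha, n),
    lam = function(n) rep(lam, n),
    tau = function(n) rep(tau, n),
    beta0 = function(n) rep(beta0, n),
    w_norm = function(n) rep(w_norm, n),
    persist = function(n) rep(persist, n)
  )
}

moral_design <- function() {
  d <- default_design()
  d[d$domain == "moral", ]
}

# small heterogeneous full-phase cohort used by io/entropy/pipeline tests
tiny_cohort <- function() {
  cached("tiny_cohort", function() simulate_cohort(2, seed = 101))
}

# moderate own-phase cohort with pinned conformity, moral domain only
signed_cohort <- function() {
  cached("signed_cohort", function() {
    simulate_cohort(40, design = moral_design(),
                    param_priors = degenerate_priors(),
                    seed = 202, phases = c("baseline", "ownD0", "ownD3"))
  })
}
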