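---
title: "Models and methods: social conformity in risky choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: social conformity in risky choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`riskconform` simulates and analyses a two-session social-conformity
experiment built on a parametric gamble task: on every trial a participant
chooses between a certain outcome of magnitude 10 (lives or currency
units) and a 50% gamble whose magnitude runs from 10 to 30, under a gain
or a loss frame. Between a baseline and a transfer assessment of their own
choices, participants guess — with trial-by-trial feedback — how a
majority group chose, where the group's behaviour is constructed to be
systematically risk-averse or risk-seeking. Own choices are re-tested
three days later. This vignette documents the generative model, the
estimation machinery, the numerical choices, and what the simulation-based
validation does and does not establish.

## The task

Five phases make up the two sessions. Own-choice phases (baseline,
transfer/`ownD0`, day-3 retest/`ownD3`) present 11 scenarios (gamble
values 10, 12, ..., 30); guessing phases (`learning` with feedback,
`othersD3` without) present 21 scenarios (10, 11, ..., 30). Every scenario
repeats 4 times, giving 44 and 84 trials per phase; the two options have
equal expected value at gamble value 20 in both frames. Trial order is a
seeded uniform permutation with no blocking — the design needs only "a
randomized order", and an unconstrained permutation is the simplest
reproducible choice.

```{r, eval = FALSE}
library(riskconform)
sched <- build_phase_schedule("baseline", "gain", "moral", seed = 1)
table(sched$gamble_value)  # each of the 11 values exactly 4 times
```

## The generative agent

Each simulated participant carries six parameters (`agent_params()`):

* `alpha` (> 0): curvature of the Prospect-Theory power value function
  `v(x) = x^alpha` for gains, `-lam * x^alpha` for losses. `alpha < 1`
  gives diminishing sensitivity, hence risk aversion in gains and risk
  seeking in losses at equal expected value.
* `lam` (> 0): loss aversion; `lam > 1` makes losses loom larger.
* `tau` (>= 0): softmax temperature; `tau = 0` is utility-blind responding.
* `beta0`: a frame-independent bias toward the gamble on the latent scale.
* `w_norm` (in [0, 1]): the conformity weight (below).
* `persist` (in [0, 1]): the fraction of the conformity weight retained at
  the day-3 retest.

Before norm exposure the gamble probability is
`plogis(tau * (0.5 * v(g) - v(10)) + beta0)`. Probability weighting is
deliberately omitted: with the gamble probability fixed at 0.5 throughout
the task a weighting function is not identifiable, so the canonical
power-utility form with a single curvature is used.

Conformity is modelled as a probability mixture
(`conformity_shift()`): after learning, the choice probability is
`(1 - w) * p_own + w * p_norm(g)` with `w = w_norm` on day 0 and
`w_norm * persist` on day 3. The mixture was chosen over a latent-utility
offset because the study's outcome measure *is* a difference in gamble
probability, which makes `w` directly identifiable from that difference
and guarantees post-learning probabilities stay between the participant's
own curve and the norm curve.

Default priors (`default_param_priors()`): `alpha ~ U(0.4, 1.1)`,
`lam ~ LogNormal(log 1.5, 0.3)`, `tau ~ Gamma(2, scale 0.5)`,
`beta0 ~ N(0, 0.3)`, `w_norm ~ Beta(2, 2)`, `persist ~ Beta(5, 2)`. These
are package defaults selected once to reproduce the qualitative baseline
phenomena (risk aversion in gains, relative risk seeking in losses,
heterogeneous conformity, partial three-day retention); they are not
fitted to any dataset.

## Norm schedules and feedback

The "majority" is synthetic: for each gamble value it chooses the gamble
with probability taken from a pilot gambling-rate curve shifted by a fixed
offset of 0.20 — downward for the risk-averse norm, upward for the
risk-seeking norm — then clipped to [0.05, 0.95] so feedback stays
probabilistic (`build_norm_schedule()`). Two wording-level ambiguities in
how such manipulations are usually described were resolved as follows:

* *Direction.* "20% above the group gambling rate" read literally would
  make the risk-averse group gamble more, contradicting what risk
  aversion means. The package takes risk-averse = pilot gambling rate
  minus 0.20 (equivalently, certain-option rate plus 0.20) and
  risk-seeking = plus 0.20.
* *Pilot curves.* A pilot sample comes from the same population as the
  participants, so the default pilot curves are the logistic fits to the
  population-average baseline choice curve implied by the default priors:
  `plogis(0.15 * (v - 24))` in gains and `plogis(-0.18 * (v - 24))` in
  losses, identical across domains (the default priors carry no domain
  effect). An earlier candidate that crossed 0.5 at the equal-EV point in
  losses made the risk-seeking loss norm sit *below* typical agents' own
  behaviour over half the grid — i.e. no manipulation at all in that cell
  — which is why matching the population curve was adopted instead.

During the learning phase the agent's guess probability starts at its own
choice probability and converges to the running empirical majority
frequency via pseudo-count averaging (`simulate_guess_learning()`): the
own preference counts `prior_weight = 2` observations, the pooled
phase-wide majority frequency `pool_weight = 4`, and per-value counts
enter directly, shrinking sparse per-value evidence toward the pooled
rate. The day-3 guessing phase draws from the final learned estimates with
no feedback and no further updating. Note the conformity mixture targets
the *true* schedule, not the learned estimate: learning performance and
own-choice conformity are decoupled in the generator.

## Estimation

**Per-participant Prospect-Theory fits** (`fit_pt_model()`) maximize the
choice likelihood over (`alpha`, `tau`, `beta0`[, `lam`]) with L-BFGS-B on
log/identity transforms, 5 jittered restarts, and box constraints
(`alpha` in [0.2, 2], `tau` in [1e-4, 10], `beta0` in [-3, 3], `lam` in
[0.1, 10]). With a single certain-option anchor the likelihood has a
near-flat ridge — a vanishing `alpha` compensated by an extreme `tau` and
`beta0` yields an almost identical choice curve (numerically it can even
beat the generative truth's likelihood at 1,000 trials) — so the default
adds a weak-prior penalty (`alpha ~ N(0.75, 0.35)`,
`tau ~ Gamma(2, scale 1)`, `beta0 ~ N(0, 0.4)`,
`lam ~ LogNormal(log 1.5, 0.4)`); `regularize = FALSE` gives pure
constrained maximum likelihood. Under the default, simulation at 200
agents x 176 trials gives rank correlations of about 0.85-0.9 between
true and recovered `alpha` and `tau`; point recovery of `tau` remains
coarse (roughly +-0.3 at `tau = 2` with 1,000 trials) because of the
ridge, and `alpha` recovers to about +-0.1. `lam` is fitted only when
both frames are present — from a single frame it is a pure rescaling of
`tau`. Curvature is flagged non-identifiable when the fit fails to beat
the `tau = 0` (bias-only) restriction by a chi-square(2) likelihood-ratio
margin, which catches coin-flip responders.

**The mixed logit** (`fit_mixed_logit()`) is a logistic regression of the
binary gamble choice with a subject-level random intercept integrated out
by adaptive Gauss-Hermite quadrature (15 nodes by default; estimates move
by less than 1e-4 going to 31 nodes). The default fixed-effect structure
is the full phase x norm x frame (x domain) interaction plus
frame-specific gamble-value slopes; the gamble value enters centred at 20
(the equal-EV point) and divided by 10, for stable and interpretable
coefficients. `fit_pooled_logit()` fits the same structure with no random
effect; at zero generative heterogeneity the two agree to better than
1e-3 per coefficient, which is the package's oracle cross-check.

**Marginal gamble probabilities** (`marginal_gamble_prob()`) average the
inverse logit over the estimated random-intercept distribution
(Gauss-Hermite) and over the cell's value grid; intervals come from 2,000
draws of the coefficients from their asymptotic normal (the intercept SD
is held at its estimate — its sampling noise is second-order for these
cell means). **Contrasts** (`contrast_cells()`) are probability-scale
differences between cells; the family is adjusted by a single-step
max-|z| procedure whose reference distribution is simulated from the same
joint normal, giving adjusted p-values and simultaneous intervals. This
replaces a multivariate-t-based single-step adjustment; the two coincide
asymptotically, and the simulated version needs no degrees-of-freedom
heuristic. Under a simulated null (1,000 datasets, four contrasts) the
family-wise error is about 0.05 at nominal 0.05.

## Conformity metrics

`influence_curve()` reports the change in gamble probability between a
post-exposure phase and baseline, per gamble value and marginalized over
the 11-value grid — model-based by default (smooth, with parametric-draw
intervals), or from raw proportions with t-intervals over participants.
`persistence()` is the same contrast against the day-3 own choices.
`peak_influence_alignment()` finds the value of maximal absolute
influence and the value where the baseline curve crosses 0.5 (linear
interpolation; multiple crossings return the one nearest the peak,
flagged), quantifying the "influence is strongest where choices are most
uncertain" phenomenon; with model-based curves the two locations agree to
within about 2 value units in simulation. The raw-proportion peak is much
noisier because mid-grid influence is nearly flat — use the model-based
curve for this metric.

`entropy_phase_comparison()` scores each participant's consistency on
repeated identical scenarios with the binary entropy of the gamble
fraction, averages within participant and phase, and compares phases with
a two-sided paired Wilcoxon signed-rank test: zero differences dropped,
exact distribution for n <= 25 without ties, otherwise the normal
approximation with continuity correction. A scenario-level pairing is
computed alongside, since aggregation level is a genuine analytic choice;
the participant-level test is primary. The per-participant conformity
score used by `awareness_conformity_correlation()` is the norm-signed
mean probability change (positive = moved toward the assigned norm) — a
definition the package fixes explicitly because phase differences alone
are sign-ambiguous across norm conditions. The awareness generator
`100 * plogis(-2.2 + 3 * w_norm + N(0, 0.8))` was calibrated once so the
population awareness-conformity correlation is about 0.2 with mean
reported awareness in the thirties, the order observed in debriefing
self-reports; it was then frozen.

## Quality control

`apply_exclusions()` implements the study's rules: drop participants with
two or more of four comprehension questions wrong, constant responders
(identical response on every own-choice trial of a session; a flag widens
this to guessing trials), and attention-check failures. Comprehension is
modelled abstractly as four correctness booleans. QC is a pure,
idempotent filter and reconciles all counts in an `exclusion_report`.

## Validation scale and limitations

The bundled checks run at desk scale, chosen so the full suite and the
acceptance script each complete comfortably on a single CPU: parameter
recovery at 200 agents x 176 trials; influence-sign recovery over 20
seeds x 8 cells at 64 participants per cell (sized so the weakest cell's
true effect, about 0.07, sits more than four standard errors from zero);
null calibration of the contrast family over 1,000 datasets of 40
participants fitted with the pooled engine (the null generator has no
subject heterogeneity, where the pooled likelihood is exact and hundreds
of times faster than quadrature); interval coverage at 25 replicates.

What passing these checks shows — and what it does not:

* The generator reproduces the qualitative phenomena it encodes: framing
  signature at baseline, norm-signed influence with partial day-3
  retention, an awareness-conformity correlation of the right order, and
  peak influence at maximal uncertainty. It does **not** emulate domain
  differences in baseline risk attitudes (the default priors are
  domain-blind), dropout between sessions, reaction times, or
  individually tailored norms.
* The probability-mixture conformity model reduces repeated-choice
  entropy only where the norm reinforces and extremizes the dominant
  tendency (e.g. a strong risk-averse norm in gains, the configuration
  the entropy checks use). Where a norm opposes near-deterministic
  individual preferences, the mixture pulls probabilities toward 0.5 and
  entropy *rises* — so an across-the-board entropy reduction in real
  data is evidence about the uncertainty-resolution mechanism that this
  generator does not encode.
* Degenerate inputs are handled explicitly rather than silently:
  coin-flip responders are flagged non-identifiable, all-identical
  responses abort the model fits, all-zero paired differences mark the
  Wilcoxon as degenerate, and a baseline curve that never crosses 0.5
  flags the alignment metric as undefined.

## Reproducibility

Every stochastic routine takes or derives an explicit seed; cohorts give
each participant and phase a deterministically derived substream, so a
cohort is byte-identical across runs of the same master seed and
unchanged participants keep their data when others are added.
`run_pipeline()` executes simulate - QC - fit - metrics from one YAML
config and writes a bundle whose manifest records the seed, package
version, config echo and data hashes.
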