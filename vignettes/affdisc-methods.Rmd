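---
title: "Models and design choices in affdisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in affdisc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`affdisc` implements a complete analysis pattern for two-group
intertemporal-choice (IC) experiments that separate an *immediate*
condition (smaller-sooner option available today) from a *non-immediate*
condition (everything shifted 15 days out).  This vignette documents the
models, the tunable parameters, what the synthetic cohorts do and do not
emulate, and the choices made where the design was genuinely open.

## Task logic

The staircase titrates the SS amount by bisection.  The state is an
interval `[lower, upper]` with the probe at its midpoint from the second
trial on; an LL choice raises `lower` to the probe, an SS choice lowers
`upper`, and the block terminates when `upper − lower ≤ stop_width`
(default CNY 5, read as "no more than five").  Starting from the width-200
interval this is always exactly six responses, and the interval width
after `n` responses is exactly `200 / 2^n` — probes are kept as exact
binary fractions rather than rounded to whole CNY so that traces are
reproducible to the bit.  The behavioural indifference point is reported
as the midpoint of the terminal interval.  The task description leaves
the estimator open (the analysis uses model-based discount rates, not
behavioural indifference points); the midpoint minimises the worst-case
localisation error, and a property test checks that for any deterministic
threshold agent the reported point is within the terminal width of the
true threshold.

Five staircase blocks per condition use LL delays of 7, 15, 30, 80 and
140 days (immediate; +15 days in the non-immediate condition), so the
two conditions span nine distinct delays between 7 and 155 days — this
reconstruction is forced by the requirement of nine distinct delays
within 7–160 days.  The fixed ten-pair battery uses SS amounts of
100–194 CNY; only the range and count are constrained, so the amounts are
the ten equally spaced values rounded to whole CNY (100, 110, 121, 131,
142, 152, 163, 173, 184, 194), with the LL option at 85 days (immediate)
or 105 days (non-immediate).  Practice blocks can be generated but are
flagged (`practice = TRUE`) and never analysed.

## Discounting model

Present values are hyperbolic, `V = A / (1 + k t)` with `k` in units of
1/day, and choices follow a softmax rule
`P(LL) = logistic(τ (V_LL − V_SS))` with inverse temperature `τ` in units
of 1/CNY.  The hierarchical model places normal group-level distributions
on `log k` (per participant, per condition under the `split_by_condition`
structure; one per participant under `joint`) and on `log τ`.  Priors are
weakly informative and configurable: group means of `log k` are
Normal(log 0.05, 1.5²) — centred on a typical laboratory discount rate
with a two-orders-of-magnitude soft range — `log τ` group means are
Normal(0, 1), and group-level scales are half-normal(1).

Sampling is MCMC via JAGS.  The discount-rate hierarchy is centred (it is
well informed by the data); the temperature hierarchy is *non-centred*
(`log τ_p = μ_t + σ_t z_p`), because on realistic cohorts the group-level
temperature scale shrinks toward zero and the centred form funnels — with
the hybrid parameterisation every parameter of the full-scale fits reaches
R̂ < 1.01.  Defaults are 4 chains × 1,000 retained draws; the analysis
drivers use 1,000 adaptation and 1,000 burn-in iterations with thinning 2,
and the recovery suites use reduced settings (2–4 chains × 300–500 draws)
at 12–16 participants per group.  Chains are seeded deterministically, so
a fit is a pure function of (data, spec, config).

Convergence is diagnosed with the classic Gelman–Rubin potential scale
reduction factor, `sqrt(Var⁺/W)` with `Var⁺ = ((n−1)/n) W + B/n`,
implemented from its defining formula (no chain splitting inside the
operation; callers may pre-split).  Any fit with a parameter at R̂ ≥ 1.1
is flagged, and the one-command reproduction aborts on it by default.
WAIC uses the variance form: `lppd` via log-sum-exp (safe for extremely
negative log-likelihoods), `p_waic` as the sum of pointwise draw
variances (S − 1 denominator), `waic = −2(lppd − p_waic)`.  A model is
preferred only when ΔWAIC > 10; both statistics are validated against
naive two-pass reference implementations to 1e−9.

## Time perception

Line-scale judgments (28.5 cm line) are converted to subjective days by
anchoring the *cohort-mean* one-week mark at 7 days, `T = 7 L / L̄_week`.
The anchoring wording ("overall mean … for each individual") is ambiguous
between cohort-level and individual-level anchors, so both are
implemented; cohort-mean is the default and individual anchoring is
exposed for sensitivity analysis.  Note that under cohort anchoring the
fitted α̂ is a *relative* contraction, `α̂ ≈ (α/ᾱ) 7^{1−β}`; group
contrasts are preserved but α̂ is not the generative α.

The power law `T = α t^β` is fit per participant and condition by OLS on
the log scale — the natural estimator under multiplicative (Weber-like)
judgment noise — with nonlinear least squares available as a
cross-check; both agree exactly on noiseless data.  Points with `T ≤ 0`
are dropped with a warning, and fits need at least 3 usable points.  The
immediate-condition fit uses durations {7, 15, 30, 80, 140}; the
non-immediate fit {15, 22, 30, 45, 95, 155}, i.e. each battery's own
delays, with the shared 15-day duration contributing to both.  The
subjective discounting variant replaces every delay `t` in the likelihood
with that participant-condition's `T = α̂ t^β̂` (with `t = 0 → T = 0`).

## The synthetic cohorts

The generator's defaults encode the study conditions: 31 participants
per group in the titration cohort, 57/58 in the fixed-battery cohort.
Two generative mechanisms coexist in one `group_spec`:

* **Perception mechanism (default).** Both groups share one
  subjective-time discount rate (`log k_subj ~ Normal(log 0.165, 0.4²)`)
  and differ only in time contraction: α ~ truncated-Normal(2, 0.35²) in
  the affect-positive group vs (1, 0.35²) in the neutral group, with β ~
  truncated-Normal(0.45, 0.08²) in both.  Choices simulated on perceived
  time then *look* steeper on calendar time for the positive group.
* **Direct mechanism.** Per-condition objective rates
  (`log k`: immediate log 0.08 vs log 0.04 across groups, non-immediate
  log 0.045 in both, SD 0.5, within-participant correlation 0.7 — the
  correlation is an assumption, exposed in the spec) for simulations that
  bypass perception, used by the parameter- and model-recovery suites.

Two physical constraints fixed the perception defaults.  First, the line
geometry: with the one-week mark near 7.42 cm on a 28.5 cm line, a pure
power law can only span a factor ≈ 3.8 between 7 and 155 days, which
requires β ≈ 0.45 for α up to ≈ 2.8 — steeper β would clip long-delay
marks at the line end and corrupt the perception fits (mild tail clipping
remains possible and is handled; it is also what real lines do).  Second,
the calibration of `k_subj`: it was set once so that the fitted
objective-basis immediate-condition group means land near 0.08 and 0.04;
with seed 1 the full pipeline returns 0.081 and 0.031.  Because this is a
pure scale choice it cancels from every log-scale group contrast.

Remaining defaults: softmax `log τ ~ Normal(log 0.5, 0.3²)` shared across
groups (no temperature differences are modelled); lognormal line-judgment
noise with σ = 0.2 (lengths are positive and errors Weber-like);
attention propensities `p_delay_first` 0.79 vs 0.38 and
`p_delay_majority` 0.71 vs 0.49, chosen via the 2 × 2 identity
`r ≈ (p₁ − p₂) / (2√(p̄ q̄))` to give effect sizes near 0.41 and 0.22 at
N = 115.  All simulation is deterministic given the master seed;
per-participant sub-seeds are derived from it.

### What the generator does and does not emulate

It reproduces the *structure* the analysis assumes: group/condition
discount-rate differences, softmax choice noise, power-law perception
with group differences confined to α, and attention propensities.  It
does **not** emulate affect induction itself (no PANAS scores or video
ratings — group labels are taken as given), inattention or lapses,
trial-order and fatigue effects, or the discreteness of real slider
responses.  Passing recovery tests therefore show that the estimators
recover the assumed data-generating process at study scale — not that
real data satisfy those assumptions.

Three honest deviations from the canonical printed pattern are worth
knowing.  (1) Under the pure-α mechanism the objective-basis group ratio
is similar in both conditions, so at n = 31/group the *non-immediate*
simple effect is typically also significant even though its absolute size
is ~8× smaller; the interaction and the subjective-basis null — the
substantive claims — hold regardless.  (2) Subjective-basis posterior-mean
`k` shows a condition main effect: the non-immediate condition identifies
`k` more weakly, the posterior is wider, and the mean of `exp(log k)`
inflates accordingly.  The group contrast, which is the question of
interest, is unaffected.  (3) Fixed-battery SS proportions run near
ceiling in the immediate condition: at the study's own discount rates the
LL option at 85 days is worth far less than any SS offer, so a coherent
value model predicts mostly SS choices; matching the more moderate
printed proportions would require additional choice noise that nothing
else in the data motivates.

## Group-level statistics

The 2 × 2 mixed ANOVA uses the split-plot decomposition: subjects within
groups as the error for the between effect; the condition × subjects
stratum for the within and interaction effects.  Unequal group sizes
(the fixed-battery cohort is 57/58) are handled with unweighted-means
(Type III) tests computed from per-subject condition differences; with
balanced groups this reduces exactly to the textbook sums of squares
(verified against `aov` to 1e−9) and on unbalanced designs it matches
`car::Anova(type = 3)` on the multivariate formulation.  Partial η²
(`SS_eff / (SS_eff + SS_err)`) is reported alongside classic η².
Post-hoc simple effects compare groups within each condition by Student
t tests with Bonferroni adjustment (m = 2).  The chi-square test is the
uncorrected Pearson statistic — the uncorrected form is what makes the
printed χ²/r pairs satisfy `r = √(χ²/N)` exactly — and the t-test layer
offers Student, Welch, and an auto rule (Welch when an F test rejects
variance homogeneity at 5%).

## Problem sizes

The test suite exercises the estimators at deliberately reduced scale so
that the full suite runs in a few minutes: recovery at 16 + 16
participants (4 × 500 draws), model recovery and the
disappearing-effect property over 10 seeds each at 12–16 participants
with 2 × 300 draws, ANOVA calibration over 1,000 null simulations at
n = 8 per group.  The analysis drivers run the full 31 + 31 / 57 + 58
design at 4 × 1,000 retained draws with thinning 2.

## Known limitations

Only the hyperbolic discounting family is implemented (no exponential or
quasi-hyperbolic alternatives); groups are fitted separately rather than
in one model with a group covariate, matching the analysis pattern this
package reproduces; Bayesian group comparison is deliberately left to
the frequentist layer on posterior-mean point estimates; and the
perception fit propagates no uncertainty into the subjective refit —
`T` enters as a plug-in estimate.
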