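# affdisc

Incidental affect — emotion induced by things unrelated to the decision at
hand — can make people more impatient in intertemporal choice (IC), but
apparently only when one of the options is available *today*.  `affdisc`
is an R package plus analysis workflow for studying this **disjunction
effect**: the package simulates two-group (affect-positive vs
affect-neutral) IC experiments and runs the full model-based analysis that
separates "immediate" from "non-immediate" choice conditions, so that the
whole pipeline can be exercised, validated, and extended without access to
raw participant data.

It is aimed at decision-making researchers who want a tested reference
implementation of this analysis pattern: adaptive choice titration,
hierarchical Bayesian discounting, psychophysical time perception, and the
group-level statistics, end to end.

## The models

**Task.** Participants choose between a smaller-sooner reward (SS, today
or in 15 days) and a larger-later reward (LL, fixed at CNY 200).  A
bisection staircase titrates the SS amount: after an LL choice the SS
interval's lower bound rises to the current probe, after an SS choice the
upper bound falls, the next probe is the interval midpoint, and the block
stops once the interval is ≤ CNY 5 wide (six responses from the initial
width of 200).  Five LL delays per condition (7, 15, 30, 80, 140 days,
all +15 in the non-immediate condition) give nine distinct delays between
7 and 155 days.

**Discounting.** Hyperbolic present value `V = A / (1 + k t)` with a
softmax choice rule `P(LL) = logistic(τ (V_LL − V_SS))`.  Per-participant
`log k` (one per condition in the *split* model, one overall in the
*joint* model) and `log τ` follow normal group-level distributions,
sampled by MCMC (JAGS) with Gelman–Rubin R̂ < 1.1 required of every
parameter.  Joint vs split is decided by WAIC with a ΔWAIC > 10 rule.

**Time perception.** Line-scale judgments are anchored so the cohort-mean
one-week mark equals 7 subjective days, then fit per participant and
condition with the power law `T = α t^β` (α = overall time contraction,
β = diminishing time sensitivity).  The *subjective* discounting variant
refits the choice model with every delay `t` replaced by `T`.

**Group layer.** 2 × 2 mixed-design ANOVA (affect × condition) with
Bonferroni simple effects and partial η², two-sample t tests with
Cohen's d, and 2 × 2 chi-square tests with effect size `r = √(χ²/N)` for
the attribute-attention data.

## Worked example

```r
library(affdisc)

# a staircase block against a deterministic hyperbolic agent:
# k = 0.05 at a 30-day delay values CNY 200 at 200/(1+1.5) = 80
blk <- run_block(threshold_agent(80), ll_delay = 30, ss_delay = 0)
blk$records$choice        # "SS" "LL" "LL" "SS" "SS" "LL"
blk$indifference_point    # 79.6875 -- within the terminal width of 80

# simulate the default synthetic cohort and fit the split model
cohort <- sample_cohort(default_group_spec("positive"),
                        default_group_spec("neutral"), seed = 1)
trials <- simulate_cohort_choices(cohort, study = 1, seed = 2,
                                  time_basis = "subjective")
fit <- fit_hierarchical(trials[trials$group == "positive", ],
                        discount_model_spec("split_by_condition",
                                            "objective"),
                        mcmc_config(seed = 3))
extract_k_estimates(fit)  # posterior-mean k per participant x condition
```

The numbered drivers under `analysis/` run the whole workflow
(`Rscript analysis/01_simulate_cohorts.R 1`, then `02` … `05`) and write
their tables to `results/`.  With the default scenario and seed 1 they
print, among other things:

* WAIC, split vs joint: positive group 2113 vs 2344 (Δ ≈ 231), neutral
  group 2039 vs 2261 (Δ ≈ 222) — the condition-split model is decisively
  preferred in both groups.
* Objective discount rates: immediate-condition means 0.081 (positive)
  vs 0.031 (neutral); affect × condition interaction
  F(1, 60) = 21.4, p < 0.001, partial η² = 0.26.
* Time contraction α: group effect F(1, 60) = 25.7, p < 0.001; no group
  effect on β (F = 0.36, p = 0.55).
* Subjective-time discount rates: the group difference disappears
  (group F(1, 60) = 0.21, p = 0.65; immediate-condition simple effect
  p ≈ 1.0) — the disjunction effect is carried by time perception.
* Fixed-battery proportions of SS choices: positive > neutral and
  immediate > non-immediate; attention tests
  χ²(1) = 9.57, r = 0.29 (first-opened attribute) and
  χ²(1) = 3.57, r = 0.18 (majority attribute) at N = 115.

Because the cohorts are synthetic, the exact statistics vary with the
seed; the qualitative pattern above is what the generator is built to
produce.  `run_reproduction(pipeline_config(seed = 1))` performs the same
sequence in one call and returns the pattern checks programmatically.

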