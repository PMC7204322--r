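# epolr

Baseline-adjusted proportional odds models for ordinal sum score
outcomes in two-arm randomized trials.

## The problem

Ordinal sum scores with many categories — an upper-extremity motor score
on 0–50, an independence measure on 0–100 or its self-care subscore on
0–20 — are standard primary outcomes in neurological trials.  The usual
analyses are unsatisfying: t-tests and ANCOVA treat the score as
interval-scaled (a 5-point gain means something different at the bottom
and the top of the scale), the Wilcoxon test respects the ordering but
cannot use baseline information, and a classical proportional odds model
would need one intercept per category and stratum — easily more
parameters than patients — and still offers no baseline adjustment.

`epolr` replaces the category intercepts with a smooth monotone
transformation function

P(Y ≤ y | y⁰, stratum, x) = expit( h(y | y⁰, stratum) + β·x ),

where h is a Bernstein polynomial in the (floored) outcome, tensored
with a dummy coding of the strata and a response-varying baseline
regressor (1, y⁰) — e.g. 7 × 3 × 2 = 42 parameters instead of
(k − 1) × strata intercepts.  Monotonicity of h is enforced by linear
constraints on the coefficient sequences.  The single coefficient β is a
*global* treatment effect: exp(β) multiplies the odds of scoring at or
below any cut-point for treated versus control patients at the same
baseline.  Because β sits inside the distribution function, exp(−β) is
the conventional *benefit* odds ratio (> 1 means treated outcomes are
stochastically larger); every report prints both directions.

The package provides

* constrained maximum likelihood estimation (`epolr_fit`) with Wald
  confidence intervals for the odds ratio (`wald_inference`),
* a model-based permutation score test (`epolr_permutation_test`) that
  keeps its level in small samples where the Wald test is liberal,
* a parametric-bootstrap trial simulator and power study
  (`sample_outcomes`, `run_test_battery`, `estimate_power`) comparing
  the model tests against t-test, Wilcoxon and ANCOVA over a grid of
  sample sizes and odds ratios, with Wilson confidence intervals,
* a synthetic cohort generator with known ground truth
  (`generate_cohort`), so everything is testable without access to any
  patient registry,
* a thin command-line interface (`inst/cli/epolr.R`) with subcommands
  `fit`, `test`, `power` and `simulate-cohort`.

## Worked example

Simulate a 350-subject two-arm trial with a true benefit odds ratio of
1.5, then fit the stratified model and run both tests:

```r
library(epolr)

g   <- generate_cohort(cohort_config("uems", n_subjects = 350,
                                     beta_benefit = log(1.5), seed = 11))
fit <- epolr_fit(g$cohort)
fit
#> Baseline-adjusted proportional odds model
#>   n = 350, strata: seg4-6, seg7-8, seg9-10
#>   transformation: 42 parameters (7 Bernstein functions)
#>   beta (log-OR of <= score, trt:ctrl) = -0.2350 (se 0.1967); benefit OR = 1.2649
#>   log-likelihood: -1105.5807

wald_inference(fit)
#> Asymptotic (Wald) inference for the treatment effect
#>   OR (odds of <= score, treated:control): 0.7906  [0.5377, 1.1624]
#>   benefit OR exp(-beta):                  1.2649  [0.8603, 1.8598]
#>   z = -1.195, two-sided p = 0.2321 (level 0.95)

epolr_permutation_test(g$cohort, n_perm = 10000, seed = 12)
#> Permutation score test (10000 permutations)
#>   T = -6.0941, Z = -1.152, two-sided p = 0.247
```

The estimated benefit odds ratio 1.26 (true value 1.5) says a treated
subject's odds of exceeding any given score are about 1.26 times a
comparable control's; at this sample size and effect neither test is
significant, which is exactly what the power machinery quantifies:

```r
sc <- trial_scenarios(n_total = c(80, 160, 240), or_benefit = c(1.5, 2),
                      n_reps = 500)
pw <- estimate_power(sc, g$cohort, seed = 3)
```

returns the rejection fraction of all five tests per scenario with
Wilson intervals.

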