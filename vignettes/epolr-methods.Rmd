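---
title: "Smooth baseline-adjusted proportional odds models for ordinal sum scores"
author: "epolr package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smooth baseline-adjusted proportional odds models for ordinal sum scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epolr)
```

## The model

Ordinal sum scores with many categories — motor scores on 0–50,
independence measures on 0–100 — are the primary outcomes of many
neurological trials.  A classical proportional odds model would need one
intercept per category and stratum, quickly exceeding the number of
patients, and offers no natural way to condition on the baseline score.
`epolr` instead models the conditional distribution function directly:

$$
P(Y \le y \mid y^0, \texttt{stratum}, x)
  = \operatorname{expit}\bigl(h(y \mid y^0, \texttt{stratum}) + \beta x\bigr),
$$

where $x \in \{0, 1\}$ is the treatment arm and $h$ is a smooth monotone
transformation of the outcome.  The single parameter $\beta$ is a global
log odds ratio: $\exp(\beta)$ multiplies the odds of scoring at or below
any cut-point $y$ for a treated patient relative to a control with the
same baseline characteristics.  Because the linear predictor sits inside
the distribution function, negative $\beta$ corresponds to stochastically
*larger* outcomes; all reports therefore state both directions explicitly,
$\exp(\beta)$ as the "odds of lower-or-equal score" and $\exp(-\beta)$ as
the *benefit* odds ratio.

### The transformation function

$h$ is parameterized by a Bernstein polynomial basis $a(\lfloor y \rfloor)$
of `order` functions on $[0, k_{\max}]$ (default `order = 7`, a
parsimonious choice that still tracks the strongly curved logit-CDFs of
skewed scores), tensored with a dummy coding of the strata and with the
response-varying baseline regressor $(1, m^0)$:

$$
h(y \mid m^0, s) = a(\lfloor y \rfloor)^\top
  \bigl(\vartheta^{(s)}_{1} + \vartheta^{(s)}_{2}\, \tilde m^0\bigr),
\qquad \tilde m^0 = \frac{m^0 - m_{\min}}{m_{\max} - m_{\min}} \in [0, 1].
$$

With 7 basis functions, 3 strata and the two covariates this yields
$7 \times 3 \times 2 = 42$ transformation parameters.  The boundary
conventions $h(-1) = -\infty$ and $h(k_{\max}) = +\infty$ make the
category probabilities telescope to one.  The likelihood contribution of
an observation is the difference of two expits,
$\operatorname{expit}(h(y) + \beta x) - \operatorname{expit}(h(y-1) + \beta x)$,
evaluated on the log scale with a log-difference-of-expits identity so
that extreme categories do not underflow.

### Monotonicity

A Bernstein polynomial is non-decreasing whenever its coefficient
sequence is.  Because $h$ is affine in $\tilde m^0$, requiring increasing
coefficients at *both extremes* $\tilde m^0 \in \{0, 1\}$ of the
theoretical baseline range is sufficient for monotonicity at every
intermediate baseline value; this is the minimal linear constraint set
and the package's own choice — how the response-varying interaction
should be constrained is genuinely open, and nothing stronger is needed.
Internally each constrained sequence is reparameterized as
(first value, log-increments), with a strictness floor of $10^{-8}$ on
the increments, so an unconstrained quasi-Newton optimizer (BFGS with an
analytic gradient, `reltol` $10^{-10}$, at most 1000 iterations) can be
used without active-set bookkeeping.  Whenever the observed information
is computed, a damped Newton polish sharpens the optimum beyond the BFGS
stopping rule; this is what makes the binary-outcome reduction agree with
`glm` to $10^{-6}$.

### Initialization, covariance, degenerate inputs

The transformation is initialized from the per-stratum empirical marginal
logit-CDF evaluated on the Bernstein node grid (clipped to
$[0.02, 0.98]$, increments floored at $0.05$), with zero baseline slope
and $\beta = 0$.  Standard errors come from the observed information of
the reparameterized problem, mapped back to $(\beta, \vartheta)$ by the
delta method; a rank-deficient information matrix (flat directions arise
when increments hit the strictness floor) falls back to a pseudo-inverse.
A stratum with fewer observations than basis functions triggers a
warning; a stratum with fewer than two distinct outcome values is an
error, since no transformation is identifiable there.  Baseline scores
outside the declared range are clamped with a warning.

## Permutation score inference

The Wald ("asymptotic") test reads $p$-values off the normal
approximation for $\hat\beta$.  For small trials that approximation is
known to be liberal, so the package also provides a model-based
permutation score test: fit the *intercept-only* model, extract per-
subject score contributions

$$
S_i = \frac{w(h(y_i)) - w(h(y_i - 1))}{\operatorname{expit}(h(y_i)) -
  \operatorname{expit}(h(y_i - 1))},
\qquad w = \operatorname{expit}',
$$

(the derivative of subject $i$'s log-likelihood with respect to a common
shift, evaluated at zero), and compare the observed
$T = \sum_i S_i I(x_i = 1)$ with its distribution under uniform
re-randomization of the arm labels.  Two-sidedness is obtained by
centring at the permutation mean and using $|T - \bar T|$ — standard and
symmetric for balanced allocation — and the add-one estimator
$(b + 1)/(B + 1)$ keeps the $p$-value strictly positive.  Permutations
are simple label shuffles; the stratification enters through the null
model's $h$.  A within-stratum permutation option exists but is off by
default.  With the fixed rank transformation
$h(m) = \operatorname{logit}(R(m)/N)$ (upranks $R$) the same construction
reproduces Wilcoxon scores, which is exploited as a test oracle: on
tie-free data the score test's accept/reject decisions coincide with the
exact rank sum test.

## Power simulation

`estimate_power()` implements a parametric bootstrap power study for
two-arm trials.  The intercept-only model fitted to a treatment-naive
base cohort acts as the generator.  For each scenario — by default five
total sample sizes (80–240) crossed with nine benefit odds ratios
(1–3), i.e. 45 scenarios, 1:1 allocation — subjects are resampled with
replacement from the base cohort (with-replacement keeps scenarios valid
when the trial size exceeds the pool), baselines and strata are kept,
and *all* follow-up outcomes are redrawn from the generator, the treated
arm shifted by the scenario's benefit log odds ratio.  Resampling the
control arm as well (rather than keeping observed follow-ups) makes null
trials exactly exchangeable, so the permutation test's level is exact by
construction.  Each simulated trial is analysed with five tests: pooled
t-test on change scores, Wilcoxon rank sum on change scores
(tie-corrected normal approximation; exact enumeration is infeasible at
trial sizes with ties), ANCOVA of the follow-up on baseline plus arm,
the asymptotic model test, and the permutation score test with the null
model re-estimated on every simulated trial.  Rejection fractions at
$\alpha = 0.05$ are reported with Wilson confidence intervals.  The
replicate count is a configuration parameter (default 1000 per scenario
for desk-scale runs; a full-scale study would use 15000, whether per
scenario or in total across the grid is deliberately left to the user).
One master seed spawns per-scenario, per-replicate sub-streams, so any
scenario can be reproduced independently.

## The synthetic cohort generator

Real registry data of this kind is not redistributable, so the package
ships a generator whose draws have known ground truth and whose law lies
(approximately) inside the fitted model family:

* baseline scores: a discretized $\mathrm{Beta}(1.2, 3.5)$ scaled to the
  preset range — right-skewed, bounded, two tunable parameters;
* segments below motor level uniform on 4..10, collapsed to the strata
  bands [4,6], [7,8], [9,10] (single stratum for the SCIM presets);
* follow-up from the transformation model with
  $h(y) = a_0 + a_s + b_s \operatorname{logit}\bigl((y + 0.5)/(k_{\max} + 1)\bigr)
  + c\,\tilde m^0$, defaults $a_0 = 3$, $a_s = (-1.2, 0, 1.2)$,
  $b_s = (0.9, 1.0, 1.1)$, $c = -12$; the negative $c$ makes follow-up
  stochastically non-decreasing in baseline (Spearman correlation about
  0.7 under the defaults), and the treated arm's transformation is
  shifted by $-\beta_{\text{benefit}}$.

The presets mirror the three outcome scales of interest: follow-up 0–50
with baseline 0–28 and three strata; 0–100; and 0–20.  What the
generator does *not* emulate: assessment-time windows, item-level
structure, missingness, or any estimate of a real cohort's marginal
distributions — passing tests demonstrate correctness of the machinery
and the qualitative power ordering, not the numeric power values of any
particular patient population, which depend on that population's
baseline distribution.

## Problem sizes used by the test-suite

The package's own acceptance checks run at sizes chosen to make the
statistical assertions sharp while staying desk-scale: the type-I error
of the permutation test is estimated from 1000 null trials of size 80
with 1000 permutations each (Wilson-compatible band around 0.05);
Wald-CI coverage from 200 cohorts of size 2000; the power-monotonicity
and dominance sweep from a reduced grid
($N \in \{80, 240\} \times \mathrm{OR} \in \{1, 2, 3\}$) at 300
replicates per scenario with 500 permutations per trial.

## Known limitations

* The Wald test inherits the liberal small-sample behaviour typical of
  maximum likelihood in richly parameterized ordinal models; at size 2000
  its empirical CI coverage sits near the lower edge of the nominal band
  (first-order ML bias of order parameters/N plus a mildly
  anticonservative observed-information variance).  The permutation test
  is the recommended primary inference for small trials.
* One binary treatment term only; no repeated-measures trajectories, no
  non-logit links.
* The response-varying baseline effect is constrained at the extremes of
  the *declared* baseline range; a grossly misdeclared range weakens the
  monotonicity guarantee between the true extremes.
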