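---
title: "Bayesian reanalysis of trial subgroups from summary statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian reanalysis of trial subgroups from summary statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesreanal)
```

## The problem

Regulatory decisions about the anti-amyloid antibodies lecanemab and
donanemab diverge on one subgroup: ApoE &epsilon;4 homozygotes, who carry
the highest risk of amyloid-related imaging abnormalities (ARIA). The
phase-3 publications report the subgroup effects on the Clinical Dementia
Rating scale Sum of Boxes (CDR-SB) only as adjusted mean differences (MD)
with 95% confidence intervals and group sizes — both intervals include
zero, one trending each way. A frequentist "not significant" cannot
distinguish *absence of evidence* from *evidence of absence*. This package
implements the Bayesian toolkit for answering that question from exactly
those published summaries: how strongly do the subgroup data support a
treatment effect, no effect, or a difference between the two antibodies,
and what effect size do the two trials jointly imply?

Everything operates on summary statistics; no patient-level data are used
anywhere.

## Reconstruction of effect estimates

From a published (MD, 95% CI, $n_a/n_b$) record we reconstruct

$$\mathrm{SE} = \frac{|\,\mathrm{upper} - \mathrm{lower}\,|}{2\,t_{0.975,\nu}},
\qquad T = \mathrm{MD}/\mathrm{SE},$$

using the Student-t quantile for $\nu \le 120$ and the normal quantile
1.959964 above (the comparisons of interest all have more than 200 cases,
where the two are indistinguishable at printed precision). The contrast
"effect of antibody A versus effect of antibody B" has
$\mathrm{MD} = \mathrm{MD}_A - \mathrm{MD}_B$ and
$\mathrm{SE} = \sqrt{\mathrm{SE}_A^2 + \mathrm{SE}_B^2}$, each trial's
total sample acting as one "group" of the contrast.

Two reconstructed columns have no published formula and are our own
convention, chosen because they reproduce all printed values to
$\pm 0.03$: the implied standard deviation of the effect
$\mathrm{SD} = \mathrm{SE}\sqrt{n_a n_b/(n_a+n_b)}$ and Cohen's
$d = \mathrm{MD}/\mathrm{SD}$. The identity
$T = d\sqrt{n_a n_b/(n_a+n_b)}$ then holds exactly and is enforced by a
property test.

**Degrees of freedom.** The source analyses use $\nu = n_a + n_b$ ("total
number of cases") rather than the conventional $n_a + n_b - 2$. We
implement the stated convention as the default (`df_convention = "total"`)
and expose `"residual"`; at these sample sizes the Bayes factors differ in
the fifth decimal, so nothing downstream depends on the choice.

**Rounding.** All computation carries full precision; rounding
(half-away-from-zero, as in the published tables) happens only in print
methods and reports. Reconstructed t statistics (e.g. $-0.41/0.30 =
-1.3667$) therefore differ in the third decimal from the printed ones
($-1.36$); tolerances in the test suite are wide enough to absorb this
input-rounding, which is also why the published contrast t of $-1.61$
versus our $-1.5995$ is immaterial.

## Bayes factor t tests from summary statistics

With $\nu$ degrees of freedom and effective sample size
$n_\mathrm{eff} = n_a n_b/(n_a+n_b)$, the t statistic has density
$f_{t}(t;\nu)$ under $H_0: \delta = 0$ and noncentral-t density
$f_{t}(t;\nu,\delta\sqrt{n_\mathrm{eff}})$ given a standardized effect
$\delta$. The Bayes factor for $H_1: \delta \sim \pi$ is

$$\mathrm{BF}_{10} = \frac{\int f_{t}(t;\nu,\delta\sqrt{n_\mathrm{eff}})\,
  \pi(\delta)\,d\delta}{f_{t}(t;\nu)}.$$

Two prior families are provided:

* `cauchy_prior(scale = 0.707)` — the zero-centered Cauchy of the default
  Jeffreys–Zellner–Siow test, scale $r = \sqrt{2}/2$;
* `student_t_prior(location, scale, df)` — a shifted/scaled t, used with
  `df = 3` as the "adversarial" prior of an optimistic expert. Its scale
  comes from a standard error via
  $\mathrm{scale} = \mathrm{SE}\sqrt{\mathrm{df}/(\mathrm{df}-2)}$
  (`adversarial_scale()`), which makes the prior's standard deviation
  equal that SE.

The integral is evaluated by adaptive quadrature (relative tolerance
$10^{-9}$) on a domain split at the prior location $\pm\{1, 10, 100\}$
scales, with the two unbounded tails mapped to $(0,1)$ by
$u \mapsto u/(1-u)$; the splits keep the quadrature honest against the
Cauchy/t heavy tails. The noncentral-t density is clamped to zero where it
underflows at extreme noncentrality, which is exact to working precision.
A $10^6$-draw Monte-Carlo prior-predictive estimate serves as an
independent oracle in the tests and agrees within three Monte-Carlo
standard errors across randomized configurations.

**The adversarial prior's scale of measurement.** The published
donanemab prior is centered at $-0.36$ — a *raw* CDR-SB effect from the
phase-2 trial — yet is entered into a test that operates on the
*standardized* effect $\delta$. Only that literal interpretation (prior on
$\delta$ with the printed location and scale) reproduces the published
BF of 0.64, so it is the default; the ambiguity is real, and users can
place a raw-scale prior by standardizing location and scale with the
reconstructed SD before calling `bf10_adversarial()`.

**One- versus two-sided.** The headline API is two-sided, matching the
published analysis; `alternative = "less"/"greater"` truncates and
renormalizes the prior, and for symmetric priors the two one-sided
marginal likelihoods average exactly to the two-sided one (a property
test).

`robustness_curve()` recomputes the JZS factor over 150 log-spaced Cauchy
scales on $[0.01, 1.5]$. At $r \to 0$ the alternative collapses onto the
null and $\mathrm{BF}_{10} \to 1$; for all three bundled comparisons the
curve never exceeds about 1, i.e. no prior width in the plausible range
yields even moderate evidence for an effect.

Evidence bands follow the conventional ladder (3, 10, 30, 100 and their
reciprocals). Note one boundary subtlety: a BF of 0.353 sits just *above*
1/3 and is therefore labelled "anecdotal evidence for H0" by the literal
bands, even though it is colloquially reported as roughly threefold
support for the null.

## The random-effects meta-analysis

The two subgroup results enter a normal-normal hierarchical model
(NNHM):

$$y_i \mid \theta_i \sim N(\theta_i, \sigma_i^2), \quad
  \theta_i \mid \mu, \tau \sim N(\mu, \tau^2), \quad
  \mu \sim N(0, s_0^2), \quad \tau \sim \pi(\tau),$$

with $s_0 = 1$ CDR-SB point and $\tau \sim$ half-normal(0.5) by default —
a weakly informative choice consistent with empirical heterogeneity
surveys. Conditional on $\tau$ the $\mu$ posterior is conjugate normal
with precision $s_0^{-2} + \sum_i (\sigma_i^2+\tau^2)^{-1}$; the $\tau$
marginal is computed on a uniform grid of at least 1600 nodes
(trapezoidal weights), whose upper end doubles until the posterior mass
beyond 95% of the grid is below $10^{-6}$. All posterior functionals —
$\mu$ summaries, shrinkage per study, the posterior predictive
$N(\mu, \tau^2)$ mixture for a new study, and the Savage–Dickey density
at zero — are exact mixtures of conditional normals over that grid, so
the whole fit is deterministic and bit-reproducible given the grid spec
(stored in the fit object).

**Interval conventions.** The $\mu$ (and predictive) intervals are
equal-tailed; the $\tau$ interval is shortest-coverage, whose lower bound
is typically 0 under the half-normal prior. Both styles are exposed for
both parameters. The $\tau$ point estimate is the posterior median by
default (the posterior mean is available); on the bundled input the two
differ by less than the reporting precision.

**The Jeffreys heterogeneity prior.** "Jeffreys prior" for $\tau$ admits
variants. We use the one derived from the Fisher information of $\tau$ in
the marginal model $y_i \sim N(\mu, \sigma_i^2 + \tau^2)$,

$$\pi(\tau) \propto \tau\sqrt{\textstyle\sum_i (\sigma_i^2+\tau^2)^{-2}},$$

which is the convention of the reference Bayesian meta-analysis software
and — decisive for us — the only variant that reproduces the published
sensitivity result ($\hat\tau$ rising from 0.33 to 0.59 with a 95% CrI of
[0.01, 2.76]); the variant without the leading $\tau$ factor *lowers*
$\hat\tau$ instead. The prior is improper; it is normalized numerically
on the grid. Its posterior tail decays only polynomially
($\propto \tau^{-3}$ with two studies), so the $10^{-6}$ tail rule is
unattainable below the hard grid cap of $100 \times \max_i \sigma_i$; for
improper priors we truncate at that cap, having verified that the median
and interval change by less than 0.01 when the cap is quadrupled. Proper
priors that fail to concentrate below the cap raise an error instead.

**Three Bayes factor routes.** `bf10_meta()` computes the evidence for a
nonzero overall effect three ways:

1. *Savage–Dickey* (default): posterior over prior density of $\mu$ at 0;
2. *marginal-likelihood ratio*: $\int p(y\mid\tau,\mu{=}0)\pi(\tau)d\tau$
   against $\int p(y\mid\tau)\pi(\tau)d\tau$ — analytically identical to
   Savage–Dickey, implemented independently and required by the tests to
   agree within $10^{-4}$;
3. *inclusion*: the fixed/random model-averaged factor
   $\bigl(p(y\mid\mathrm{FE}_1)+p(y\mid\mathrm{RE}_1)\bigr) /
   \bigl(p(y\mid\mathrm{FE}_0)+p(y\mid\mathrm{RE}_0)\bigr)$ with equal
   model prior odds, where FE pins $\tau = 0$ and RE integrates it over
   the prior.

On the bundled input these give 0.311 (routes 1–2) and 0.263 (route 3).
The published meta-analytic BF of 0.26 matches the inclusion route — the
default of the model-averaged meta-analysis software family — so that is
what the reproduction reports, while Savage–Dickey remains the default of
the plain NNHM API. The discrepancy is not numerical error: the two
answer slightly different questions (evidence within the random-effects
model versus evidence averaged over fixed- and random-effects models).

## Sensitivity analyses

`run_sensitivity_suite()` re-fits the meta-analysis under named variants;
the bundled preset holds the four published ones: baseline, SEs inflated
by 20% (`inflate_se()`, guarding against imprecision in graph-derived
SEs), the Jeffreys $\tau$ prior, and a wide $\mu$ prior (SD 4). "Results
preserved" is operationalized as *same side of* $\mathrm{BF} = 1$ as
baseline (the `preserved` flag); the stricter same-verbal-band check is
reported separately (`same_band`) because band boundaries — baseline
0.311 versus inflated-SE 0.337 straddling 1/3 — make it noisy without
changing any substantive conclusion. No numeric preservation criterion
was published, so none is invented.

## What the simulators emulate

`simulate_trial_subgroup()` draws per-arm normal outcome changes and
summarizes them exactly as publications do (MD, 95% CI via the same
quantile convention as the reader, arm sizes); defaults mirror the
magnitudes of the bundled subgroups ($n$ 123/97, true difference
$-0.41$, outcome SD 2.2 CDR-SB points, giving $E[\mathrm{SE}] \approx
0.30$). It deliberately omits dropout, covariate adjustment and
MMRM-style modelling: the analysis consumes only (MD, CI, n), so those
features would be invisible to everything tested. A green simulation test
therefore establishes correctness of the summary-statistics pipeline, not
fidelity to clinical-trial conduct.

`simulate_meta_studies()` draws directly from the NNHM with known
$(\mu, \tau)$, and `recovery_experiment()` (defaults: 10 studies,
$\mu = -0.3$, $\tau = 0.3$, $\sigma_i = 0.3$, 200 replicates) checks that
the 95% $\mu$ interval covers truth at its nominal rate within binomial
error — the calibration evidence behind the credible intervals reported
for the real data. All generators are pure functions of their seed
(Mersenne-Twister/inversion, recorded in the output) and restore the
caller's RNG state.

## Numerical choices, edge cases, limitations

* Quadrature failures raise a typed numerical error carrying the failing
  segment; invalid inputs raise a distinct input-error class (the CLI
  maps them to exit codes 1 and 2).
* A zero-width CI yields SE 0 at reconstruction and a diagnostic division
  error when a t statistic is requested.
* A study with $\sigma_i \to \infty$ provably drops out of every
  posterior; the tests verify this to $10^{-6}$.
* The half-normal grid starts at $8$ prior SDs, which bounds the
  posterior tail regardless of the data, so one wildly imprecise study
  cannot degrade grid resolution.
* With only two studies, $\tau$ is weakly identified and its posterior is
  prior-driven — visible in the half-normal versus Jeffreys comparison
  (0.33 versus 0.59). That is a feature of the data situation, not of the
  implementation, and is the reason the prediction interval is wide.
* Bayes factors here quantify evidence about the *subgroup* effects as
  published; nothing in the package addresses ARIA safety, dose
  interruptions, or any patient-level mechanism behind the findings.

## One-call reproduction

`run_full_reanalysis()` chains every stage — reconstruction, the three
JZS tests with robustness curves, the two adversarial tests (donanemab
prior centered on the phase-2 effect $-0.36$ with scale 0.42; contrast
prior centered on its observed $d = -0.15$ with scale 0.745), the
meta-analysis, and the sensitivity suite — and optionally writes every
table and JSON record to a directory. Reruns are byte-identical; no stage
after input uses randomness.
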