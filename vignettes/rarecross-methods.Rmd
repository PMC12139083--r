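---
title: "Methods for small-sample longitudinal cross-over trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods for small-sample longitudinal cross-over trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(rarecross)
```

## The setting

rarecross targets 2-period, 2-sequence cross-over trials with very few
subjects and repeated assessments per period — the design used in
rare-disease dermatology, where outcomes are blister counts and ordinal
pain/pruritus scores on a visual analogue scale (VAS, 0–10 cm in 0.5-cm
steps). Each subject is assessed at four occasions per period: a
within-period baseline, 2 weeks, end of treatment, and a later follow-up.
The treatment received is fully determined by the sequence group (`AB` =
active first) and the period, which is what makes sequence-label
permutation a valid re-randomization null.

With a dozen to twenty subjects, asymptotic arguments are unreliable and
every discarded observation hurts. The package therefore implements, side
by side, the three analysis families suited to this regime, a
data-generating mechanism to compare them on equal terms, and a
prediction tool for individualizing treatment once a mixed model for the
outcome exists.

## Generalized pairwise comparisons (GPC)

Every active endpoint vector is compared with every placebo endpoint
vector over an ordered priority list of endpoints (outcome × occasion).
The first priority level on which the pair differs by at least the
threshold of clinical relevance $\tau$ decides a *win* (active better) or
*loss*; only pairs tying on all levels remain ties. The net benefit is

$$\mathrm{NB} = \frac{\#\text{wins} - \#\text{losses}}{\#\text{pairs}} \in [-1, 1].$$

Design choices worth knowing:

* **Unmatched vs matched.** In a cross-over every subject supplies both an
  active and a placebo vector. The unmatched analysis forms all $n^2$
  cross pairs, including a subject's own pair — "unmatched" means the
  pairing is ignored, and excluding own-pairs would create a third variant
  with no standard name. The matched analysis uses only the $n$ own-pairs.
* **Thresholds.** A win requires a difference $\ge \tau$ when $\tau > 0$
  and a strict difference when $\tau = 0$ (otherwise equal values would
  count as wins in both directions). A natural choice of $\tau$ for
  standardized blister counts is the baseline-period variability; for the
  doubled VAS scale, $\tau = 2$ corresponds to one VAS point.
* **Missing values** make the affected priority level a tie for that pair
  — a conservative, information-preserving choice; imputation is out of
  scope throughout the package.
* **Stratification** forms pairs within pre-specified subgroups only and
  pools the win/loss/tie counts by summation.
* **Inference** is a two-sided permutation test: sequence labels are
  reshuffled across subjects (profiles intact), and
  $p = (1 + \#\{|\mathrm{NB}^\ast| \ge |\mathrm{NB}|\})/(n_\mathrm{perm} + 1)$.
  No asymptotic variance is used anywhere — at these sample sizes the
  permutation distribution is the only defensible reference.

## Rank-based marginal model and the ANOVA-type statistic

The cross-over maps onto a 2 × 4 (treatment × time) within-subject
factorial: each complete subject contributes exactly one observation per
cell. Pooling all $N$ observations of an outcome and mid-ranking them
gives cell relative effects
$\hat p_s = (\overline{R}_s - \tfrac12)/N$; the size-weighted mean of the
$\hat p_s$ is exactly $\tfrac12$, and all inference is invariant under
strictly monotone transformations of the outcome — the property that makes
this family appropriate for the ordinal-metric VAS.

Hypotheses (treatment, time, treatment × time) are projections $T$ of the
cell-effect vector; the ANOVA-type statistic is

$$F = \frac{\hat p^{\,\prime} T \hat p}{\operatorname{tr}(T \hat\Sigma)/N},$$

with $\hat\Sigma$ estimated from the within-sequence empirical covariance
of the subject-level rank vectors. Small-sample behaviour comes from the
Box approximation: $F$ is referred to an $F(\hat f, \hat f_0)$
distribution with $\hat f = \operatorname{tr}(T\hat\Sigma)^2 /
\operatorname{tr}(T\hat\Sigma T\hat\Sigma)$, and $\hat f_0$ obtained by a
Satterthwaite-type combination of the per-sequence trace contributions
(each carrying $n_g - 1$ degrees of freedom). The $\chi^2$ limit was
deliberately not used: with 8 subjects per sequence the estimated
denominator degrees of freedom matter. Calibration of this choice is
checked by simulation in the test suite (rejection under the permutation
null stays within Monte-Carlo error of 5%).

Complete-case analysis only: a subject with any missing value in the
profile is excluded, matching the method's current theory.

## Cumulative-logit GEE for ordinal VAS scores

Doubling the VAS grid gives integer categories 0..20. The marginal model
is

$$\operatorname{logit} P(X_{kt} < a) = \beta_a + \beta_1 G + \beta_2 P +
\textstyle\sum_{j=3}^5 \beta_j T_j + \beta_6 GP + \sum_{j=7}^9 \beta_j G T_j
+ \sum_{j=10}^{12} \beta_j P T_j,$$

with $a = 1..20$ threshold intercepts (threshold $a$ carries the
indicator $1(X \le a-1)$, so the boundary below category 1 — the
probability of a zero score — is modelled too), treatment indicator $G$,
period indicator $P$ and time dummies $T_2..T_4$ (occasion 1 is the
reference).
Clusters are subjects; each contributes the stacked cumulative indicators
over 20 thresholds × 8 occasions, and the reported covariance is always
the robust sandwich.

**Working association.** `"independence"` treats the stacked indicators as
uncorrelated. `"hetero_ar1"` combines the model-implied multinomial
covariance among one occasion's cumulative indicators with an AR(1)
correlation $\rho^{|t-t'|}$ across occasions and occasion-specific scale
parameters $\phi_t$ — the conventional reading of a "heterogeneous
autoregressive" structure; ordinal-GEE association parametrizations differ
across implementations, so this simplest occasion-level version was chosen
and is stated openly. Numerical safeguards, all of which only affect the
*working* matrix and are covered by the sandwich:

* the working correlation is shrunk 15% toward the identity (empty
  categories otherwise make adjacent indicators perfectly correlated, and
  a near-singular weight matrix can push the weighted equations into
  quasi-separation);
* $\rho$ and $\phi_t$ are moment estimates from winsorized Pearson
  residuals, updated once after an initial solve (two-stage estimation —
  a joint fixed point need not exist at these sample sizes);
* if the weighted equations have no finite root at the estimated $\rho$,
  $\rho$ is backed off geometrically until they do.

The coefficient solver is modified Fisher scoring with step capping and a
line search on the estimating-function norm, followed by a Newton polish
with a numerical Jacobian (plain scoring ignores the $\beta$-dependence of
$D'V^{-1}$ and need not contract at the root). Convergence requires a
maximum parameter change below `tol` (default 1e-8); the achieved
estimating-function norm is reported as `score_norm`.

**Degenerate thresholds.** In small trials some categories are empty; a
threshold whose cumulative indicator never varies cannot support a finite
intercept. Such intercepts are profiled out and reported as $\pm\infty$
with a flag, and the slopes remain estimable. Intercept monotonicity is
checked post-fit and warned about, not enforced — standard GEE practice.

**Testing and small-sample corrections.** `wald_treatment_test()` defaults
to the joint 5-coefficient treatment set $\{G, GP, GT_2, GT_3, GT_4\}$,
and `small_sample_correction()` offers the Mancl–DeRouen and
Kauermann–Carroll leverage adjustments (default `"none"`, i.e. the plain
sandwich). These defaults are kept for transparency, but they should not
be combined blindly: with 16 clusters the sandwich meat has rank at most
16, a 5-df quadratic form built on it rejects a true null about 40% of
the time, and uncorrected 1-df tests still reject at ~0.10. The harness
adapter `gee_method()` therefore defaults to the calibrated
configuration — the 1-df average treatment effect
(`ate_contrast()`: `G + G:P/2 + (G:T2 + G:T3 + G:T4)/4`, the
active-vs-placebo difference in the linear predictor averaged over
periods and occasions) with the Mancl–DeRouen correction — which brings
the type I error into the slightly-liberal range just above 5% that is
expected of GEE in small samples. This is the configuration used in the
package's own simulations.

One consequence worth stating plainly: when the injected effect is
uniform over all post-baseline occasions, this calibrated 1-df GEE test
is close to optimal and its power essentially matches the prioritized
GPC's; the GPC's large published-style advantage over GEE-type models
arises when the effect concentrates at the occasions the priority list
puts first — prioritization is exactly the mechanism by which the GPC
can be advantaged, a point the methodology literature itself makes. The
GPC's advantage over the ATS is robust in our emulation either way.

## The synthetic data generator

`generate_trial()` draws a latent Gaussian panel per subject — random
intercept (SD `subject_sd`) plus an AR(1) residual over the 8 occasions —
and pushes it through its own cdf and the marginal quantile function
(a Gaussian copula). The requested marginal therefore holds *exactly* at
every occasion while within-subject correlation decays with lag. Ordinal
outcomes use a 21-category pmf; counts use a negative-binomial marginal.

The default configuration is the package's standing emulation of the
motivating trial: 8 subjects per sequence, a zero-inflated pmf with 35%
of scores at 0 (mirroring the many pain-free baselines seen in practice),
latent autocorrelation 0.6 and a subject intercept of 0.8 latent SD. These
are emulation choices, not estimates from the deposited trial data, and
they are deliberately never tuned per analysis.

Treatment effects are *injected*, never generated: `permute_null()`
reassigns sequence labels across subjects with profiles intact — removing
any treatment association while preserving the longitudinal structure —
and `inject_effect()` modifies active-treatment observations at
post-baseline occasions only. The shift of 3 categories (1.5 VAS points)
and the thinning retention of 0.6 (a 40% average blister reduction, i.e.
an effect sitting exactly at the dichotomization boundary) are fixed
clinical-reasoning defaults; the corresponding settings of the companion
simulation studies are not printed in the source material, so no numerical
agreement with their published power values is claimed. What the package
reproduces is the *qualitative* findings: the prioritized unmatched GPC
outpowers both the ATS and the GEE Wald test on the ordinal alternative,
and dichotomizing counts costs the GPC substantial power.

What the generator does **not** emulate: carry-over effects (flagged in
the field as an open clinical issue, and deliberately absent so that the
permutation null is exact), missingness mechanisms (out of scope
package-wide), rater effects, and the empirical quirks of any specific
real trial. Passing tests therefore demonstrate internal validity of the
methods under a plausible emulation, not agreement with any particular
dataset.

## The simulation harness

`run_rejection_study()` applies all methods to the *same* replicate
datasets (paired comparison), derives per-replicate seeds from the master
seed before the loop (so adding a method never shifts the data stream),
excludes failed fits from that method's denominator with a reported
exclusion rate, and aborts if a method fails on more than 20% of
replicates. Proportions carry 95% Wilson score intervals — with 5000
replicates the Wilson interval matches the method-comparison CIs this
package is designed to reproduce to three decimals, which is also the
basis for treating 5000 as the reference replicate count. The packaged
simulations and tests use 400–2000 replicates so the full suite runs in
minutes; `n_sim` scales up trivially.

## MAP / empirical-Bayes individual prediction

Given a fitted mixed model (fixed effects $\beta$, random-effect
covariance $\Omega$) and one subject's data, `map_estimate()` minimizes

$$l_i(\beta, b_i, z_i) + b_i'\Omega^{-1} b_i + \log\det(2\pi\Omega),$$

i.e. $-2\times$ the log posterior kernel of $b_i$ under $b_i \sim
N(0,\Omega)$, with $l_i$ the conditional $-2$ log-likelihood. (A published
form of this objective *adds* the log prior density to $l_i$; taken
literally that would penalize prior-plausible values, so the standard MAP
sign convention is implemented and the discrepancy documented here rather
than followed.) Optimization is BFGS with analytic gradients where the
built-in specs provide them, multi-start (prior mode + 4 draws from
$N(0,\Omega)$, ties broken toward the smallest $\|b\|$), and a damped
Newton polish so the Gaussian case matches the closed-form BLUP to
machine precision. With no subject data the estimate is the prior mode 0 —
the population-typical prediction; estimation of $(\beta, \Omega)$
themselves is explicitly not this module's job.

## Problem sizes and tolerances used in the shipped checks

* GPC: exact agreement with exhaustive pair enumeration on 100 random
  trials of up to 10 subjects; Mann–Whitney identity on single-priority
  analyses.
* Permutation-null size of the GPC test and the ATS: 2000 replicates of
  the default emulation, rejection within $0.05 \pm 3\,\mathrm{SE}$.
* GEE: binary-collapse agreement with the logistic-GLM oracle to $10^{-5}$
  relative; estimating-function norm below $10^{-6}$ at every reported
  solution.
* MAP: BLUP agreement to $10^{-6}$ (achieved: machine precision).
* Power comparisons: 1000 replicates per scenario, 199 permutations per
  GPC test.

## Known limitations

* The GEE's hetero-AR(1) association is a working approximation with
  deliberate regularization; the association parameters themselves should
  not be interpreted as estimates of the data's correlation structure.
* The ATS implementation is specific to the complete 2 × 4 cross-over
  layout; general factorial layouts and the clustered-data extension with
  missing values are out of scope.
* No covariate adjustment beyond stratification (GPC) and the factorial
  structure itself; no imputation or weighting for missing data anywhere.
* Carry-over is neither generated nor modelled; in a real trial a wash-out
  argument has to come from the design.
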