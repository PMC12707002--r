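---
title: "Constructing and validating a gendered cultural context index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and validating a gendered cultural context index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcci)
```

## The problem

Cultural norms that restrict women's opportunities — early marriage,
exclusion from household decisions, normalised violence, curtailed
schooling — operate at the level of communities, not individuals.  A
woman's reproductive-health risks depend not only on her own attributes
but on the prevailing rules of the place she lives.  Measuring that
context has usually required country-level indices with heavy data
demands, useless for comparing small communities within one country.

This package builds a community-level index from the microdata of
standard family-health surveys (DHS-type designs).  Five binary
indicators are coded per ever-married woman:

| indicator | coded 1 when |
|---|---|
| child marriage | first cohabitation before age 18 |
| no decision-making power | sole/joint decider on **none** of four household decisions |
| wife-beating justifiable | beating endorsed for **any** of five listed reasons |
| physical violence (12m) | any listed act "sometimes"/"often" in the past 12 months |
| low education | highest schooling below secondary |

The violence item is asked only of a half-household subsample with its
own weights, a standard domestic-violence module design; the package
treats that asymmetry explicitly everywhere (aggregation, errors on
missingness, reweighting).

## The index model

Weighted prevalences of the five indicators are aggregated per community
(the sampling stratum, treated as an opaque grouping key).  Internal
consistency across communities is assessed with covariance-based
Cronbach's alpha.  The index itself is a one-factor principal-factor
(principal-axis) model on the 5×5 correlation matrix of the prevalence
columns:

* the diagonal is replaced by squared multiple correlations (SMC),
* the leading eigenpair of the reduced matrix gives loadings
  $\ell = \sqrt{\lambda_1}\,v_1$ (sign fixed so $\sum_k \ell_k > 0$:
  higher = more restrictive),
* uniqueness is $1-\ell_k^2$,
* regression (Thomson) scores use coefficients $R^{-1}\ell$ on
  column-standardized prevalences, giving scores with mean exactly zero
  and variance at most one.

Two conventions deserve a note because software differs on them.
First, extraction is non-iterated SMC principal factoring by default
(the common statistical-package default for this workflow); an iterated
option exists behind the `iterate` flag.  Second, the *proportion of
variance explained* divides $\lambda_1$ by the sum of the **positive**
eigenvalues of the reduced matrix, not by the number of items.  With a
strong single factor this proportion is large (70%+) even when
$\lambda_1 < K$; dividing by $K$ would understate it by roughly a third
and is not what principal-factor routines report.  With one factor,
orthogonal rotation is the identity, so rotated and unrotated loadings
coincide.

A loading below 0.3 triggers a warning but never an automatic drop:
item retention is a substantive judgement (an item can be kept for its
conceptual importance even when it weakens internal consistency, as the
violence item typically does), so the software only flags.

## Ordinal categories

For descriptive use, the continuous scores are partitioned into ordinal
categories by k-means.  Rather than seeded Lloyd iterations — whose
result depends on starting values and leaves tie-breaking ambiguous —
the package computes the **globally optimal** 1-D partition by dynamic
programming over interval splits of the sorted scores (optimal 1-D
clusters are contiguous).  The number of clusters is chosen over a
candidate range (default 3–5) by the Calinski–Harabasz pseudo-F

$$CH(k) = \frac{B_k/(k-1)}{W_k/(n-k)},$$

with $B_k + W_k$ equal to the total sum of squares; the largest value
wins, ties go to the smaller $k$, and a zero within-cluster dispersion
is reported as $+\infty$ with a warning.  Clusters are labelled in
ascending order of mean score — for $k=4$ with the conventional
vocabulary *least restrictive* < *less restrictive* < *restrictive* <
*most restrictive*, otherwise generically.  Equal scores are kept
together by stable ordering.

## Validation: inequality and variance decomposition

**Concentration index.**  For a binary risk $y$ with weighted mean
$\mu$, the Wagstaff concentration index is
$CI = \frac{2}{\mu}\mathrm{cov}(y_i, R_i)$, with $R_i$ the fractional
rank (cumulative population share below the group plus half its own
share) and the covariance population-weighted.  The bounded-outcome
correction divides by $1-\mu$.  Communities are ranked least→most
restrictive, so a risk concentrated in restrictive communities yields a
*positive* index; this matches the sign convention of published
risk-gradient tables (where e.g. cesarean delivery, concentrated in the
least restrictive communities, is the negative-signed exception).  A
`direction` flag reverses the ranking for users who prefer the
opposite convention, which simply negates the index.  The |CI| > 0.10
"high inequality" flag in the gradient table is a reporting heuristic
only.

**Multilevel ladder.**  A three-model random-intercept logistic ladder
for a clustered binary outcome (multiparity, five or more children, in
the default workflow): Model 1 null, Model 2 adds individual covariates
(age grand-mean centered; education, ref. less than secondary; wealth
quintile, ref. poorest; early marriage; experienced child death),
Model 3 adds the ordinal category (ref. most restrictive).  Fitting is
by adaptive Gauss–Hermite quadrature (via `lme4::glmer`; 12 nodes by
default, which leaves the log-likelihood stable to well under $10^{-3}$
against 15 nodes).  Reported per model: the level-2 variance
$\sigma^2_u$ with a delta-method standard error, the latent-scale ICC
$\sigma^2_u/(\sigma^2_u + \pi^2/3)$ — the convention in which the
level-1 residual is the standard-logistic variance, and the only one
consistent with published ICC arithmetic from printed variances — the
proportional change in variance against the preceding model, and the
likelihood-ratio test of Model 3 against Model 2.  The likelihood is
unweighted: survey weights serve descriptive representation, while the
variance decomposition is a model-based quantity.  A weighted
pseudo-likelihood is out of scope.

## The synthetic study

Because the motivating survey microdata are access-restricted, the
package carries a generator that emulates the design: 47 communities of
436 women (≈20,500 total), a 50% domestic-violence subsample with
reweighting, and a single latent community restrictiveness factor
$\eta_j \sim N(0,1)$ driving all five indicators,
$\Pr(\text{indicator}_k) = \mathrm{logit}^{-1}(a_k + b_k\eta_j)$.
Intercepts $a_k$ are solved numerically (40-node Gauss–Hermite) so the
*marginal* prevalences hit (0.21, 0.22, 0.17, 0.11, 0.36); loadings
$b_k = (0.55, 0.65, 0.80, 0.60, 0.75)$ were set once by delta-method
calibration so the between-community spread of each indicator is
realistic for a national survey of this design, and are overridable.

The outcome model decomposes the community effect into an
index-explainable part ($0.46\,\eta_j$) and an independent residual
intercept ($e_j$, SD 0.46), so the total latent-scale level-2 variance
is $0.46^2 + 0.46^2 \approx 0.42$ with a known explainable share of
50% — giving recovery tests a ground truth.  Covariate effects use
odds ratios typical for multiparity (1.14 per year of age, 2.81 for
early marriage, 4.99 for child death, graded education and wealth
effects); the outcome intercept −2.5 was calibrated once so marginal
multiparity is ≈11%.  Raw questionnaire responses (cohabitation age,
decision items, beating reasons, violence acts, schooling levels) are
back-filled consistently with the drawn indicators, so the coding rules
are exercised end-to-end; ages are nudged up where needed so
cohabitation cannot precede current age, leaving the age distribution
approximately uniform on 15–49.

What the generator does *not* emulate: nonresponse, household rosters,
within-community covariate clustering (age, wealth are independent of
$\eta_j$ by default), multi-factor norm structure, or informative
weights (weights are lognormal noise independent of everything).  A
passing test suite therefore shows the machinery is correct under a
one-factor world, not that any real country's norms are one-factor.
Notably, under the pure one-factor default the five prevalence columns
are far more correlated than real data (alpha ≈ 0.95+ versus ≈ 0.74
in practice); `indicator_noise_sd` adds indicator-specific community
noise for users who want that realism, but it is off by default so that
the generating model and the index model coincide exactly.

## Numerical choices and degenerate inputs

* Missing raw responses outside the DV design are errors, never
  imputed; a community with no DV rows is an error naming it.
* A constant prevalence column makes alpha and the factor model
  undefined → error.  An identity correlation matrix (all SMC zero) is
  reported as a degenerate factor solution.
* `k` above the number of distinct scores is an error; `k = n` gives
  zero within-SS; CH requires $1 < k < n$.
* Concentration index: $\mu \in \{0, 1\}$ is an error; the
  $|1-\mu|$ absolute value in some write-ups is vacuous for binary
  $\mu \in (0,1)$ and is implemented as $1-\mu$.
* Separation in the logit (|coefficient| > 15) and singular designs
  are errors naming the covariate.
* Aggregation weights must be strictly positive; prevalence is
  invariant to uniform weight rescaling.

Whether prevalence aggregation in the motivating workflow used survey
weights is not documented; weighted aggregation is the default here
(flagged in the docs), with `use_weights = FALSE` retained for exact
oracle checks.

## Problem sizes in the tests

The suite exercises the default 47-community fixture end-to-end
(including the full three-model ladder at 12 quadrature nodes), checks
the DP clustering against 1,000-restart Lloyd on 200 random datasets of
up to 60 points, recovers mixed-model parameters over 20 replicates of
a 100-cluster × 100-observation design, and sizes the likelihood-ratio
test over 500 small replicates (20 × 15).  These scales were chosen to
keep each property statistically informative while a full run stays in
the minutes range on a laptop.

## A worked run

```{r example, eval = FALSE}
d <- simulate_survey(sim_config())   # the default 47-community study
fit <- gcci(d)
summary(fit)

risk_gradient_table(d, fit$gccs, outcomes = "multiparity")
ladder <- model_ladder(d, fit$gccs)
ladder
```

`run_pipeline(pipeline_config())` performs the same chain and writes
every intermediate (prevalence matrix, alpha table, factor model, CH
diagnostics, assignment, risk gradient, model ladder, summary JSON) as
plain CSV/JSON so each stage can be audited or re-entered
independently.

## Known limitations

* One factor is assumed, not tested; no retention rules (scree,
  parallel analysis) are offered.
* No Erreygers-corrected index, CI decomposition, or dominance tests.
* No random slopes, cross-level interactions, or survey-weighted
  variance estimation in the multilevel stage.
* Cross-country comparability of the index values is explicitly not a
  goal; only the within-country ordering is meaningful.
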