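# gcci

Community-level measurement of restrictive gendered cultural context,
and its validation against reproductive-health inequality.

## What this is for

Health surveys of the DHS family record, for each ever-married woman,
whether she was married as a child, takes part in household decisions,
considers wife-beating justifiable, experienced recent physical
violence, and finished secondary school.  Researchers studying
structural determinants of women's health need those five signals
summarised *at the level of small communities* — a single continuous
index of how restrictive a community's gender norms are, an ordinal
categorisation of communities, and evidence that the index actually
stratifies health risks.  This package implements that workflow
end-to-end for epidemiologists and survey statisticians:

1. **Indicator coding** from raw questionnaire responses, with the
   domestic-violence half-sample design handled explicitly.
2. **Weighted community prevalences** of the five indicators.
3. **Cronbach's alpha** item analysis across communities.
4. **One-factor principal-factor model** (SMC communalities, regression
   scoring): the continuous index (GCCI), mean 0, variance ≤ 1, higher
   = more restrictive.  Loadings ℓ, uniqueness 1 − ℓ², scoring
   coefficients R⁻¹ℓ.
5. **Ordinal categories (GCCS)** by *exact* one-dimensional k-means
   (dynamic programming, no seeds) with the number of clusters chosen
   by the Calinski–Harabasz pseudo-F, CH(k) = (B_k/(k−1))/(W_k/(n−k)).
6. **Wagstaff concentration index** of binary risks across the ordered
   categories, CI = (2/μ)·cov(y, R) with fractional ranks R and the
   binary correction CI/(1−μ).
7. **Random-intercept logistic ladder** (null → individual covariates →
   + GCCS) with the latent-scale ICC σ²ᵤ/(σ²ᵤ + π²/3), proportional
   change in level-2 variance, and likelihood-ratio tests.

A calibrated synthetic survey generator (47 communities, ~20,500 women,
a latent community restrictiveness factor with a known explainable
variance share) makes the whole pipeline reproducible without access to
restricted microdata.

## A worked example

```r
library(gcci)
d   <- simulate_survey(sim_config())   # default synthetic study, seed 20210
fit <- gcci(d)                         # prevalences -> alpha -> factor -> clusters
fit
#> Gendered Cultural Context Index: 47 communities
#>   Cronbach's alpha 0.964; factor explains 99.9% of variance
#>   Scores: mean 5.5e-17, SD 0.993, range [-1.81, 2.64]
#>   Ordinal score: k = 5 clusters (pseudo-F 189.97)

risk_gradient_table(d, fit$gccs, outcomes = "multiparity")
#>       outcome level 1 of 5 level 2 of 5 level 3 of 5 level 4 of 5 level 5 of 5
#> 1 multiparity          4.8          8.4         10.5         12.6         16.5
#>   wagstaff_ci high_inequality
#> 1   0.2268896            TRUE
```

Reading the output: the factor scores place each community on a
restrictiveness continuum (mean exactly zero by construction of
regression scores).  Multiparity (five or more children) climbs from
4.8% of women in the least restrictive category to 16.5% in the most
restrictive, and the corrected concentration index of 0.23 — positive,
above the conventional 0.10 reporting threshold — says the burden is
concentrated in restrictive communities.  Under the pure one-factor
generator the five prevalence columns are nearly collinear, hence the
very high alpha and explained variance; real surveys sit much lower
(alpha ≈ 0.7), and `sim_config(indicator_noise_sd = ...)` can emulate
that.  `model_ladder(d, fit$gccs)` then quantifies how much of the
between-community outcome variance the categories explain (ICC and
PCV rows; on this fixture the GCCS removes roughly half of the level-2
variance, matching the generator's built-in 50% explainable share).

A thin command-line wrapper lives at `inst/cli/gcci.R`
(`simulate`, `index`, `inequality`, `multilevel`, `all` verbs);
`run_pipeline()` / `pipeline_config()` are the programmatic equivalent
and write every intermediate as plain CSV/JSON.

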