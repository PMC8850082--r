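---
title: "Oxidative balance scoring and survey-weighted telomere analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oxidative balance scoring and survey-weighted telomere analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxbal)
```

## The problem

Oxidative stress — a predominance of prooxidant over antioxidant exposure —
is one proposed driver of leukocyte telomere attrition. Because individual
nutrients or behaviours have weak and inconsistent marginal associations
with telomere length, a composite *oxidative balance score* (OBS) is used
instead: each of twenty dietary and lifestyle components contributes 0, 1
or 2 points, and a higher total indicates antioxidant predominance. This
package implements the full analytic chain for relating such a score to
leukocyte telomere length (LTL, measured as a qPCR T/S ratio) in a complex
survey sample: score construction, cohort exclusions, telomere replicate
quality control, survey-weighted regression, quartile/trend and sub-score
analyses, leave-one-component-out sensitivity analysis, and a synthetic
cohort generator with planted ground truth that makes every stage testable
without access to restricted survey data.

## The scoring model

Sixteen nutrient components come from a single 24-hour dietary recall
(fiber, carotene, riboflavin, niacin, vitamin B6, total folate, vitamin
B12, vitamin C, vitamin E, calcium, magnesium, zinc, copper, selenium as
antioxidants; total fat and iron as prooxidants) and four lifestyle
components complete the score (leisure-time physical activity as an
antioxidant; alcohol, body mass index and serum cotinine as prooxidants).
Each tertile-scored component is cut at its sex-specific tertiles
$(t_1, t_2)$: groups are $<t_1$, $[t_1, t_2)$ and $\ge t_2$. Antioxidants
score 0/1/2 from the lowest to the highest group, prooxidants 2/1/0.
Alcohol uses a fixed rule: nondrinkers (exactly 0 g/d) score 2, nonheavy
drinkers 1, and heavy drinkers ($\ge 30$ g/d for males, $\ge 15$ g/d for
females) 0. The total OBS therefore lies in $[0, 40]$ and decomposes
exactly into a dietary score ($[0, 32]$) plus a lifestyle score
($[0, 8]$).

Two design points deserve comment.

* **Reference cutpoints.** The packaged cutpoint table stores each
  boundary pair in ascending order and derives the point direction from
  the component's polarity, because only the combination of ascending
  boundaries and the inverse-assignment rule for prooxidants is
  self-consistent. Published scheme tables sometimes print prooxidant
  boundaries under the point columns in a visually reversed order; we
  treat that as typesetting, not as a different rule. Users can override
  the packaged boundaries with `compute_cutpoints()`, which recomputes
  sex-specific tertiles from the analytic sample (the right choice for a
  synthetic cohort or a new survey cycle).
* **Quantile definition.** All quantiles in the package — tertile
  cutpoints, OBS quartiles, weighted medians — use one step-function
  definition: the quantile at probability $p$ is the smallest observed
  value whose cumulative normalized weight is at least $p$, and a value
  equal to a cut belongs to the upper group. With equal weights this is
  the classic type-1 (inverse-ECDF) quantile. A consequence worth knowing:
  group sizes need not be perfectly equal on small discrete samples (for
  scores 1..8 the quartile groups are {1}, {2,3}, {4,5}, {6,7,8}); we
  prefer this honest step-function behaviour to interpolation because the
  scored variable is integer-valued and the cut must be an observable
  value.

## Cohort exclusions

`apply_exclusions()` applies, in order: (1) missingness in any OBS
component or model covariate, (2) age outside 20–84 (the upper ages are
top-coded at 85 in the emulated survey, and the analytic range is adults
20–84), (3) pregnancy, (4) dietary recall below minimum quality, (5)
implausible energy intake (male <800 or >4200 kcal/d, female <500 or
>3500 kcal/d; the bounds themselves are retained). The steps are
sequential with first-violation attribution, matching the semantics of an
attrition flowchart; a participant failing several criteria is counted
once. The pipeline is idempotent, and the missingness column list is
configurable.

## Telomere replicate quality control

Each DNA sample is assayed in duplicate wells on three days, nominally six
T/S values. Per sample, the largest and smallest values are marked as
potential outliers; the mean $m$ of the remaining values is computed; a
potential outlier $v$ is excluded when $|\log(m/v)| > 0.4$. Potential
outliers that pass are restored before the final mean and SD — restoring
is the reading we adopt of the usual "excluded from the calculation"
phrasing, and `restore_passing = FALSE` gives the stricter alternative.
The base of the logarithm in the 0.4 criterion is not fixed by convention;
we default to the natural log (symmetric-ratio criteria conventionally
are) and expose `log_base` so a base-10 reading is equally reproducible —
note the two readings genuinely differ (a factor 1.6 is excluded under
$\ln$, retained under $\log_{10}$). At most two values per sample can ever
be excluded, and the returned mean is scale-equivariant. Run-level QC
(`flag_runs()`) excludes an assay run when it has $\ge 8$ invalid control
wells or when more than 4 of its control DNA values fall outside 2.5
across-run standard deviations; both thresholds are exact, so a run with
exactly 4 out-of-band controls is retained.

## Survey-weighted estimation

Point estimates are weighted least squares with the examination-centre
analysis weights. Variance is the stratified ultimate-cluster Taylor
linearization: with per-PSU totals of weighted score contributions
$z_{hj} = \sum_{i \in \mathrm{PSU}\,hj} w_i x_i e_i$,

$$G = \sum_h \frac{n_h}{n_h - 1} \sum_j (z_{hj} - \bar z_h)(z_{hj} - \bar z_h)',
\qquad V = (X'WX)^{-1} G (X'WX)^{-1},$$

with design degrees of freedom (number of PSUs − number of strata) for the
t-based intervals and p-values. Strata with a single PSU are an error by
default (`lonely_psu = "fail"`); an explicit `"adjust"` mode centres such
strata at the grand mean of PSU totals. The estimator is validated in the
test suite against a closed-form WLS solution, an independently coded
loop-based implementation of the same formulas on a fixed 12-observation
design (agreement to 1e-10 relative), and the heteroscedasticity-robust
sandwich estimator in the degenerate one-PSU-per-observation case.

The four adjustment models are nested: Model 1 crude; Model 2 adds age
(continuous), ethnicity (five categories, non-Hispanic white reference),
education (five ordered categories entered as indicators) and the poverty
income ratio (three categories); Model 3 adds dietary energy (continuous);
Model 4 adds C-reactive protein (continuous, untransformed). The outcome
is the natural log of the T/S ratio throughout — natural rather than
common log because a typical T/S median of about 1.03 alongside a log mean
of about 0.03 is consistent only with $\ln$. The p for trend enters the
quartile index 1–4 as a single continuous term in the adjusted model
(`coding = "median"` substitutes within-quartile score medians). All
primary analyses are stratified by sex as separate model fits, not
interaction terms.

## Sensitivity and sub-scores

`run_sensitivity()` removes one component at a time, recomputes the
19-component total (range 0–38; no renormalization, since continuous-score
betas are compared on the per-point scale) and refits the fully adjusted
continuous-score model per sex — 40 rows. `run_subscore_analysis()` fits
the dietary (0–32) and lifestyle (0–8) scores as separate continuous
exposures under all four models.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of a four-year national health
and nutrition survey sample, not its joint distribution:

* **Design**: 14 strata × 2 PSUs by default, with inverse-inclusion
  probability weights that vary by stratum and age band (ages 20–39
  oversampled, 60–84 undersampled), so weighted and unweighted estimands
  genuinely differ and the design machinery is actually exercised.
* **Intakes**: each tertile-scored component is log-normal per sex with
  parameters chosen so the packaged reference cutpoints are the population
  tertiles; dietary components share a latent log-energy factor
  (correlation 0.5) because nutrient intakes scale with total intake.
  Energy itself is log-normal moment-matched to means ± SD of 2477 ± 781
  kcal/d (males) and 1818 ± 622 (females) and truncated to the plausible
  envelope so that only deliberately planted rows violate the energy
  criterion. Alcohol is zero-inflated (35%/55% nondrinkers by sex);
  cotinine is a nonsmoker/smoker log-normal mixture with a small
  below-detection point mass.
* **Outcome**: $\log(T/S) = \alpha_{sex} + \beta_{sex}(\mathrm{OBS}-20) +
  \gamma'(\text{centred covariates}) + u_{\mathrm{PSU}} +
  \varepsilon$, with residual SD 0.24 (matching the typical SD of
  log-transformed T/S in adult survey data), a small PSU-level intercept
  (SD 0.02), and the true OBS computed by the package's own scoring of
  the generated intakes against cutpoints recomputed from the generated
  sample. The default planted effect, 0.004 per OBS point in females and
  0 in males, is of the magnitude reported for continuous-OBS
  associations with log LTL, so power at realistic sample sizes is
  realistic.
* **Planted violations**: configurable rates of missingness, over-age,
  pregnancy, sub-minimum recalls and implausible energy, applied to
  disjoint rows after the outcome is built; the ground-truth record lists
  the affected row ids so attrition can be checked exactly.

What the generator deliberately does **not** emulate: the joint
correlation structure of real nutrient intakes beyond the shared energy
factor, measurement error in a single 24-hour recall, item-specific
missingness patterns, or any real geographic clustering. Passing tests on
synthetic cohorts therefore demonstrate that the *machinery* (scoring,
filtering, weighting, variance estimation) is correct under a known
truth — not that any substantive association in real data would be
reproduced.

## Calibration checks and problem sizes

The test suite runs two simulation studies sized to finish comfortably on
one CPU: parameter recovery and 95% interval coverage over 300 replicates
at n = 1600 with 14 strata (mean estimate within 10% of the planted
0.004; empirical coverage required in [0.93, 0.97]), and the type-I error
of the fully adjusted p-for-trend over 600 null replicates at n = 800
(rejection rate within a 99% Monte-Carlo band of 0.05). Property checks
(score decomposition, polarity flips, leave-one-out algebra, QC
equivariance) run on cohorts of a few hundred to ~1200 rows.

## Numerical choices and edge cases

* Weighted quantiles never interpolate; cuts are observed values.
* Tertile/quartile computation requires at least 3 (respectively 4)
  distinct values per sex and errors on degenerate distributions rather
  than silently producing empty groups.
* `survey_lm()` refuses singular weighted cross-products (collinearity)
  and lonely-PSU strata rather than falling back silently.
* Replicate QC with all values identical returns the common value and
  marks nothing.
* Exactly-at-boundary values: component value equal to $t_1$ scores the
  middle group; energy exactly at a plausibility bound is retained;
  alcohol exactly at the heavy threshold scores 0.
* Report tables format betas and confidence bounds to 4 decimal places;
  regeneration from the same fitted objects is bit-identical.

## Known limitations

Single-recall intakes are treated as error-free exposures; no supplement
or medication nutrients are included by construction; the baseline tables
are descriptive only (no design-based chi-squared or rank tests); and the
package makes no attempt to reproduce any published cohort's numeric
estimates, which would require the restricted-use source data.
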