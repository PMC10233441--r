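---
title: "Estimating healthy life years from survey-predicted activity limitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating healthy life years from survey-predicted activity limitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlyr)
```

## The problem

Life expectancy in low-mortality countries has outpaced *healthy* life
expectancy, and the size of the gap — years lived with activity
limitation — is a primary target of health policy. National
cross-sectional surveys measure limitation with a single question ("Do
you have any health problem which limits your daily activity?") together
with age, sex, and which of 40 diseases or injuries a respondent is
under treatment for. `hlyr` models the limitation outcome from those 42
features, converts age-specific predicted prevalence into healthy life
years (HLY) with Sullivan's method, and supports two applications:
counterfactual policy simulation (what happens to HLY if a disease's
prevalence is reduced to a target?) and an individual 0–100 health score
(HCAL).

This vignette records the modelling choices, the synthetic study
conditions the package is validated under, and what those validations do
and do not establish.

## The classifier

Activity limitation is a binary outcome with a realistic positive rate
around 13.5%, so the classifier and all resampling are stratified. The
learner is extreme gradient boosting (`xgboost`), the standard choice
for heterogeneous tabular survey features; age enters as a raw integer
(trees need no scaling), sex as an is-female indicator.

* **Splitting** uses a ceiling rule: the test partition holds
  `ceiling(N × fraction)` records, allocated across label strata by
  largest remainder. This makes printed subset sizes exactly
  reproducible from N (for example a 90/10 split of 1,537,773 records is
  1,383,995 / 153,778).
* **Recursive feature elimination** drops one feature per step by total
  gain and scores each feature count by stratified cross-validated
  AUROC; ties prefer the smaller set. Whether to score by CV or training
  AUROC was an open choice; CV was selected because training AUROC is
  monotonically optimistic in feature count.
* **Grid search** evaluates every configuration of a user-supplied grid
  by stratified k-fold CV AUROC, breaking ties toward fewer trees, then
  shallower depth. The shipped `default_search_grid()` is illustrative:
  5 tree counts × 4 depths × 3 learning rates × 2 minimum child weights
  × 2 maximum delta steps × 2 subsampling rates = 480 configurations,
  containing the default winning point of `default_hyperparameters()`
  (200 trees, depth 9, eta 0.1, min_child_weight 2, max_delta_step 5,
  subsample 0.5). No single axis decomposition is canonical; the grid is
  therefore fully configurable and only the shipped example is fixed.
* **Model complexity must match sample size.** The default
  hyperparameters suit a survey of over a million records. On the
  50,000-record synthetic populations used for validation, depth-9
  models visibly overfit (train–test AUROC gap, overconfident top
  calibration bins), and the package's own cross-validated grid search
  selects shallower settings that are both better-discriminating and
  well calibrated. The test suite and the acceptance script therefore
  let `grid_search()` choose complexity at that scale instead of
  hard-coding the full-scale defaults.
* **Determinism.** Training runs single-threaded with the RNG seeded and
  restored, so identical inputs and seeds give identical predictions.

## Evaluation surface

* AUROC uses the rank (Mann–Whitney) formulation with average ranks for
  ties; its confidence interval is a percentile bootstrap over 1,000
  class-stratified resamples (the CI method was unspecified upstream;
  percentile is the assumption-light default).
* Calibration uses 10 equal-width bins on [0, 1]; empty bins are
  omitted and bin counts always partition the sample.
* The cost-benefit cutoff scores threshold t by
  `cost(t) = (#FP − #FN)/n` and minimizes |cost|, ties to the smallest
  t, on a grid from 0 to 1 in steps of 0.01 (two-decimal granularity;
  finer grids change nothing on realistic sample sizes). At the optimum
  predicted prevalence ≈ observed prevalence, the property that matters
  when thresholded predictions feed a prevalence schedule.
* Permutation importance uses error = 1 − AUROC with 5 shuffles per
  feature (log loss was the alternative; AUROC matches the headline
  metric). Raw values below zero are clipped to 0 and the vector is
  normalized so the top feature scores exactly 1. Importances of
  features with tiny true effects sit inside permutation noise
  (±ca. 3·10⁻⁴ on 5,000 test rows with 5 repeats); rankings among such
  features are not meaningful, which is why the null-feature validation
  asserts "indistinguishable from zero, below every strong feature"
  rather than a total order over all 42 features.
* Exact TreeSHAP is out of scope; `mc_shapley()` provides a
  permutation-sampling Shapley estimate on the probability scale whose
  contributions satisfy the efficiency identity up to Monte-Carlo error.

## Sullivan's method

`build_life_table()` uses the standard abridged construction from
central death rates m_x: for a closed group of width n,
q_x = n·m_x / (1 + (n − a_x)·m_x) with a_x = n/2, except a_0 = 0.3 years
for a width-1 infant group (deaths in infancy cluster early); the open
terminal group has q = 1 and L = l/m. The default age scheme is the
conventional 0, 1–4, then five-year groups to 85+. With this fine
scheme, table e_0 agrees with a 200,000-lifetime microsimulation under
piecewise-constant hazards to well under 0.1 years; on deliberately
coarse groups (30–50-year widths) the a_x = n/2 approximation biases
e_0 by a few tenths of a year, which the test suite documents rather
than hides. HLY at age x is Σ_{y≥x} L_y (1 − π_y) / l_x, so HLY at
birth is linear in each π_x with slope −L_x/l_0 — a property tested
exactly.

The prevalence schedule π_x defaults to the **mean predicted
probability** per age group rather than the fraction above the cutoff:
mean probability is the unbiased plug-in for group prevalence under a
calibrated model, and the thresholded mode is kept for sensitivity
analysis. Empty age groups borrow from the nearest populated group with
a warning. Sexes, where needed, are handled by separate life tables and
schedules. Standard errors for Sullivan estimates are not computed.

## Policy scenarios and HCAL

A scenario maps diseases to target prevalence rates. The counterfactual
clears (or sets) the flag in a simple random sample of carriers
(non-carriers) of size `round(|p0 − p1|·N)`, achieving the target within
1/N while preserving population size and age structure — a requirement
of Sullivan's method that deleting or re-weighting rows would violate.
The change in HLY is reported as mean ± SD over 20 seeded repeats
(single-run results hide resampling noise). The fitted model is reused,
not retrained, in counterfactuals: the scenario changes exposure, not
the physiology linking exposure to limitation.

HCAL = 100 − 100·probability, an affine decreasing transform of risk.
The age curve fits a third-order polynomial by least squares to per-age
mean HCAL, with normal-approximation 95% intervals per age.

## The synthetic study conditions

Real national microdata cannot be shipped, so the generator defines the
study conditions under which everything is validated:

* **Ages** follow a mixture of uniform(0, 60) with weight 0.6 and
  triangular(60, 110, mode 75) with weight 0.4, discretized to integer
  years — an aged-population pyramid that keeps old-age strata populated
  (Sullivan's method is meaningless with empty elderly cells).
* **Sex** is Bernoulli with P(female) = 0.52.
* **Each disease flag** is Bernoulli(plogis(b + s·age + f·female)). Age
  slopes and female shifts are set by domain plausibility (strongly
  age-driven: dementia, hypertension, osteoporosis, prostatic
  hypertrophy; female-shifted: thyroid disease, osteoporosis, anemia;
  male-shifted: gout; effectively sex-restricted: pregnancy, prostatic
  hypertrophy), and each intercept b is solved by `uniroot()` so the
  marginal prevalence, integrated over the age/sex distribution, equals
  published Japanese national treatment rates (e.g. hypertension 13.4%,
  back pain 5.3%, dementia 0.7%).
* **The limitation label** is Bernoulli of a logistic linear predictor
  with a dominant age coefficient (0.055 per year), a small female shift
  (0.10), and per-disease log-odds largest for the conditions most
  tied to daily-activity limitation (mental disease, neurological
  disorders, stroke, fractures, arthritis, dementia). The intercept
  −6.675 was calibrated once, by Monte-Carlo integration of the
  generative model, so marginal limitation prevalence is ≈ 13.5%, the
  realistic class balance.
* The generator stores each record's true limitation probability, so
  the **Bayes AUROC** — the discrimination ceiling no classifier can
  beat — is computable and every fitted model can be compared to it.

What the generator deliberately does **not** emulate: disease flags are
conditionally independent given age and sex (no comorbidity clustering
beyond shared age/sex drivers), reporting is noiseless, and there is no
survey nonresponse or weighting. Consequently, passing validations show
the pipeline's arithmetic and statistical machinery are correct and that
the model recovers a known truth; they do not show that real survey data
satisfy the generator's independence assumptions, and real-data AUROC or
HLY levels will differ from the synthetic ones.

## Problem sizes and numerical choices

Validation uses 50,000-record populations (train 45,000 / test 5,000)
for parameter-recovery checks, 20,000 for policy simulations, 200,000
simulated lifetimes for life-table oracles, 1,000 bootstrap resamples
for CIs, and 100 random instances for brute-force threshold checks —
sizes at which binomial error bands are tight enough to be informative
while the full suite runs in about a minute. Percentages in descriptive
tables round half-up to one decimal (matching how printed survey tables
round; base R's round-half-even does not). Chi-square tests on 2×2
tables omit the Yates continuity correction so the statistic equals the
textbook formula exactly. Degenerate 2×2 tables (a variable present in
everyone) yield an undefined statistic and an NA significance flag
rather than an error. Probabilities are clipped to [10⁻¹⁵, 1 − 10⁻¹⁵]
before log loss.

## Known limitations

* Sullivan HLY standard errors are not implemented.
* Correlated comorbidity generation is not provided; scenarios that
  would rely on disease–disease dependence (e.g. treating one disease
  reducing another) cannot be expressed.
* The abridged q_x formula loses accuracy on age groups much wider than
  five years; use the standard scheme for quantitative work.
* The counterfactual mechanism assumes curing a disease removes exactly
  its conditional association with limitation; causal confounding in
  real data is untouched by resampling flags.
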