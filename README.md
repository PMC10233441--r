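# hlyr — healthy life years without activity limitation

`hlyr` estimates **healthy life years (HLY)** — expected years of life
free of self-reported activity limitation — from cross-sectional
health-survey records, and turns those estimates into policy and
individual-level tools. It is aimed at epidemiologists and public-health
analysts working with surveys shaped like the Japanese Comprehensive
Survey of Living Conditions: one row per respondent with age, sex, 40
binary flags for diseases or injuries under treatment, and a binary
answer to *"Do you have any health problem which limits your daily
activity?"*.

The pipeline has four stages:

1. **Classification.** A gradient-boosted tree classifier (xgboost)
   predicts the probability of activity limitation from the 42 features
   (age, sex, 40 diseases), with stratified 90/10 hold-out splitting,
   recursive feature elimination, and cross-validated grid search.
2. **Evaluation.** AUROC with a stratified percentile-bootstrap CI, log
   loss, a 10-bin reliability curve, confusion metrics, and a
   cost-benefit threshold: with false positives costing +1, false
   negatives −1 and correct calls 0, the cutoff minimizes
   |mean cost| = |#FP − #FN| / n, which makes predicted prevalence match
   observed prevalence. Feature impact is measured by permutation
   importance (increase in 1 − AUROC when a column is shuffled,
   normalized so the top feature is 1), with an optional Monte-Carlo
   Shapley attribution per record.
3. **Sullivan's method.** An abridged period life table
   (q_x = n·m_x / (1 + (n − a_x)·m_x), open terminal group closed by
   L = l/m) is combined with the age-specific prevalence schedule π_x of
   predicted limitation:

   HLY(x) = Σ_{y ≥ x} L_y (1 − π_y) / l_x.

4. **Application.** Policy scenarios resample disease prevalence to
   target rates (clearing flags in a random sample of carriers, so
   population size and age structure are preserved) and report the
   simulated change in HLY; the **HCAL index**
   (100 − predicted probability in %) scores individual health on a
   0–100 scale, with a cubic age curve.

Because national survey microdata are not distributable, the package
ships a synthetic-survey generator with a fully known logistic
ground-truth model (per-disease age/sex-dependent prevalence calibrated
to published national rates, limitation risk dominated by age). Every
stage is validated against this generator's analytic truth, including
the Bayes AUROC upper bound.

## Worked example

```r
library(hlyr)

cfg   <- generator_config(n_records = 20000, seed = 42)
pop   <- generate_population(cfg)
sp    <- split_records(pop, test_fraction = 0.10, seed = 42)
model <- fit_limitation_model(sp$train, seed = 42)

evaluate_model(model, sp$test, n_boot = 500, seed = 42)
#> <evaluation_report> n = 2000
#>   AUROC 0.933 (95% CI 0.920-0.947)   log loss 0.2073
#>   cost-benefit cutoff 0.34   sensitivity 0.684   specificity 0.950
#>   top features: age, back_pain, eye_disease, arthritis, depression_or_other_mental_disease

lt  <- generate_life_table()     # synthetic abridged life table, e_0 ~ 84
hly <- sullivan_hly(lt, prevalence_schedule(pop, values = predict_proba(model, pop)))
glance(hly)
#> # A tibble: 1 × 3
#>   hly_0   e_0 gap_0
#>   <dbl> <dbl> <dbl>
#> 1  77.6  84.0  6.38

simulate_policy_hly(pop, model, policy_scenario(c(back_pain = 0.026)), lt, seed = 42)
#> <policy_simulation>
#>   baseline HLY at birth: 77.63 years
#>   change in HLY: +0.256 years (SD 0.006 over 20 repeats)
```

Reading: the classifier separates limited from unlimited respondents
with AUROC 0.93 (close to the generator's Bayes bound, so almost all
learnable signal is captured). Weighting the life table by predicted
limitation prevalence gives 77.6 healthy life years at birth against a
life expectancy of 84.0 — a 6.4-year gap. Halving back-pain prevalence
to 2.6% is simulated to prolong HLY at birth by about a quarter of a
year.

Result objects have `tidy()` / `glance()` methods and `autoplot()`
displays (ROC, calibration, cost curve, importance, HCAL age curve, HLY
by age).

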