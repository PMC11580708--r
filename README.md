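# copdindices

Anemia-augmented multidimensional prognostic indices for hospitalized
COPD patients, with the statistical machinery to evaluate them.

## The problem

The BODEx index (BMI, airflow Obstruction, Dyspnea, severe
Exacerbations; range 0–9) and the ADO index (Age, Dyspnea, Obstruction;
range 0–10) summarize a COPD patient's mortality risk as a small integer
score. Anemia — hemoglobin < 12 g/dL in women or < 13 g/dL in men (WHO) —
is a strong independent predictor of death in patients admitted for COPD
exacerbation, yet neither index uses it. The augmented indices
**BODEx-A3** (0–12) and **ADO-A3** (0–13) add three points to the base
score when the patient is anemic at admission.

This package is for biostatisticians and respiratory researchers who want
to compute these scores on patient-level data and to test, on a cohort
with known one- and three-year vital status, whether the augmentation
improves discrimination. It provides:

* validated cohort records with CSV reading/writing (`read_cohort`,
  `write_cohort`, `classify_anemia`, `check_eligibility`);
* declarative scoring tables and score computation (`bodex_score`,
  `ado_score`, `augment_score`, `score_cohort`);
* from-scratch ROC analysis: Mann–Whitney AUC (mean over positive ×
  negative pairs of ψ = 1, ½, 0), empirical ROC curves, the Youden
  optimal cutpoint J = sensitivity + specificity − 1, and DeLong's
  placement-value test for comparing two correlated AUCs measured on the
  same patients (`auc`, `roc_curve`, `youden_cutpoint`, `delong_test`);
* a calibrated synthetic admission-cohort generator whose defaults
  emulate the study population these indices were evaluated on
  (n = 141, 24% anemia, 15%/34% mortality at 1/3 years), with mortality
  P(death) = logistic(α_h + 0.45·BODEx + 1.35·anemic) and intercepts
  found by bisection (`cohort_config`, `generate_cohort`,
  `calibrate_mortality`);
* an end-to-end pipeline that scores a cohort, evaluates all four
  indices at both horizons, compares base vs augmented with DeLong's
  test, and sweeps the anemia weight over 1–4 points (`run_analysis`,
  `sweep_anemia_points`).

See the methods vignette (`vignettes/copd-anemia-indices.Rmd`) for the
models, conventions and design choices.

## Worked example

```r
library(copdindices)

cohort <- generate_cohort(cohort_config(seed = 42))
summarize_cohort(cohort)[, c("characteristic", "value")]
#>                                 characteristic         value
#> 1                           Number of patients           141
#> 2                                  Age (years)  74.12 ± 9.27
#> 3                      Gender (female/male), n        27/114
#> ...
#> 9                    Anemia, n (% of patients)      35 (25%)
#> 10                           BODEx (range 0-9)   3.76 ± 1.73
#> 11                       BODEx-A3 (range 0-12)   4.50 ± 2.13
#> 15                    Mortality, 1 year, n (%)      20 (14%)
#> 16                   Mortality, 3 years, n (%)      43 (30%)

run_analysis(cohort)
#> Index evaluation on 141 patients (anemia weight 3)
#>
#> Discrimination per index and horizon:
#>     index horizon   auc cutpoint sensitivity specificity
#>     BODEx      1y 0.608        7       0.200       0.967
#>  BODEx-A3      1y 0.671        7       0.450       0.876
#>     BODEx      3y 0.655        4       0.698       0.531
#>  BODEx-A3      3y 0.729        6       0.535       0.816
#>       ADO      1y 0.498        4       0.950       0.099
#>    ADO-A3      1y 0.592        8       0.350       0.835
#>       ADO      3y 0.555        7       0.326       0.827
#>    ADO-A3      3y 0.658        7       0.581       0.745
#>
#> DeLong base vs augmented:
#>  index horizon auc_base auc_augmented     z p_value significant
#>  BODEx      1y    0.608         0.671 1.293  0.1960       FALSE
#>  BODEx      3y    0.655         0.729 2.070  0.0385        TRUE
#>    ADO      1y    0.498         0.592 1.601  0.1090       FALSE
#>    ADO      3y    0.555         0.658 2.375  0.0176        TRUE
#> ...
```

Reading the output: each `auc` is the probability that a randomly chosen
patient who died outscores a randomly chosen survivor; `cutpoint` is the
Youden-optimal "score ≥ c predicts death" threshold with its sensitivity
and specificity; the DeLong table tests, per index family and horizon,
whether the anemia-augmented AUC differs from the base AUC on the same
patients (here the three-year improvements of both families are
significant at α = 0.05 on this simulated cohort). `sweep_anemia_points()`
reports the AUC for anemia weights 1–4 and marks the best weight per
index and horizon.

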