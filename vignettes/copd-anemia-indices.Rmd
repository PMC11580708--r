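---
title: "Anemia-augmented prognostic indices for hospitalized COPD: methods"
author: "copdindices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anemia-augmented prognostic indices for hospitalized COPD: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copdindices)
```

## The clinical question

Multidimensional indices such as BODEx (BMI, airflow Obstruction, Dyspnea,
severe Exacerbations) and ADO (Age, Dyspnea, Obstruction) summarize a COPD
patient's prognosis as a small integer score; higher scores mean higher
mortality risk. Anemia — hemoglobin below the WHO sex-specific thresholds
of 12 g/dL (women) and 13 g/dL (men) — is a strong independent mortality
predictor in hospitalized COPD patients but is absent from both indices.
This package implements the anemia-augmented variants BODEx-A3 and ADO-A3,
which add three points to the base score when the patient is anemic at
admission, together with the full machinery to evaluate whether the
augmentation improves discrimination of death at fixed one- and three-year
horizons.

Outcomes are treated as fixed-horizon binary labels, not survival times:
the evaluation design assumes complete follow-up to three years, so no
censoring model is needed or provided.

## Scoring

The component point tables are data, not code: each component is a
`scoring_table()` partitioning the real line into half-open bins, and an
index is an `index_definition()` holding a list of components. The
defaults are the standard published tables, pinned by the attainable
ranges (BODEx 0–9, ADO 0–10):

| BODEx component | 0 | 1 | 2 | 3 |
|---|---|---|---|---|
| BMI (kg/m²) | > 21 | ≤ 21 | | |
| FEV1 (% predicted) | ≥ 65 | 50–64 | 36–49 | ≤ 35 |
| mMRC dyspnea | 0–1 | 2 | 3 | 4 |
| Severe exacerbations (prior year) | 0 | 1–2 | ≥ 3 | |

| ADO component | 0 | 1 | 2 | 3 | 4 | 5 |
|---|---|---|---|---|---|---|
| Age (years) | < 50 | 50–59 | 60–69 | 70–79 | 80–89 | ≥ 90 |
| mMRC dyspnea | 0–1 | 2 | 3 | | | |
| FEV1 (% predicted) | ≥ 65 | 36–64 | ≤ 35 | | | |

The printed integer category labels must extend to continuous
measurements, so bins are half-open: FEV1 falls in `[65, Inf)`, `[50,
65)`, `[36, 50)`, `(0, 36)` and BMI in `(21, Inf)` vs `(0, 21]`. This
makes the partition exact — every admissible value lands in exactly one
bin — and `enumerate_scores()` verifies by brute force that every total in
the published range is attainable (0–9, 0–10, and 0–12 / 0–13 with the
3-point augmentation).

`augmentation_rule(k)` adds `k` points when `classify_anemia()` is true.
Weights 0–4 are admitted: 0 makes the base index a special case of the
augmented one, and 1–4 is the range swept by `sweep_anemia_points()` when
asking which weight discriminates best. The anemia comparison is strict
(`Hb < 12.0` / `< 13.0`), so a woman at exactly 12.0 g/dL is not anemic.

## ROC analysis

All discrimination statistics are computed from first principles on the
Mann–Whitney kernel ψ(s⁺, s⁻) = 1, ½, 0 for s⁺ >, =, < s⁻:

* **AUC** is the mean of ψ over all positive–negative pairs, identical to
  the trapezoidal area under the empirical ROC curve (asserted to 1e−12
  in the test suite). Orientation is fixed — higher score = higher risk,
  positive class = dead — rather than auto-detected, which prevents
  silent curve flipping on pathological cohorts.
* **Candidate cutpoints** are the observed unique score values only
  (scores are small integers); the classification rule at cutpoint c is
  "score ≥ c predicts death".
* **Youden's cutpoint** maximizes J = sensitivity + specificity − 1 over
  the candidates. Ties in J are broken toward the *lowest* threshold: in
  prognostic screening the more sensitive rule is preferred. The
  convention is explicit and overridable (`ties = "highest"`).
* **DeLong's test** compares two correlated AUCs measured on the same
  patients. For each marker the per-positive placements V10ᵢ = meanⱼ
  ψ(sᵢ, sⱼ) and per-negative placements V01ⱼ are formed; S10 and S01 are
  their 2×2 empirical covariance matrices across positives (divisor m−1)
  and negatives (divisor n−1); then
  var(ΔAUC) = (S10ₐₐ + S10ᵦᵦ − 2·S10ₐᵦ)/m + (S01ₐₐ + S01ᵦᵦ − 2·S01ₐᵦ)/n
  and z = ΔAUC / √var is referred to the standard normal, two-sided, with
  no continuity correction. Identical score vectors give var = 0 with
  equal AUCs; that case degenerates benignly to z = 0, p = 1. A 95%
  normal confidence interval for the AUC difference is exposed as
  supplementary output.

Cohorts here are small (n ≈ 141) with integer scores, so the O(m·n)
placement matrices are formed explicitly; one transparent code path
yields the AUC, its variance, and the test statistic, and the test suite
cross-checks both AUC and the DeLong z/p against an independent
implementation (pROC) and against a paired permutation test.

## The synthetic cohort generator

No patient-level data accompany the indices' evaluation, so
`generate_cohort()` emulates the admission cohort the evaluation design
describes: 141 patients, 26/141 women, age 73 ± 10 (truncated 40–100),
BMI 27 ± 6, FEV1 46 ± 17% predicted, mMRC 2.2 ± 0.9 (rounded, clipped to
0–4), 49% with no severe exacerbation in the prior year and mean count
1.3 (zero-inflated: 0 with probability 0.49, else 1 + Poisson(λ) with λ
solved from the mean; the sd is approximate, not calibrated), pack-years
59 ± 27 (truncated ≥ 10), 24% anemic, and 15% / 34% mortality at one /
three years. Continuous fields use inverse-CDF truncated normal draws and
are rounded to clinically realistic precision (age and pack-years to
integers, the rest to one decimal), which also makes the CSV round-trip
bit-exact. FEV1/FVC has no published moments; it is drawn truncated
normal mean 48, sd 10 on [25, 69] so every record meets the obstruction
inclusion criterion. Smoking status (39% current smokers) is a cohort
descriptor only — it is not a record field and enters neither scoring nor
outcomes, so the config accepts it without using it.

Joint structure is deliberately minimal: covariates are independent
except hemoglobin (conditioned on anemia status and sex, each stratum a
truncated normal on the correct side of the WHO threshold) and mortality.
This is the simplest structure that makes every pipeline property
testable; real admission cohorts correlate age, FEV1, exacerbation
history and anemia, so passing tests demonstrate correctness of the
machinery, not clinical realism of any particular correlation.

### The mortality mechanism and its calibration

Death at horizon h follows a logistic model on the base index and anemia:

P(dead at h) = logistic(α_h + β_index · BODEx + β_anemia · anemic)

Defaults are β_index = 0.45 log-odds per point — consistent with
published per-point hazard ratios around 1.5 for these indices — and
β_anemia = 3 × β_index = 1.35: the augmented indices weight anemia as
three points, so the generator gives anemia exactly the weight the
3-point augmentation assumes. These were fixed once, on that reasoning.

The intercepts are calibrated by bisection so the *expected* mortality
over the covariate distribution (estimated on a 100,000-draw Monte-Carlo
sample, deterministic given the config seed) hits the 15% / 34% targets,
to a tolerance of 1e−4 on the proportion. With both betas zero the
closed form α_h = logit(target) is used directly. One-year deaths are a
subset of three-year deaths by construction — dead_3y ~ Bernoulli(p₃),
then dead_1y | dead_3y ~ Bernoulli(p₁/p₃) — which honors the
absorbing-death invariant exactly and preserves E[dead_1y] = E[p₁]
because α_1y < α_3y makes p₁ < p₃ pointwise.

Randomness uses one seed with deterministic per-field sub-streams
(a fixed hash of seed and field offset), so adding a field to the
generator does not perturb the draws of earlier fields.

## Numerical and design choices

* Half-open scoring bins (above); `findInterval()` does the placement, so
  boundary behavior is exact, not tolerance-based.
* Youden J ties compared with a 1e−12 guard; with integer scores and
  common denominators the comparison is effectively exact.
* Bisection for the calibration intercepts brackets on [−30, 30] and
  refuses targets unattainable under the configured betas.
* Required record fields are never imputed: a record missing a scoring or
  outcome field is rejected with its row number. Pack-years and FEV1/FVC
  are optional (reported by the cohort description but unused by scoring);
  missing values there produce eligibility *warnings*, not violations.
* Degenerate inputs: single-class outcome vectors give a horizon-level
  error (`run_analysis()` still reports the other horizon); an empty
  cohort round-trips as a header-only CSV; a one-patient summary flags
  the sd as undefined rather than reporting 0.

## Replication sizes used by the test suite

The suite verifies the stochastic properties at sizes chosen to give
stable verdicts at interactive runtimes: 1,000 random instances for the
AUC oracle equivalence, 200 simulated null cohorts of n = 141 for the
DeLong type-I error (accepted band 2–9% at α = 0.05), 50 replicate
cohorts for generator calibration (±2 percentage points on prevalence
and mortality), and 200 replicates for the anemia-effect recovery (the
augmented index must win at the 3-year horizon in ≥ 90% of them).

## Known limitations

* **Uninformative augmentation carries a noise penalty.** With
  β_anemia = 0 the anemia flag is pure noise, and adding ±3 noise points
  to a working index *lowers* AUC slightly on average (the test suite
  measures a mean difference near −0.04 at n = 141). The meaningful
  negative-control fact — the systematic positive gain disappears when
  the effect is absent — holds, but the difference is not centered on
  exactly zero; no augmentation of a score with an outcome-independent
  covariate can be AUC-neutral.
* The generator matches marginal moments only; joint correlations are
  configurable but default to independence.
* The original BODE (six-minute walk distance) and the updated 15-point
  ADO are out of scope; only BODEx and the original 10-point ADO are
  implemented.
* Cross-family comparisons (BODEx vs ADO) are computed as a report
  appendix but are supplementary to the base-vs-augmented question the
  package is organized around.
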