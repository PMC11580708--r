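# One synthetic patient row with overridable fields.
make_patient <- function(patient_id = "P0001", age = 73, sex = "male",
                         bmi = 27, fev1_pct = 46, fev1_fvc_ratio = 55,
                         mmrc = 2, severe_exacerbations_prior_year = 1,
                         pack_years = 59, hemoglobin = 14.5,
                         dead_1y = FALSE, dead_3y = FALSE) {
  data.frame(patient_id = patient_id, age = age, sex = sex, bmi = bmi,
             fev1_pct = fev1_pct, fev1_fvc_ratio = fev1_fvc_ratio,
             mmrc = mmrc,
             severe_exacerbations_prior_year = severe_exacerbations_prior_year,
             pack_years = pack_years, hemoglobin = hemoglobin,
             dead_1y = dead_1y, dead_3y = dead_3y,
             stringsAsFactors = FALSE)
}

make_toy_cohort <- function() {
  rbind(
    make_patient("P0001", age = 81, bmi = 19, fev1_pct = 30, mmrc = 4,
                 severe_exacerbations_prior_year = 3, hemoglobin = 11.2,
                 dead_1y = TRUE, dead_3y = TRUE),
    make_patient("P0002", age = 67, sex = "female", bmi = 24,
                 fev1_pct = 52, mmrc = 2, hemoglobin = 11.8,
                 dead_3y = TRUE),
    make_patient("P0003", age = 58, bmi = 31, fev1_pct = 68, mmrc = 1,
                 severe_exacerbations_prior_year = 0, hemoglobin = 15.1),
    make_patient("P0004", age = 74, sex = "female", bmi = 22,
                 fev1_pct = 44, mmrc = 3, hemoglobin = 13.4),
    make_patient("P0005", age = 70, bmi = 26, fev1_pct = 38, mmrc = 2,
                 severe_exacerbations_prior_year = 2, hemoglobin = 12.1,
                 dead_3y = TRUE)
  )
}

# O(m*n) brute-force Mann-Whitney AUC, the independent oracle for auc().
brute_force_auc <- function(scores, outcomes) {
  pos <- scores[outcomes]
  neg <- scores[!outcomes]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exhaustive-search Youden oracle over observed thresholds, lowest
# threshold on ties.
brute_force_youden <- function(scores, outcomes) {
  thresholds <- sort(unique(scores))
  best <- NULL
  for (c in thresholds) {  # ascending: later candidates only replace on
    sens <- mean(scores[outcomes] >= c)    # strictly larger J, so the
    spec <- mean(scores[!outcomes] < c)    # lowest threshold wins ties
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden_j + 1e-12) {
      best <- list(cutpoint = c, sensitivity = sens, specificity = spec,
                   youden_j = j)
    }
  }
  best
}
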