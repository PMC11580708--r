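# Index point tables are declarative data: each component maps one patient
# field onto integer points through a binned partition of the real line, so
# a corrected table changes data, not code.

#' Scoring table for one index component
#'
#' Defines the categorical point assignment for a single patient field as a
#' partition of the real line. With `right = FALSE` bins are half-open on
#' the right, `[breaks[i], breaks[i+1])`; with `right = TRUE` they are
#' half-open on the left, `(breaks[i], breaks[i+1]]`. `breaks` must start at
#' `-Inf` and end at `Inf` so every admissible value maps to exactly one
#' point value.
#'
#' @param component_name Label, e.g. `"fev1"`.
#' @param field Patient-record column the component scores.
#' @param breaks Increasing numeric vector of bin edges, from `-Inf` to
#'   `Inf`.
#' @param points Non-negative integer points, one per bin
#'   (`length(breaks) - 1`).
#' @param right Whether bins are right-closed (see above).
#' @return An object of class `scoring_table`.
#' @export
scoring_table <- function(component_name, field, breaks, points,
                          right = FALSE) {
  stopifnot(is.numeric(breaks), !is.unsorted(breaks, strictly = TRUE),
            breaks[1] == -Inf, breaks[length(breaks)] == Inf,
            length(points) == length(breaks) - 1,
            all(points >= 0), all(points %% 1 == 0))
  structure(list(component_name = component_name, field = field,
                 breaks = breaks, points = as.integer(points),
                 right = right),
            class = "scoring_table")
}

# Points for a vector of values under one scoring table.
apply_scoring_table <- function(table, values) {
  if (any(is.na(values))) {
    stop(sprintf("scoring error: field '%s' is missing", table$field),
         call. = FALSE)
  }
  bin <- findInterval(values, table$breaks, left.open = table$right,
                      rightmost.closed = FALSE)
  table$points[bin]
}

#' Index definition: a named set of scoring tables
#'
#' @param name Index name, e.g. `"BODEx"`.
#' @param components List of [scoring_table()] objects.
#' @return Object of class `index_definition` with `min_score` (sum of
#'   per-component minima, always 0) and `max_score` (sum of maxima).
#' @export
index_definition <- function(name, components) {
  stopifnot(all(vapply(components, inherits, TRUE, "scoring_table")))
  structure(list(
    name = name, components = components,
    min_score = sum(vapply(components, function(c) min(c$points), 0L)),
    max_score = sum(vapply(components, function(c) max(c$points), 0L))
  ), class = "index_definition")
}

#' The BODEx index definition
#'
#' Points for BMI (>21: 0; <=21: 1), airflow obstruction as FEV1 % predicted
#' (>=65: 0; 50-64: 1; 36-49: 2; <=35: 3), dyspnea on the mMRC scale
#' (0-1: 0; 2: 1; 3: 2; 4: 3), and severe exacerbations in the prior year
#' (0: 0; 1-2: 1; >=3: 2). Range 0-9. Continuous inputs are placed with
#' half-open bins: FEV1 in `[65,Inf) [50,65) [36,50) (0,36)` and BMI in
#' `(21,Inf)` vs `(0,21]`.
#'
#' @return An [index_definition()].
#' @export
bodex_index <- function() {
  index_definition("BODEx", list(
    scoring_table("bmi", "bmi", c(-Inf, 21, Inf), c(1, 0), right = TRUE),
    scoring_table("fev1", "fev1_pct", c(-Inf, 36, 50, 65, Inf),
                  c(3, 2, 1, 0), right = FALSE),
    scoring_table("dyspnea", "mmrc", c(-Inf, 1, 2, 3, Inf), c(0, 1, 2, 3),
                  right = TRUE),
    scoring_table("exacerbations", "severe_exacerbations_prior_year",
                  c(-Inf, 0, 2, Inf), c(0, 1, 2), right = TRUE)
  ))
}

#' The ADO index definition (original 10-point version)
#'
#' Points for age (<50: 0; 50-59: 1; 60-69: 2; 70-79: 3; 80-89: 4;
#' >=90: 5), dyspnea on the mMRC scale (0-1: 0; 2: 1; 3: 2; 4: 3), and
#' airflow obstruction as FEV1 % predicted (>=65: 0; 36-64: 1; <=35: 2).
#' Range 0-10.
#'
#' @return An [index_definition()].
#' @export
ado_index <- function() {
  index_definition("ADO", list(
    scoring_table("age", "age", c(-Inf, 50, 60, 70, 80, 90, Inf), 0:5,
                  right = FALSE),
    scoring_table("dyspnea", "mmrc", c(-Inf, 1, 2, 3, Inf), c(0, 1, 2, 3),
                  right = TRUE),
    scoring_table("fev1", "fev1_pct", c(-Inf, 36, 65, Inf), c(2, 1, 0),
                  right = FALSE)
  ))
}

#' Anemia augmentation rule
#'
#' The A-variant of an index adds a fixed number of points when the patient
#' is anemic (WHO criteria). The published variant uses 3 points (BODEx-A3,
#' ADO-A3); weights 0-4 are admitted so the base index is the special case
#' `anemia_points = 0` and the 1-4 sweep is expressible.
#'
#' @param anemia_points Integer in 0..4, default 3.
#' @return Object of class `augmentation_rule`.
#' @export
augmentation_rule <- function(anemia_points = 3) {
  stopifnot(length(anemia_points) == 1, anemia_points %% 1 == 0,
            anemia_points >= 0, anemia_points <= 4)
  structure(list(anemia_points = as.integer(anemia_points)),
            class = "augmentation_rule")
}

#' Score a cohort (or record) with an index
#'
#' @param cohort Data frame with the index's component fields.
#' @param index An [index_definition()].
#' @return Integer vector of base scores, one per row.
#' @export
score_index <- function(cohort, index) {
  stopifnot(inherits(index, "index_definition"))
  missing_fields <- setdiff(
    vapply(index$components, function(c) c$field, ""), names(cohort))
  if (length(missing_fields) > 0) {
    stop("scoring error: field(s) missing from cohort: ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  total <- integer(nrow(cohort))
  for (comp in index$components) {
    total <- total + apply_scoring_table(comp, cohort[[comp$field]])
  }
  total
}

#' BODEx score
#'
#' @param cohort Data frame with `bmi`, `fev1_pct`, `mmrc`,
#'   `severe_exacerbations_prior_year`.
#' @return Integer vector in 0..9.
#' @export
bodex_score <- function(cohort) score_index(cohort, bodex_index())

#' ADO score
#'
#' @param cohort Data frame with `age`, `mmrc`, `fev1_pct`.
#' @return Integer vector in 0..10.
#' @export
ado_score <- function(cohort) score_index(cohort, ado_index())

#' Augment a base score for anemia
#'
#' @param base_score Integer base index score(s).
#' @param anemic Logical anemia status, recycled against `base_score`.
#' @param rule An [augmentation_rule()].
#' @return `base_score + anemia_points` where anemic, else `base_score`.
#' @examples
#' augment_score(4, TRUE)   # 7
#' augment_score(4, FALSE)  # 4
#' @export
augment_score <- function(base_score, anemic, rule = augmentation_rule()) {
  stopifnot(inherits(rule, "augmentation_rule"), is.logical(anemic))
  base_score + rule$anemia_points * as.integer(anemic)
}

#' Score every patient of a cohort
#'
#' Computes the base index score, the WHO anemia flag, and (if a rule is
#' supplied) the anemia-augmented score, one row per patient in input
#' order.
#'
#' @param cohort Validated cohort data frame.
#' @param index An [index_definition()].
#' @param rule An [augmentation_rule()], or `NULL` for the base index only.
#' @return Data frame with columns `patient_id`, `base_index_name`,
#'   `base_score`, `anemic`, and (with a rule) `augmented_score`.
#' @export
score_cohort <- function(cohort, index = bodex_index(),
                         rule = augmentation_rule()) {
  base <- score_index(cohort, index)
  anemic <- if (nrow(cohort) > 0) {
    classify_anemia(cohort$hemoglobin, cohort$sex)
  } else logical(0)
  out <- data.frame(
    patient_id = as.character(cohort$patient_id),
    base_index_name = rep_len(index$name, nrow(cohort)),
    base_score = base,
    anemic = anemic,
    stringsAsFactors = FALSE
  )
  if (!is.null(rule)) out$augmented_score <- augment_score(base, anemic, rule)
  out
}

#' Enumerate all attainable scores of an index
#'
#' Brute-force enumeration over every combination of component bins,
#' optionally with the anemia augmentation; the consistency check that the
#' published ranges (BODEx 0-9, ADO 0-10, A3 variants 0-12 / 0-13) are
#' exactly attainable.
#'
#' @param index An [index_definition()].
#' @param rule Optional [augmentation_rule()]; when given, both anemia
#'   states are enumerated.
#' @return Sorted integer vector of all attainable total scores.
#' @export
enumerate_scores <- function(index, rule = NULL) {
  per_component <- lapply(index$components, function(c) unique(c$points))
  totals <- Reduce(function(a, b) unique(as.vector(outer(a, b, `+`))),
                   per_component, accumulate = FALSE, init = 0L)
  if (!is.null(rule)) {
    totals <- unique(c(totals, totals + rule$anemia_points))
  }
  sort(totals)
}
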