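#' @keywords internal
"_PACKAGE"

# Canonical column order of the cohort CSV schema. Empty string = missing,
# allowed only for the optional columns.
COHORT_COLUMNS <- c(
  "patient_id", "age", "sex", "bmi", "fev1_pct", "fev1_fvc_ratio",
  "mmrc", "severe_exacerbations_prior_year", "pack_years", "hemoglobin",
  "dead_1y", "dead_3y"
)

OPTIONAL_COLUMNS <- c("fev1_fvc_ratio", "pack_years")

#' Physiological bounds for cohort validation
#'
#' Admissible ranges for the numeric patient fields. Records outside these
#' bounds are rejected by [validate_cohort()]; they are deliberately wide,
#' catching data-entry errors rather than clinical outliers.
#'
#' @param age_min,age_max Age range in years.
#' @param bmi_min,bmi_max Body-mass index range in kg/m^2.
#' @param fev1_min,fev1_max FEV1 as percent of the reference value.
#' @param hb_min,hb_max Hemoglobin range in g/dL.
#' @return A named list of bounds.
#' @export
physiological_bounds <- function(age_min = 18, age_max = 110,
                                 bmi_min = 10, bmi_max = 70,
                                 fev1_min = 5, fev1_max = 150,
                                 hb_min = 3, hb_max = 22) {
  list(
    age = c(age_min, age_max), bmi = c(bmi_min, bmi_max),
    fev1_pct = c(fev1_min, fev1_max), hemoglobin = c(hb_min, hb_max)
  )
}

#' WHO anemia classification
#'
#' Classifies anemia from hemoglobin using the WHO sex-specific thresholds:
#' Hb < 12 g/dL in women, Hb < 13 g/dL in men. The comparison is strict, so
#' a woman with Hb exactly 12.0 g/dL is not anemic.
#'
#' @param hemoglobin Numeric vector, hemoglobin in g/dL; must be positive
#'   and finite.
#' @param sex Character vector, `"female"` or `"male"` (recycled against
#'   `hemoglobin` if length one).
#' @return Logical vector, `TRUE` where anemic.
#' @examples
#' classify_anemia(11.5, "female")  # TRUE
#' classify_anemia(12.5, c("male", "female"))  # TRUE, FALSE
#' @export
classify_anemia <- function(hemoglobin, sex) {
  if (!is.numeric(hemoglobin) || any(!is.finite(hemoglobin)) ||
      any(hemoglobin <= 0)) {
    stop("'hemoglobin' must be positive and finite (g/dL)", call. = FALSE)
  }
  sex <- normalize_sex(sex)
  n <- max(length(hemoglobin), length(sex))
  hemoglobin <- rep_len(hemoglobin, n)
  sex <- rep_len(sex, n)
  threshold <- ifelse(sex == "female", 12.0, 13.0)
  hemoglobin < threshold
}

# Accepts {f, m, female, male} case-insensitively; errors otherwise.
normalize_sex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  out <- ifelse(s %in% c("f", "female"), "female",
         ifelse(s %in% c("m", "male"), "male", NA_character_))
  if (anyNA(out)) {
    bad <- unique(sex[is.na(out)])
    stop("invalid sex value(s): ", paste(bad, collapse = ", "),
         " (expected female/male or F/M)", call. = FALSE)
  }
  out
}

#' Study eligibility rule
#'
#' Inclusion criteria for the hospitalized-COPD cohort: age at least 40
#' years, smoking history of at least 10 pack-years, and post-bronchodilator
#' FEV1/FVC below 70%.
#'
#' @param min_age Minimum age in years.
#' @param min_pack_years Minimum smoking exposure in pack-years.
#' @param max_fev1_fvc Upper (exclusive) FEV1/FVC bound in percent.
#' @return An object of class `eligibility_rule`.
#' @export
eligibility_rule <- function(min_age = 40, min_pack_years = 10,
                             max_fev1_fvc = 70) {
  stopifnot(min_age > 0, min_pack_years > 0, max_fev1_fvc > 0)
  structure(list(min_age = min_age, min_pack_years = min_pack_years,
                 max_fev1_fvc = max_fev1_fvc),
            class = "eligibility_rule")
}

#' Check a patient record against the eligibility rule
#'
#' Reports (never throws) inclusion-criteria violations for one record.
#' Missing optional fields (pack-years, FEV1/FVC) yield warnings, not
#' violations, since their criterion cannot be checked.
#'
#' @param record A one-row data frame or named list with at least `age`,
#'   and optionally `pack_years` and `fev1_fvc_ratio`.
#' @param rule An [eligibility_rule()].
#' @return A list with character vectors `violations` and `warnings`;
#'   an eligible record has `length(violations) == 0`.
#' @export
check_eligibility <- function(record, rule = eligibility_rule()) {
  stopifnot(inherits(rule, "eligibility_rule"))
  record <- as.list(record)
  violations <- character()
  warnings <- character()
  if (record$age < rule$min_age) {
    violations <- c(violations, sprintf(
      "age %s below minimum %s", format(record$age), format(rule$min_age)))
  }
  py <- record$pack_years
  if (is.null(py) || is.na(py)) {
    warnings <- c(warnings, "pack_years missing; smoking criterion unchecked")
  } else if (py < rule$min_pack_years) {
    violations <- c(violations, sprintf(
      "pack_years %s below minimum %s", format(py),
      format(rule$min_pack_years)))
  }
  ratio <- record$fev1_fvc_ratio
  if (is.null(ratio) || is.na(ratio)) {
    warnings <- c(warnings,
                  "fev1_fvc_ratio missing; obstruction criterion unchecked")
  } else if (ratio >= rule$max_fev1_fvc) {
    violations <- c(violations, sprintf(
      "fev1_fvc_ratio %s not below %s", format(ratio),
      format(rule$max_fev1_fvc)))
  }
  list(violations = violations, warnings = warnings)
}

#' Check every record of a cohort against the eligibility rule
#'
#' @param cohort A validated cohort data frame.
#' @param rule An [eligibility_rule()].
#' @return A list of [check_eligibility()] results, one per row.
#' @export
check_cohort_eligibility <- function(cohort, rule = eligibility_rule()) {
  lapply(seq_len(nrow(cohort)), function(i) {
    check_eligibility(cohort[i, , drop = FALSE], rule)
  })
}

#' Validate a cohort data frame
#'
#' Enforces the patient-record invariants: required columns present and
#' non-missing, numeric fields within physiological bounds, mMRC an integer
#' grade 0-4, exacerbation count a non-negative integer, and death absorbing
#' (dead at one year implies dead at three years). Column order is
#' normalized to the canonical CSV schema and `sex` to `"female"`/`"male"`.
#'
#' @param cohort A data frame with the cohort CSV columns.
#' @param bounds Bounds from [physiological_bounds()].
#' @return The validated, normalized cohort data frame (invisibly usable).
#' @export
validate_cohort <- function(cohort, bounds = physiological_bounds()) {
  cohort <- as.data.frame(cohort, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cohort <- cohort[, COHORT_COLUMNS]
  if (nrow(cohort) == 0) return(cohort)

  cohort$patient_id <- as.character(cohort$patient_id)
  cohort$sex <- normalize_sex(cohort$sex)
  for (col in c("dead_1y", "dead_3y")) {
    cohort[[col]] <- parse_outcome(cohort[[col]], col)
  }

  required_numeric <- c("age", "bmi", "fev1_pct", "mmrc",
                        "severe_exacerbations_prior_year", "hemoglobin")
  for (col in required_numeric) {
    v <- suppressWarnings(as.numeric(cohort[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0) {
      stop(sprintf("row %d: required field '%s' is missing or not numeric",
                   bad[1], col), call. = FALSE)
    }
    cohort[[col]] <- v
  }
  for (col in OPTIONAL_COLUMNS) {
    cohort[[col]] <- suppressWarnings(as.numeric(cohort[[col]]))
  }

  check_range <- function(col, lo, hi, what) {
    bad <- which(cohort[[col]] < lo | cohort[[col]] > hi)
    if (length(bad) > 0) {
      stop(sprintf("row %d: %s %s outside bounds [%s, %s]", bad[1], what,
                   format(cohort[[col]][bad[1]]), format(lo), format(hi)),
           call. = FALSE)
    }
  }
  check_range("age", bounds$age[1], bounds$age[2], "age")
  check_range("bmi", bounds$bmi[1], bounds$bmi[2], "bmi")
  check_range("fev1_pct", bounds$fev1_pct[1], bounds$fev1_pct[2], "fev1_pct")
  check_range("hemoglobin", bounds$hemoglobin[1], bounds$hemoglobin[2],
              "hemoglobin")

  bad <- which(cohort$mmrc %% 1 != 0 | cohort$mmrc < 0 | cohort$mmrc > 4)
  if (length(bad) > 0) {
    stop(sprintf("row %d: mmrc must be an integer grade in 0..4 (got %s)",
                 bad[1], format(cohort$mmrc[bad[1]])), call. = FALSE)
  }
  ex <- cohort$severe_exacerbations_prior_year
  bad <- which(ex %% 1 != 0 | ex < 0)
  if (length(bad) > 0) {
    stop(sprintf(
      "row %d: severe_exacerbations_prior_year must be a count >= 0",
      bad[1]), call. = FALSE)
  }
  bad <- which(cohort$dead_1y & !cohort$dead_3y)
  if (length(bad) > 0) {
    stop(sprintf(
      "row %d: dead_1y is true but dead_3y is false (death is absorbing)",
      bad[1]), call. = FALSE)
  }
  cohort
}

# Coerce {0,1,true,false,yes,no,TRUE,FALSE} to logical; NA not allowed.
parse_outcome <- function(x, col) {
  if (is.logical(x)) {
    v <- x
  } else {
    s <- tolower(trimws(as.character(x)))
    v <- ifelse(s %in% c("1", "true", "yes"), TRUE,
         ifelse(s %in% c("0", "false", "no"), FALSE, NA))
  }
  bad <- which(is.na(v))
  if (length(bad) > 0) {
    stop(sprintf(
      "row %d: outcome field '%s' must be one of 0/1/true/false/yes/no",
      bad[1], col), call. = FALSE)
  }
  as.logical(v)
}

#' Read a patient cohort from CSV
#'
#' Reads and validates a cohort file in the canonical schema (see
#' [write_cohort()]). Header names are matched case-insensitively; outcome
#' columns accept 0/1, true/false, or yes/no; empty cells are missing and
#' permitted only for the optional columns (`fev1_fvc_ratio`,
#' `pack_years`).
#'
#' @param path Path to a CSV file.
#' @param delimiter Field delimiter, default comma.
#' @param bounds Bounds passed to [validate_cohort()].
#' @return A validated cohort data frame, one row per patient.
#' @export
read_cohort <- function(path, delimiter = ",",
                        bounds = physiological_bounds()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(), quote = "\"",
                           comment.char = "")
  names(raw) <- tolower(trimws(names(raw)))
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("CSV schema error, missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, COHORT_COLUMNS]
  for (col in OPTIONAL_COLUMNS) raw[[col]][trimws(raw[[col]]) == ""] <- NA
  validate_cohort(raw, bounds)
}

#' Write a patient cohort to CSV
#'
#' Writes the canonical comma-delimited schema: `patient_id, age, sex, bmi,
#' fev1_pct, fev1_fvc_ratio, mmrc, severe_exacerbations_prior_year,
#' pack_years, hemoglobin, dead_1y, dead_3y`. Missing optional fields are
#' written as empty cells. `read_cohort(write_cohort(x))` reproduces `x`
#' field for field.
#'
#' @param cohort A validated cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- if (nrow(cohort) > 0) validate_cohort(cohort) else
    as.data.frame(stats::setNames(
      replicate(length(COHORT_COLUMNS), character(0), simplify = FALSE),
      COHORT_COLUMNS))
  out <- cohort
  if (nrow(out) > 0) {
    out$dead_1y <- as.integer(out$dead_1y)
    out$dead_3y <- as.integer(out$dead_3y)
    # as.character() on doubles is shortest round-trippable (R >= 4.3),
    # so read_cohort(write_cohort(x)) reproduces x bit for bit.
    for (col in names(out)) {
      if (is.numeric(out[[col]])) {
        v <- as.character(out[[col]])
        v[is.na(out[[col]])] <- ""
        out[[col]] <- v
      }
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
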