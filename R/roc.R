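# ROC machinery written directly on the Mann-Whitney kernel
# psi(s_pos, s_neg) = 1, 1/2, 0 for s_pos >, =, < s_neg. Cohorts here are
# small (n ~ 141, integer scores), so the O(m*n) placement matrices are
# formed explicitly; that keeps the AUC, its DeLong variance, and the test
# statistic all on one transparent code path.

check_two_classes <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes), is.logical(outcomes))
  if (any(is.na(scores)) || any(is.na(outcomes))) {
    stop("scores and outcomes must not contain missing values",
         call. = FALSE)
  }
  if (!any(outcomes) || all(outcomes)) {
    stop("AUC undefined: outcomes contain a single class", call. = FALSE)
  }
}

# psi matrix: rows positives, columns negatives.
placement_matrix <- function(pos, neg) {
  d <- sign(outer(pos, neg, `-`))
  (d + 1) / 2
}

#' Area under the ROC curve (Mann-Whitney AUC)
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counted one half; equals the trapezoidal area
#' under [roc_curve()]. Orientation is fixed: higher score = higher
#' predicted risk, positive class = dead.
#'
#' @param scores Numeric score vector.
#' @param outcomes Logical outcome vector (TRUE = event), same length.
#' @return AUC as a fraction in `[0, 1]`.
#' @examples
#' auc(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))  # 0.75
#' @export
auc <- function(scores, outcomes) {
  check_two_classes(scores, outcomes)
  mean(placement_matrix(scores[outcomes], scores[!outcomes]))
}

#' Empirical ROC curve
#'
#' Candidate thresholds are the unique observed score values, descending;
#' the classification rule at threshold `c` is "score >= c predicts the
#' event". The point list carries the endpoints `(0,0)` (threshold `Inf`)
#' and `(1,1)` (lowest observed score).
#'
#' @inheritParams auc
#' @return Object of class `roc_curve`: a list with `thresholds`, `points`
#'   (data frame of `threshold`, `fpr`, `tpr`), `n_pos`, `n_neg`, `auc`.
#' @export
roc_curve <- function(scores, outcomes) {
  check_two_classes(scores, outcomes)
  pos <- scores[outcomes]
  neg <- scores[!outcomes]
  thresholds <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thresholds, function(c) mean(pos >= c), 0)
  fpr <- vapply(thresholds, function(c) mean(neg >= c), 0)
  points <- data.frame(threshold = c(Inf, thresholds),
                       fpr = c(0, fpr), tpr = c(0, tpr))
  structure(list(thresholds = thresholds, points = points,
                 n_pos = length(pos), n_neg = length(neg),
                 auc = auc(scores, outcomes)),
            class = "roc_curve")
}

#' Trapezoidal area under a ROC curve
#'
#' @param curve A [roc_curve()].
#' @return The trapezoidal area; agrees with the Mann-Whitney [auc()] to
#'   floating tolerance.
#' @export
trapezoid_area <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  p <- curve$points
  sum(diff(p$fpr) * (utils::head(p$tpr, -1) + utils::tail(p$tpr, -1)) / 2)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d positives, %d negatives, AUC = %.4f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' Youden optimal cutpoint
#'
#' Among the observed candidate thresholds, returns the one maximizing
#' Youden's J = sensitivity + specificity - 1 under the "score >= cutpoint
#' predicts death" rule. Ties in J are broken toward the lowest threshold
#' (the most sensitive rule), the convention suited to prognostic
#' screening; override with `ties`.
#'
#' @param curve A [roc_curve()], or a numeric score vector (then
#'   `outcomes` is required).
#' @param outcomes Logical outcomes when `curve` is a score vector.
#' @param ties `"lowest"` (default) or `"highest"` threshold on a J tie.
#' @return A list of class `cutpoint_result`: `cutpoint`, `sensitivity`,
#'   `specificity`, `youden_j`.
#' @export
youden_cutpoint <- function(curve, outcomes = NULL, ties = c("lowest",
                                                             "highest")) {
  ties <- match.arg(ties)
  if (!inherits(curve, "roc_curve")) curve <- roc_curve(curve, outcomes)
  p <- curve$points[is.finite(curve$points$threshold), ]
  j <- p$tpr - p$fpr
  best <- which(j >= max(j) - 1e-12)
  pick <- if (ties == "lowest") best[which.min(p$threshold[best])] else
    best[which.max(p$threshold[best])]
  structure(list(cutpoint = p$threshold[pick],
                 sensitivity = p$tpr[pick],
                 specificity = 1 - p$fpr[pick],
                 youden_j = j[pick]),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(
    "Youden cutpoint >= %s: sensitivity %.3f, specificity %.3f, J = %.3f\n",
    format(x$cutpoint), x$sensitivity, x$specificity, x$youden_j))
  invisible(x)
}

# Placement values for one marker: V10 (per positive) and V01 (per
# negative).
placements <- function(scores, outcomes) {
  psi <- placement_matrix(scores[outcomes], scores[!outcomes])
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong's test for two paired (correlated) AUCs
#'
#' Nonparametric asymptotic comparison of the AUCs of two markers measured
#' on the same patients. Per-positive and per-negative placement values are
#' computed for each marker; their empirical covariance matrices (divisors
#' m-1 and n-1) give the variance of the AUC difference
#' `var_diff = (S10_aa + S10_bb - 2 S10_ab)/m + (S01_aa + S01_bb -
#' 2 S01_ab)/n`, and `z = (auc_a - auc_b)/sqrt(var_diff)` is referred to
#' the standard normal (two-sided, no continuity correction).
#'
#' When `var_diff` is zero with equal AUCs (e.g. identical score vectors)
#' the test degenerates benignly: `z = 0`, `p = 1`. Zero variance with
#' differing AUCs is an error.
#'
#' @param scores_a,scores_b Numeric score vectors for the two markers,
#'   aligned to the same patients.
#' @param outcomes Logical outcome vector (TRUE = event).
#' @param conf_level Level for the normal confidence interval on
#'   `auc_a - auc_b` (interval reported as supplementary output).
#' @return Object of class `delong_test`: `auc_a`, `auc_b`, `var_diff`,
#'   `z`, `p_value`, `conf_int`, `n_pos`, `n_neg`.
#' @export
delong_test <- function(scores_a, scores_b, outcomes, conf_level = 0.95) {
  stopifnot(length(scores_a) == length(scores_b))
  check_two_classes(scores_a, outcomes)
  check_two_classes(scores_b, outcomes)
  pa <- placements(scores_a, outcomes)
  pb <- placements(scores_b, outcomes)
  m <- sum(outcomes)
  n <- sum(!outcomes)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))  # divisor m - 1
  s01 <- stats::cov(cbind(pa$v01, pb$v01))  # divisor n - 1
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  var_diff <- max(var_diff, 0)
  delta <- pa$auc - pb$auc
  if (var_diff == 0) {
    if (abs(delta) > 1e-12) {
      stop("degenerate variance: AUCs differ but the placement variance ",
           "of the difference is zero", call. = FALSE)
    }
    z <- 0
  } else {
    z <- delta / sqrt(var_diff)
  }
  se <- sqrt(var_diff)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff,
                 z = z, p_value = 2 * stats::pnorm(-abs(z)),
                 conf_int = c(delta - q * se, delta + q * se),
                 conf_level = conf_level, n_pos = m, n_neg = n),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf(
    paste0("DeLong paired AUC comparison\n  AUC A = %.4f, AUC B = %.4f\n",
           "  z = %.4f, two-sided p = %.4g\n",
           "  %g%% CI for difference: [%.4f, %.4f]\n"),
    x$auc_a, x$auc_b, x$z, x$p_value, 100 * x$conf_level,
    x$conf_int[1], x$conf_int[2]))
  invisible(x)
}

#' Compare a base index with its anemia-augmented variant
#'
#' Scores the cohort with the base index and its A-variant, then reports
#' the discrimination of both against mortality at one horizon: AUCs,
#' Youden cutpoints with sensitivity and specificity, and the DeLong
#' paired comparison.
#'
#' @param cohort Validated cohort data frame.
#' @param index An [index_definition()].
#' @param rule An [augmentation_rule()].
#' @param horizon `"1y"` or `"3y"`; selects `dead_1y` or `dead_3y`.
#' @return One-row data frame with columns `index`, `horizon`, `auc_base`,
#'   `auc_augmented`, `cutpoint_base`, `sensitivity_base`,
#'   `specificity_base`, `cutpoint_augmented`, `sensitivity_augmented`,
#'   `specificity_augmented`, `z`, `p_value`.
#' @export
compare_indices <- function(cohort, index = bodex_index(),
                            rule = augmentation_rule(),
                            horizon = c("1y", "3y")) {
  horizon <- match.arg(horizon)
  outcomes <- if (horizon == "1y") cohort$dead_1y else cohort$dead_3y
  sc <- score_cohort(cohort, index, rule)
  dl <- delong_test(sc$augmented_score, sc$base_score, outcomes)
  cut_base <- youden_cutpoint(sc$base_score, outcomes)
  cut_aug <- youden_cutpoint(sc$augmented_score, outcomes)
  data.frame(
    index = index$name, horizon = horizon,
    auc_base = dl$auc_b, auc_augmented = dl$auc_a,
    cutpoint_base = cut_base$cutpoint,
    sensitivity_base = cut_base$sensitivity,
    specificity_base = cut_base$specificity,
    cutpoint_augmented = cut_aug$cutpoint,
    sensitivity_augmented = cut_aug$sensitivity,
    specificity_augmented = cut_aug$specificity,
    z = dl$z, p_value = dl$p_value,
    stringsAsFactors = FALSE
  )
}

#' Export ROC coordinates
#'
#' Writes the `(threshold, fpr, tpr)` coordinates of a ROC curve as CSV,
#' suitable for redrawing the curve.
#'
#' @param curve A [roc_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roc_coordinates <- function(curve, path) {
  stopifnot(inherits(curve, "roc_curve"))
  utils::write.csv(curve$points, path, row.names = FALSE)
  invisible(path)
}
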