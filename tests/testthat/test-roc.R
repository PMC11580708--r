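test_that("Mann-Whitney AUC matches brute-force pair counting", {
  scores <- c(3, 5, 1, 4)
  outcomes <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(auc(scores, outcomes), 0.75)  # pairs: 1, 0, 1, 1
  expect_equal(auc(scores, outcomes), brute_force_auc(scores, outcomes))

  expect_equal(auc(c(10, 9, 2, 1), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(auc(rep(4, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_error(auc(1:3, c(TRUE, TRUE, TRUE)), "single class")
  expect_error(auc(c(1, NA), c(TRUE, FALSE)), "missing")
})

test_that("AUC is invariant under strictly increasing transforms and
           complements under negation", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    scores <- sample(0:12, n, replace = TRUE)
    outcomes <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    a <- auc(scores, outcomes)
    expect_equal(auc(exp(scores / 3), outcomes), a)
    expect_equal(auc(-scores, outcomes), 1 - a)
  }
})

test_that("ROC curve is monotone with endpoints and trapezoid area = AUC", {
  curve <- roc_curve(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_s3_class(curve, "roc_curve")
  expect_equal(curve$points$fpr[1], 0)
  expect_equal(curve$points$tpr[1], 0)
  expect_equal(utils::tail(curve$points$fpr, 1), 1)
  expect_equal(utils::tail(curve$points$tpr, 1), 1)
  expect_true(all(diff(curve$points$fpr) >= 0))
  expect_true(all(diff(curve$points$tpr) >= 0))
  expect_equal(trapezoid_area(curve), 0.75, tolerance = 1e-12)

  # perfectly separated scores pass through (0, 1)
  perfect <- roc_curve(c(9, 8, 2, 1), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(any(perfect$points$fpr == 0 & perfect$points$tpr == 1))

  # binary score: three-point curve plus the (0,0) anchor
  binary <- roc_curve(c(1, 1, 0, 0, 1), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(nrow(binary$points), 3)
})

test_that("trapezoidal area equals Mann-Whitney AUC on random instances", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    scores <- sample(0:13, n, replace = TRUE) + rnorm(n, sd = 0.01)
    outcomes <- c(TRUE, FALSE, runif(n - 2) < 0.35)
    a <- auc(scores, outcomes)
    expect_equal(trapezoid_area(roc_curve(scores, outcomes)), a,
                 tolerance = 1e-12)
    expect_equal(a, brute_force_auc(scores, outcomes))
  }
})

test_that("AUC agrees with pROC on random instances", {
  skip_if_not_installed("pROC")
  set.seed(303)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    scores <- sample(0:13, n, replace = TRUE)
    outcomes <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    ref <- pROC::roc(outcomes, scores, levels = c(FALSE, TRUE),
                     direction = "<", quiet = TRUE)
    expect_equal(auc(scores, outcomes), as.numeric(pROC::auc(ref)))
  }
})

test_that("Youden cutpoint maximizes J with lowest-threshold tie-breaking", {
  scores <- c(3, 5, 1, 4)
  outcomes <- c(TRUE, TRUE, FALSE, FALSE)
  # thresholds 5 and 3 both attain J = 0.5; the most sensitive rule wins
  res <- youden_cutpoint(scores, outcomes)
  oracle <- brute_force_youden(scores, outcomes)
  expect_equal(res$cutpoint, 3)
  expect_equal(res$sensitivity, 1.0)
  expect_equal(res$specificity, 0.5)
  expect_equal(res$youden_j, 0.5)
  expect_equal(res[c("cutpoint", "sensitivity", "specificity", "youden_j")],
               oracle, ignore_attr = TRUE)
  # the opposite convention picks the specific end of the tie
  expect_equal(youden_cutpoint(scores, outcomes, ties = "highest")$cutpoint, 5)

  perfect <- youden_cutpoint(c(9, 8, 2, 1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$youden_j, 1)
  flat <- youden_cutpoint(rep(4, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(flat$youden_j, 0)
  expect_equal(flat$cutpoint, 4)
})

test_that("Youden selection matches exhaustive search on random instances", {
  set.seed(404)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    scores <- sample(0:13, n, replace = TRUE)
    outcomes <- c(TRUE, FALSE, runif(n - 2) < 0.35)
    res <- youden_cutpoint(scores, outcomes)
    oracle <- brute_force_youden(scores, outcomes)
    expect_equal(res$cutpoint, oracle$cutpoint)
    expect_equal(res$youden_j, oracle$youden_j)
  }
})

test_that("DeLong variance matches a hand-computed toy case", {
  # positives {1,2}, negatives {3,4}; placements computed by hand:
  # V10_a = (1/2, 1), V01_a = (1, 1/2); V10_b = (1/2, 1), V01_b = (1/2, 1)
  # S10: var 1/8 each, cov 1/8; S01: var 1/8 each, cov -1/8
  # var_diff = (1/8 + 1/8 - 2/8)/2 + (1/8 + 1/8 + 2/8)/2 = 1/4
  outcomes <- c(TRUE, TRUE, FALSE, FALSE)
  res <- delong_test(c(3, 5, 1, 4), c(2, 4, 3, 1), outcomes)
  expect_equal(res$auc_a, 0.75)
  expect_equal(res$auc_b, 0.75)
  expect_equal(res$var_diff, 0.25)
  expect_equal(res$z, 0)
  expect_equal(res$p_value, 1)
})

test_that("DeLong test degenerates benignly on identical scores", {
  scores <- c(5, 3, 8, 1, 4, 2)
  outcomes <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  res <- delong_test(scores, scores, outcomes)
  expect_equal(res$z, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$var_diff, 0)
})

test_that("DeLong z is antisymmetric under swapping the two markers", {
  set.seed(505)
  for (i in 1:25) {
    n <- 40
    latent <- rnorm(n)
    outcomes <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    a <- latent + rnorm(n)
    b <- latent + rnorm(n)
    fwd <- delong_test(a, b, outcomes)
    rev <- delong_test(b, a, outcomes)
    expect_identical(fwd$z, -rev$z)
    expect_identical(fwd$p_value, rev$p_value)
    expect_true(fwd$var_diff >= 0)
  }
})

test_that("DeLong z and p agree with pROC's implementation", {
  skip_if_not_installed("pROC")
  set.seed(606)
  for (i in 1:15) {
    n <- sample(25:60, 1)
    latent <- rnorm(n)
    outcomes <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    a <- latent + rnorm(n)
    b <- latent + rnorm(n)
    mine <- delong_test(a, b, outcomes)
    ra <- pROC::roc(outcomes, a, levels = c(FALSE, TRUE), direction = "<",
                    quiet = TRUE)
    rb <- pROC::roc(outcomes, b, levels = c(FALSE, TRUE), direction = "<",
                    quiet = TRUE)
    ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    expect_equal(mine$z, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("DeLong p is consistent with a paired permutation test", {
  set.seed(707)
  n <- 20
  latent <- rnorm(n)
  outcomes <- c(TRUE, FALSE, runif(n - 2) < 0.5)
  a <- latent + rnorm(n)
  b <- latent + rnorm(n)
  observed <- auc(a, outcomes) - auc(b, outcomes)
  n_perm <- 10000
  exceed <- 0
  for (k in seq_len(n_perm)) {
    swap <- runif(n) < 0.5
    pa <- ifelse(swap, b, a)
    pb <- ifelse(swap, a, b)
    delta <- auc(pa, outcomes) - auc(pb, outcomes)
    if (abs(delta) >= abs(observed) - 1e-12) exceed <- exceed + 1
  }
  p_perm <- exceed / n_perm
  p_delong <- delong_test(a, b, outcomes)$p_value
  # asymptotic vs exact resampling: agreement to Monte-Carlo resolution
  expect_lt(abs(p_delong - p_perm), 0.1)
})

test_that("index comparison emits the full evaluation row", {
  cohort <- generate_cohort(cohort_config(seed = 21))
  row <- compare_indices(cohort, bodex_index(), augmentation_rule(3), "3y")
  expect_equal(nrow(row), 1)
  expect_true(all(c("auc_base", "auc_augmented", "cutpoint_base",
                    "sensitivity_augmented", "z", "p_value") %in%
                    names(row)))
  expect_true(row$auc_base >= 0 && row$auc_base <= 1)

  # identity augmentation gives identical columns and p = 1
  id <- compare_indices(cohort, bodex_index(), augmentation_rule(0), "3y")
  expect_equal(id$auc_base, id$auc_augmented)
  expect_equal(id$p_value, 1)
})

test_that("ROC coordinates export as threshold/fpr/tpr CSV", {
  curve <- roc_curve(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_roc_coordinates(curve, path)
  back <- utils::read.csv(path)
  expect_identical(names(back), c("threshold", "fpr", "tpr"))
  expect_equal(nrow(back), nrow(curve$points))
})
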