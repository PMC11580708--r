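test_that("BODEx scoring matches the published point table", {
  expect_equal(bodex_score(make_patient(bmi = 20, fev1_pct = 30, mmrc = 4,
    severe_exacerbations_prior_year = 4)), 9)
  expect_equal(bodex_score(make_patient(bmi = 27, fev1_pct = 70, mmrc = 1,
    severe_exacerbations_prior_year = 0)), 0)
  expect_equal(bodex_score(make_patient(bmi = 27, fev1_pct = 46, mmrc = 2,
    severe_exacerbations_prior_year = 1)), 4)  # 0 + 2 + 1 + 1
})

test_that("ADO scoring matches the published point table", {
  expect_equal(ado_score(make_patient(age = 92, mmrc = 4, fev1_pct = 30)), 10)
  expect_equal(ado_score(make_patient(age = 45, mmrc = 0, fev1_pct = 70)), 0)
  expect_equal(ado_score(make_patient(age = 73, mmrc = 2, fev1_pct = 46)), 5)
})

test_that("continuous component bins are half-open as documented", {
  fev1_pts <- function(x) bodex_score(make_patient(
    bmi = 30, fev1_pct = x, mmrc = 0, severe_exacerbations_prior_year = 0))
  expect_equal(vapply(c(65, 64.9, 50, 49.9, 36, 35.9), fev1_pts, 0),
               c(0, 1, 1, 2, 2, 3))
  bmi_pts <- function(x) bodex_score(make_patient(
    bmi = x, fev1_pct = 80, mmrc = 0, severe_exacerbations_prior_year = 0))
  expect_equal(vapply(c(21, 21.1), bmi_pts, 0), c(1, 0))
  age_pts <- function(x) ado_score(make_patient(
    age = x, mmrc = 0, fev1_pct = 80))
  expect_equal(vapply(c(49, 50, 59, 60, 79, 80, 89, 90, 101), age_pts, 0),
               c(0, 1, 1, 2, 3, 4, 4, 5, 5))
  ado_fev1 <- function(x) ado_score(make_patient(
    age = 45, mmrc = 0, fev1_pct = x))
  expect_equal(vapply(c(65, 64.9, 36, 35.9), ado_fev1, 0), c(0, 1, 1, 2))
})

test_that("anemia augmentation adds the configured points only when anemic", {
  expect_equal(augment_score(4, TRUE), 7)
  expect_equal(augment_score(4, FALSE), 4)
  expect_equal(augment_score(9, TRUE), 12)
  expect_equal(augment_score(10, TRUE), 13)
  expect_equal(augment_score(5, TRUE, augmentation_rule(0)), 5)
  expect_error(augmentation_rule(5))
  expect_error(augmentation_rule(-1))
})

test_that("augmentation is monotone in base score and anemia weight", {
  for (k in 0:4) {
    rule <- augmentation_rule(k)
    aug <- augment_score(0:10, TRUE, rule)
    expect_true(all(diff(aug) > 0))
    expect_true(all(aug >= augment_score(0:10, FALSE, rule)))
    if (k > 0) {
      expect_true(all(aug > augment_score(0:10, TRUE,
                                          augmentation_rule(k - 1))))
    }
  }
})

test_that("enumeration over all bin combinations attains the printed ranges", {
  expect_identical(enumerate_scores(bodex_index()), 0:9)
  expect_identical(enumerate_scores(ado_index()), 0:10)
  expect_identical(enumerate_scores(bodex_index(), augmentation_rule(3)),
                   0:12)
  expect_identical(enumerate_scores(ado_index(), augmentation_rule(3)),
                   0:13)
  expect_equal(bodex_index()$max_score, 9)
  expect_equal(ado_index()$max_score, 10)
  expect_equal(bodex_index()$min_score, 0)
})

test_that("cohort scoring is order-invariant and ignores unrelated fields", {
  cohort <- validate_cohort(make_toy_cohort())
  sc <- score_cohort(cohort, bodex_index(), augmentation_rule(3))
  expect_equal(nrow(sc), nrow(cohort))
  expect_identical(sc$augmented_score,
                   sc$base_score + 3L * as.integer(sc$anemic))

  perm <- c(3, 1, 5, 2, 4)
  sc_perm <- score_cohort(cohort[perm, ], bodex_index(), augmentation_rule(3))
  expect_identical(sc_perm$base_score, sc$base_score[perm])

  altered <- cohort
  altered$pack_years <- altered$pack_years + 40  # not a BODEx component
  altered$age <- altered$age + 5                 # not a BODEx component
  expect_identical(score_cohort(altered, bodex_index())$base_score,
                   sc$base_score)
})

test_that("cohort scoring handles degenerate cohorts", {
  empty <- validate_cohort(make_toy_cohort())[0, ]
  expect_equal(nrow(score_cohort(empty, bodex_index())), 0)

  no_anemia <- validate_cohort(make_toy_cohort())
  no_anemia$hemoglobin <- 15
  sc <- score_cohort(no_anemia, ado_index(), augmentation_rule(3))
  expect_identical(sc$augmented_score, sc$base_score)

  missing_field <- make_patient()
  missing_field$mmrc <- NA
  expect_error(score_cohort(missing_field, bodex_index()), "mmrc")
})

test_that("custom scoring tables validate their structure", {
  expect_error(scoring_table("x", "age", c(0, 10, Inf), c(0, 1)))   # no -Inf
  expect_error(scoring_table("x", "age", c(-Inf, 10, Inf), c(0, 1, 2)))
  expect_error(scoring_table("x", "age", c(-Inf, 10, Inf), c(0, -1)))
  tab <- scoring_table("x", "age", c(-Inf, 10, Inf), c(0, 2))
  idx <- index_definition("toy", list(tab))
  expect_equal(idx$max_score, 2)
  expect_identical(enumerate_scores(idx), c(0L, 2L))
})
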