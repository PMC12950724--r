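test_that("PG-SGA bands classify every boundary score correctly", {
  cases <- list(
    list(score = 0, category = "well", mal = FALSE),
    list(score = 1, category = "well", mal = FALSE),
    list(score = 2, category = "mild", mal = TRUE),
    list(score = 3, category = "mild", mal = TRUE),
    list(score = 4, category = "moderate", mal = TRUE),
    list(score = 8, category = "moderate", mal = TRUE),
    list(score = 9, category = "severe", mal = TRUE),
    list(score = 25, category = "severe", mal = TRUE))
  for (cs in cases) {
    d <- classify_pgsga(cs$score)
    expect_equal(d$category, cs$category, info = paste("score", cs$score))
    expect_equal(d$malnourished, cs$mal, info = paste("score", cs$score))
  }
  expect_equal(classify_pgsga(2)$subgroup, "possibly_moderate")
  expect_equal(classify_pgsga(8)$subgroup, "possibly_moderate")
  expect_equal(classify_pgsga(9)$subgroup, "severe")
  expect_error(classify_pgsga(-1), "nonnegative")
})

test_that("ESPEN conditions fire per the consensus definition", {
  # C2 via the under-70 BMI cutoff with 3-month loss
  d <- diagnose_espen(make_record(age = 65, bmi = 19.0, wl_3mo_pct = 6,
                                  wl_any_time_pct = 6))
  expect_true(d$malnourished)
  expect_true("C2" %in% d$triggered_rules)
  # C1 alone
  d <- diagnose_espen(make_record(bmi = 17.9))
  expect_true(d$malnourished)
  expect_equal(d$triggered_rules, "C1")
  # nothing can fire
  expect_false(diagnose_espen(make_record(bmi = 24))$malnourished)
  # C3 via FFMI with sex-specific cutoffs
  d <- diagnose_espen(make_record(sex = "female", bmi = 21,
                                  wl_any_time_pct = 12, ffmi = 14.5))
  expect_equal(d$triggered_rules, "C3")
  d <- diagnose_espen(make_record(sex = "male", bmi = 21,
                                  wl_any_time_pct = 12, ffmi = 16.5))
  expect_equal(d$triggered_rules, "C3")
  # male cutoff is 17, not 15
  d <- diagnose_espen(make_record(sex = "male", bmi = 21,
                                  wl_any_time_pct = 12, ffmi = 15.5))
  expect_equal(d$triggered_rules, "C3")
})

test_that("ESPEN BMI boundaries are sharp at 18.5, 20 and 22", {
  wl <- list(wl_3mo_pct = 6, wl_any_time_pct = 6)
  run <- function(bmi, age) {
    diagnose_espen(do.call(make_record,
                           c(wl, list(bmi = bmi, age = age))))$malnourished
  }
  expect_true(diagnose_espen(make_record(bmi = 18.49))$malnourished)   # C1
  expect_false(diagnose_espen(make_record(bmi = 18.5))$malnourished)
  expect_true(run(19.99, age = 60))
  expect_false(run(20.0, age = 60))
  expect_true(run(21.99, age = 70))   # >= 70 uses the 22 cutoff
  expect_false(run(22.0, age = 70))
  expect_false(run(21.0, age = 69.5)) # < 70 still on the 20 cutoff
})

test_that("ESPEN weight-loss thresholds are strictly greater-than", {
  run <- function(...) diagnose_espen(make_record(bmi = 19, ...))$malnourished
  expect_false(run(wl_3mo_pct = 5.0, wl_any_time_pct = 5.0))
  expect_true(run(wl_3mo_pct = 5.01, wl_any_time_pct = 5.01))
  expect_false(run(wl_any_time_pct = 10.0))
  expect_true(run(wl_any_time_pct = 10.01))
})

test_that("negative screen gates ESPEN and GLIM to well-nourished", {
  r <- make_record(nrs_positive = FALSE, bmi = 15, wl_6mo_pct = 20,
                   wl_3mo_pct = 15, wl_any_time_pct = 25, ffmi = 12,
                   muscle_reduced_anthro = TRUE, reduced_intake = TRUE)
  expect_false(diagnose_espen(r)$malnourished)
  expect_false(diagnose_glim(r)$malnourished)
  expect_error(diagnose_espen(make_record(nrs_positive = NA)), "nrs_positive")
})

test_that("GLIM requires one phenotypic plus one etiologic criterion", {
  # weight loss + cancer inflammation
  d <- diagnose_glim(make_record(wl_6mo_pct = 7))
  expect_true(d$malnourished)
  expect_equal(d$category, "moderate")
  # phenotypic without any etiology: no diagnosis
  d <- diagnose_glim(make_record(wl_6mo_pct = 7, has_cancer = FALSE))
  expect_false(d$malnourished)
  # etiology without phenotype: no diagnosis
  expect_false(diagnose_glim(make_record(reduced_intake = TRUE))$malnourished)
  # low BMI for age >= 70 uses the 20 cutoff
  d <- diagnose_glim(make_record(age = 75, bmi = 19.5))
  expect_true(d$malnourished)
  expect_equal(d$category, "moderate")
  expect_true("severity-default" %in% d$triggered_rules)
  # under 70 the same BMI is not low
  expect_false(diagnose_glim(make_record(age = 69, bmi = 19.5))$malnourished)
  # muscle mass by either route
  expect_true(diagnose_glim(make_record(muscle_reduced_anthro = TRUE))$malnourished)
  expect_true(diagnose_glim(make_record(sex = "female", ffmi = 14))$malnourished)
})

test_that("GLIM severity grading is sharp at 5/10/20% weight loss", {
  cat_of <- function(...) diagnose_glim(make_record(...))$category
  expect_equal(cat_of(wl_6mo_pct = 5.0), "well")      # > 5 is strict
  expect_equal(cat_of(wl_6mo_pct = 5.01), "moderate")
  expect_equal(cat_of(wl_6mo_pct = 9.99), "moderate")
  expect_equal(cat_of(wl_6mo_pct = 10.0), "severe")   # >= 10 severe
  expect_equal(cat_of(wl_6mo_pct = 12), "severe")
  expect_equal(cat_of(wl_beyond_6mo_pct = 10.0), "well")  # > 10 strict
  expect_equal(cat_of(wl_beyond_6mo_pct = 10.01), "moderate")
  expect_equal(cat_of(wl_beyond_6mo_pct = 19.99), "moderate")
  expect_equal(cat_of(wl_beyond_6mo_pct = 20.0), "severe")
})

test_that("every GLIM-malnourished patient is exactly one of moderate/severe", {
  spec <- cohort_spec(n_patients = 400, seed = 42)
  coh <- generate_mechanistic_cohort(spec)
  panel <- apply_all(coh$records)
  mal <- panel$glim == 1
  expect_true(all(panel$glim_category[mal] %in% c("moderate", "severe")))
  expect_true(all(panel$glim_category[!mal] == "well"))
})

test_that("missing optional fields warn rather than error", {
  d <- diagnose_espen(make_record(bmi = 21, wl_any_time_pct = 12,
                                  ffmi = NA))
  expect_false(d$malnourished)
  expect_true(any(grepl("ffmi-missing", d$warnings)))
  d <- diagnose_glim(make_record(ffmi = NA, muscle_reduced_anthro = NA))
  expect_false(d$malnourished)
  expect_true(any(grepl("P3-not-evaluable", d$warnings)))
})

test_that("diagnoses are deterministic and apply_all panels line up", {
  r <- make_record(bmi = 19, wl_3mo_pct = 6, wl_any_time_pct = 6,
                   pgsga_score = 4, wl_6mo_pct = 6)
  d1 <- diagnose_glim(r); d2 <- diagnose_glim(r)
  expect_identical(d1, d2)
  rec <- as.data.frame(r, stringsAsFactors = FALSE)
  panel <- apply_all(rec)
  expect_identical(panel$pgsga, 1L)
  expect_identical(panel$espen, 1L)
  expect_identical(panel$glim, 1L)
  # all-negative record
  panel0 <- apply_all(as.data.frame(make_record(), stringsAsFactors = FALSE))
  expect_equal(unlist(panel0[c("pgsga", "espen", "glim")]),
               c(pgsga = 0L, espen = 0L, glim = 0L))
})

test_that("mode imputation fills with the most frequent value, smallest on ties", {
  t1 <- mode_impute(data.frame(x = c(1, 1, 2, NA)))
  expect_equal(t1$x, c(1, 1, 2, 1))
  t2 <- mode_impute(data.frame(x = c(1, 1, 2, 2, NA)))
  expect_equal(t2$x[5], 1)   # tie broken to the smaller value
  t3 <- mode_impute(data.frame(x = c("b", "b", "a", "a", NA)))
  expect_equal(t3$x[5], "a")
  expect_error(mode_impute(data.frame(x = c(NA, NA)), "x"), "x")
  # observed cells untouched
  df <- data.frame(x = c(3, NA, 3, 7), y = c(NA, TRUE, TRUE, FALSE))
  out <- mode_impute(df)
  expect_equal(out$x[c(1, 3, 4)], c(3, 3, 7))
  expect_equal(out$y[1], TRUE)
  expect_false(anyNA(out))
})
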