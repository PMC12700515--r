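test_that("invalid truths are rejected with the violated field named", {
  expect_error(simulation_truth(ar1_rho = 1), "ar1_rho")
  expect_error(simulation_truth(random_intercept_sd = -1),
               "random_intercept_sd")
  expect_error(simulation_truth(intercept_slope_corr = 1.2),
               "intercept_slope_corr")
  expect_error(simulation_truth(n_patients = 2,
                                followup_months_per_patient = c(3, 40)),
               "followup")
  expect_error(simulation_truth(
    missingness = list(window_drop_prob = 1.3, nonwear_day_prob = 0,
                       month_visit_miss_prob = 0)),
    "window_drop_prob")
  expect_error(simulation_truth(fixed_slopes = data.frame(
    phenotype = "not_a_phenotype", dimension = "positive", slope = 1)),
    "fixed_slopes")
})

test_that("generation is deterministic and partitioned per patient", {
  tr <- simulation_truth(n_patients = 3, followup_months_per_patient = c(2, 1, 2),
                         seed = 99)
  b1 <- generate_cohort(tr, level = "windows")
  b2 <- generate_cohort(tr, level = "windows")
  expect_identical(b1$windows, b2$windows)
  expect_identical(b1$clinical, b2$clinical)

  tr4 <- simulation_truth(n_patients = 4,
                          followup_months_per_patient = c(2, 1, 2, 3),
                          seed = 99)
  b4 <- generate_cohort(tr4, level = "windows")
  keep <- b4$windows$patient_id %in% unique(b1$windows$patient_id)
  expect_identical(b1$windows, b4$windows[keep, ])
})

test_that("total window-level missingness empties the month", {
  tr <- simulation_truth(n_patients = 1, followup_months_per_patient = 1,
                         missingness = list(window_drop_prob = 1,
                                            nonwear_day_prob = 0,
                                            month_visit_miss_prob = 0),
                         seed = 4)
  b <- generate_cohort(tr, level = "windows")
  expect_equal(nrow(b$windows), 0)
})

test_that("degenerate noise-free scores equal the fixed intercept exactly", {
  tr <- simulation_truth(
    n_patients = 4, followup_months_per_patient = rep(3, 4),
    fixed_intercepts = c(positive = 10, negative = 10,
                         cognitive_disorganization = 10,
                         depression_anxiety = 10, excitement_hostility = 10),
    fixed_slopes = data.frame(phenotype = character(0),
                              dimension = character(0), slope = numeric(0)),
    random_intercept_sd = 0, random_slope_sd = 0, residual_sd = 0,
    seed = 2)
  b <- generate_cohort(tr, level = "monthly")
  for (d in panss_dimensions()) expect_true(all(b$clinical[[d]] == 10))
})

test_that("rho = 0 yields uncorrelated within-patient residual steps", {
  tr <- simulation_truth(
    n_patients = 500, followup_months_per_patient = rep(20, 500),
    fixed_slopes = data.frame(phenotype = character(0),
                              dimension = character(0), slope = numeric(0)),
    random_intercept_sd = 0, ar1_rho = 0, residual_sd = 5,
    fixed_intercepts = c(positive = 50, negative = 50,
                         cognitive_disorganization = 50,
                         depression_anxiety = 50, excitement_hostility = 50),
    missingness = list(window_drop_prob = 0, nonwear_day_prob = 0,
                       month_visit_miss_prob = 0),
    seed = 8)
  b <- generate_cohort(tr, level = "monthly")
  cl <- b$clinical[order(b$clinical$patient_id, b$clinical$month_index), ]
  r <- cl$positive - 50
  lag_ok <- cl$patient_id[-1] == cl$patient_id[-nrow(cl)]
  r1 <- r[-1][lag_ok]; r0 <- r[-nrow(cl)][lag_ok]
  expect_lt(abs(cor(r0, r1)), 0.05)  # ~9500 patient-month pairs
})

test_that("planted AR(1) correlation is recovered in the residual stream", {
  tr <- simulation_truth(
    n_patients = 300, followup_months_per_patient = rep(20, 300),
    fixed_slopes = data.frame(phenotype = character(0),
                              dimension = character(0), slope = numeric(0)),
    random_intercept_sd = 0, ar1_rho = 0.6, residual_sd = 5,
    fixed_intercepts = c(positive = 50, negative = 50,
                         cognitive_disorganization = 50,
                         depression_anxiety = 50, excitement_hostility = 50),
    missingness = list(window_drop_prob = 0, nonwear_day_prob = 0,
                       month_visit_miss_prob = 0),
    seed = 8)
  cl <- generate_cohort(tr, level = "monthly")$clinical
  cl <- cl[order(cl$patient_id, cl$month_index), ]
  r <- cl$positive - 50
  lag_ok <- cl$patient_id[-1] == cl$patient_id[-nrow(cl)]
  expect_equal(cor(r[-nrow(cl)][lag_ok], r[-1][lag_ok]), 0.6,
               tolerance = 0.05)
})

test_that("daily sleep:wake ratios track the configured schedule", {
  tr <- simulation_truth(n_patients = 17,
                         followup_months_per_patient = rep(2, 17),
                         missingness = no_missing, seed = 13)
  b <- generate_cohort(tr, level = "windows")
  days <- day_summaries(b$windows)
  expect_gte(nrow(days), 1000)
  expect_equal(mean(days$sleep_wake_ratio),
               tr$sleep_hours_mean / tr$wake_hours_mean, tolerance = 0.02)
})

test_that("missing phenotype columns and non-finite values are data errors", {
  tr <- simulation_truth(n_patients = 2, followup_months_per_patient = c(2, 2),
                         seed = 3)
  b <- generate_cohort(tr, level = "monthly")
  bad <- b$monthly
  bad$rmssd_sleep_mean[1] <- NaN
  expect_error(simulate_panss_from_lmm(bad, tr), "non-finite")
  expect_error(simulate_panss_from_lmm(bad[, 1:3], tr), "absent")
})

test_that("cohort artifacts round-trip to plain-text files", {
  tr <- simulation_truth(n_patients = 2, followup_months_per_patient = c(1, 1),
                         seed = 5)
  b <- generate_cohort(tr, level = "windows")
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  expect_true(all(file.exists(file.path(dir, c("windows.csv", "clinical.csv",
                                               "monthly_latent.csv",
                                               "truth.json")))))
  w <- utils::read.csv(file.path(dir, "windows.csv"), nrows = 5)
  expect_match(w$window_start[1], "^2020-.*Z$")
  tr_back <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(tr_back$seed, 5)
})
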