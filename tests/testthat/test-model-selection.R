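# Drives the 3-step selection on cohorts with known planted structure.

planted_truth <- function(seed, slope_per_sd = 1.2, ...) {
  simulation_truth(
    n_patients = 30, followup_months_per_patient = rep(8, 30),
    fixed_slopes = default_fixed_slopes(slope_per_sd)[4, ],  # acc_ste_sleep_mean -> depression
    missingness = no_missing, seed = seed, ...)
}

test_that("step-1 screen retains a strongly planted pair and applies both gates", {
  tab <- monthly_table(planted_truth(5))
  traces <- step1_screen(tab, phenotypes = c("acc_ste_sleep_mean",
                                             "gyro_ste_wake_sd"),
                         dimensions = c("depression_anxiety", "positive"))
  expect_length(traces, 4)
  hit <- traces[["acc_ste_sleep_mean.depression_anxiety"]]
  expect_true(hit$step1$retained)
  expect_lt(hit$step1$fit$p_values[["acc_ste_sleep_mean"]], 0.05)
  expect_gte(hit$step1$fit$f2, 0.01)
  # a non-retained pair records its failing gate(s)
  misses <- traces[names(traces) != "acc_ste_sleep_mean.depression_anxiety"]
  miss_reasons <- unlist(lapply(misses, function(tr)
    if (!tr$step1$retained) tr$step1$reasons))
  expect_gt(length(miss_reasons), 0)

  # all-missing and constant phenotype columns are skipped with a reason
  tab$gyro_ste_wake_sd <- NA_real_
  tab$rmssd_wake_sd <- 1
  tr2 <- step1_screen(tab, phenotypes = c("gyro_ste_wake_sd", "rmssd_wake_sd"),
                      dimensions = "positive")
  expect_match(tr2[[1]]$skipped, "missing")
  expect_match(tr2[[2]]$skipped, "variance")
})

test_that("the completed trace is internally consistent and auditable", {
  tab <- monthly_table(planted_truth(11))
  traces <- step1_screen(tab, phenotypes = "acc_ste_sleep_mean",
                         dimensions = "depression_anxiety")
  tr <- select_best_model(traces[[1]], tab)
  expect_true(tr$best_model %in% c("random_intercept", "autocorrelation",
                                   "random_slope",
                                   "autocorrelation_plus_random_slope"))
  # best-model label consistent with the recorded LRT p-values at alpha=.05
  p2 <- tr$step2$lrt$p_value
  p3 <- if (!is.null(tr$step3$lrt)) tr$step3$lrt$p_value else NA
  expected <- if (is.finite(p3) && p3 < 0.05) {
    if (p2 < 0.05 || tr$fallback) "autocorrelation_plus_random_slope"
    else "random_slope"
  } else if (p2 < 0.05) "autocorrelation" else "random_intercept"
  expect_equal(tr$best_model, expected)
  fe <- tr$final_fixed_effect
  expect_true(all(is.finite(c(fe$estimate, fe$se, fe$t, fe$df, fe$p))))
  # audit trail suffices to recompute the step-2 comparison
  expect_equal(tr$step2$lrt$statistic,
               max(0, tr$step1$fit$minus2_loglik -
                     tr$step2$fit$minus2_loglik), tolerance = 1e-8)
  expect_error(select_best_model(structure(list(step1 = list(retained = FALSE),
                                                phenotype = "a",
                                                dimension = "b"),
                                           class = "selection_trace"), tab),
               "not retained")
})

test_that("retained sets are invariant to row shuffling", {
  tab <- monthly_table(planted_truth(21))
  phs <- c("acc_ste_sleep_mean", "nn_count_wake_mean", "rmssd_sleep_sd")
  dims <- c("depression_anxiety", "negative")
  s1 <- selection_summary(step1_screen(tab, phs, dims))
  set.seed(1)
  tab_shuf <- tab[sample(nrow(tab)), ]
  s2 <- selection_summary(step1_screen(tab_shuf, phs, dims))
  expect_equal(s1$retained, s2$retained)
  expect_equal(s1$step1_p, s2$step1_p, tolerance = 1e-8)
})

test_that("covariate screening detects a planted group shift and skips degenerate input", {
  hits <- 0L
  reps <- 12L
  for (r in seq_len(reps)) {
    tab <- monthly_table(planted_truth(300 + r))
    # plant a between-patient shift of ~1.5 patient-SD on one phenotype
    shift <- ifelse(tab$gender == "male", 0.35 * mean(tab$gyro_ste_wake_mean), 0)
    tab$gyro_ste_wake_mean <- tab$gyro_ste_wake_mean + shift
    sc <- screen_covariates(tab, "gender", phenotypes = "gyro_ste_wake_mean",
                            dimensions = character(0))
    if (sc$results$significant[[1]]) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.8)

  tab$const_cov <- 1
  sc2 <- screen_covariates(tab, "const_cov", phenotypes = "gyro_ste_wake_mean",
                           dimensions = character(0))
  expect_match(sc2$results$skipped[[1]], "variance")
  expect_false(sc2$results$significant[[1]])

  # factor with >= 3 levels goes through an F test
  set.seed(2)
  tab$site <- sample(c("a", "b", "c"), nrow(tab), replace = TRUE)
  sc3 <- screen_covariates(tab, "site", phenotypes = "gyro_ste_wake_mean",
                           dimensions = character(0))
  expect_equal(sc3$results$df1[[1]], 2)
})

test_that("interaction analysis enforces eligibility and labels confounding", {
  tab <- monthly_table(planted_truth(31))
  # the truth plants a within-patient acc_ste_sleep -> depression slope;
  # gender additionally shifts both sides, making it an eligible confounder
  ph <- "acc_ste_sleep_mean"; dim <- "depression_anxiety"
  tab[[ph]] <- tab[[ph]] + ifelse(tab$gender == "male", 100, 0)
  tab[[dim]] <- tab[[dim]] + ifelse(tab$gender == "male", 6, 0)
  screen <- screen_covariates(tab, c("gender", "diagnosis"),
                              phenotypes = ph, dimensions = dim)
  expect_true(confounder_eligible(screen, "gender", ph, dim))
  traces <- step1_screen(tab, phenotypes = ph, dimensions = dim)
  expect_true(traces[[1]]$step1$retained)
  tr <- select_best_model(traces[[1]], tab)
  rep <- interaction_analysis(tr, "gender", tab, screen)
  expect_true(rep$conclusion %in% c("confounded", "robust"))
  expect_true(all(c("estimate", "t", "df", "p") %in% names(rep$terms)))
  expect_gte(nrow(rep$terms), 3)  # phenotype, covariate, interaction rows

  # a covariate significant on only one side is ineligible
  expect_false(confounder_eligible(screen, "diagnosis", ph, dim))
  expect_error(interaction_analysis(tr, "diagnosis", tab, screen),
               "eligible")
})

test_that("a mediated phenotype effect loses significance in the interaction model", {
  confounded_runs <- 0L
  reps <- 10L
  for (r in seq_len(reps)) {
    tr_truth <- simulation_truth(
      n_patients = 30, followup_months_per_patient = rep(8, 30),
      fixed_slopes = data.frame(phenotype = character(0),
                                dimension = character(0), slope = numeric(0)),
      missingness = no_missing, seed = 400 + r)
    tab <- monthly_table(tr_truth)
    ph <- "rmssd_sleep_mean"; dim <- "positive"
    male <- tab$gender == "male"
    tab[[ph]] <- tab[[ph]] + ifelse(male, 25, 0)
    tab[[dim]] <- tab[[dim]] + ifelse(male, 5, 0)  # link fully via gender
    screen <- screen_covariates(tab, "gender", phenotypes = ph,
                                dimensions = dim)
    if (!confounder_eligible(screen, "gender", ph, dim)) next
    traces <- step1_screen(tab, phenotypes = ph, dimensions = dim)
    if (!traces[[1]]$step1$retained) next
    sel <- select_best_model(traces[[1]], tab)
    rep_ <- interaction_analysis(sel, "gender", tab, screen)
    p_ph <- rep_$terms$p[rep_$terms$term == ph]
    if (length(p_ph) && p_ph >= 0.05) confounded_runs <- confounded_runs + 1L
  }
  expect_gte(confounded_runs, 5L)  # majority of evaluable replicates
})
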