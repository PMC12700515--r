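# Ground-truth parameterization of the synthetic cohort generator.
#
# The generative model for monthly symptom scores is the largest model the
# analysis fits, run forward: for dimension d and patient i at month t,
#   score_it = b0 + u0_i + (b1 + u1_i) * x_it + e_it,
# with (u0_i, u1_i) bivariate normal (SDs and correlation below) and e_it an
# AR(1) process with parameter rho and marginal SD `residual_sd`.

PANSS_DIMENSIONS <- c("positive", "negative", "cognitive_disorganization",
                      "depression_anxiety", "excitement_hostility")

# minimum possible dimension scores = item counts of the 5-factor grouping
PANSS_FLOORS <- c(positive = 4, negative = 6, cognitive_disorganization = 3,
                  depression_anxiety = 3, excitement_hostility = 4)

#' The 20 monthly digital phenotype names
#'
#' Mean and SD of accelerometer STE, gyroscope STE, NN count and RMSSD,
#' separately for wake and sleep, plus mean and SD of the daily sleep:wake
#' ratio and daily steps per minute.
#'
#' @return Character vector of length 20.
#' @export
phenotype_names <- function() {
  win <- c("acc_ste", "gyro_ste", "nn_count", "rmssd")
  c(as.vector(outer(win, c("wake_mean", "wake_sd", "sleep_mean", "sleep_sd"),
                    paste, sep = "_")),
    "sleep_wake_ratio_mean", "sleep_wake_ratio_sd",
    "steps_per_minute_mean", "steps_per_minute_sd")
}

#' The five symptom-dimension names
#' @return Character vector of length 5.
#' @export
panss_dimensions <- function() PANSS_DIMENSIONS

# per-window feature distributions by state: gamma with state-dependent mean
# and shape (CV = 1/sqrt(shape)); patient and month lognormal multipliers act
# on the mean. Values chosen to be physiologically plausible for wrist-worn
# sensors (NN counts from ~59-72 bpm; RMSSD higher in sleep).
.window_profiles <- function() {
  data.frame(
    feature = rep(c("acc_ste", "gyro_ste", "nn_count", "rmssd"), each = 2),
    state = rep(c("wake", "sleep"), 4),
    base = c(4000, 300, 3500, 800, 360, 295, 35, 50),
    shape = c(2, 2, 2, 2, 200, 200, 12, 12),
    stringsAsFactors = FALSE
  )
}

# lognormal SDs (log scale) of the patient- and month-level multipliers on
# latent monthly feature means
.LN_PATIENT_SD <- 0.20
.LN_MONTH_SD <- 0.10

#' Construct the planted ground truth for a synthetic cohort
#'
#' Defaults mirror the reference cohort: 38 patients, follow-up drawn from a
#' discretized normal on 1..26 months with mean 11.8; a planted phenotype ->
#' dimension slope map with standardized effects sized to Cohen f2 ~ 0.02;
#' random-intercept SD 3 score units; AR(1) residuals with rho 0.2 and
#' marginal SD 2.5; no random slope by default.
#'
#' @param n_patients Number of patients.
#' @param followup_months_per_patient Optional integer vector (one entry per
#'   patient, each in 1..26); `NULL` samples follow-up lengths.
#' @param fixed_intercepts Named numeric, baseline score per dimension.
#' @param fixed_slopes data.frame with columns `phenotype`, `dimension`,
#'   `slope` (score units per phenotype unit); `NULL` for the default planted
#'   map, `data.frame()` for a global null.
#' @param random_intercept_sd,random_slope_sd,residual_sd Nonnegative SDs in
#'   score units (slope SD in score units per phenotype unit).
#' @param intercept_slope_corr Correlation of random intercept and slope.
#' @param ar1_rho AR(1) parameter of the residual process, |rho| < 1.
#' @param missingness List with `window_drop_prob`, `nonwear_day_prob`,
#'   `month_visit_miss_prob`, each in \[0, 1\].
#' @param wake_hours_mean,sleep_hours_mean Mean daily wake/sleep hours.
#' @param score_floors Named numeric clipping floors (item counts).
#' @param round_scores Round scores to integers (default `FALSE`: continuous).
#' @param seed Integer seed; all cohort randomness flows from it.
#' @return Object of class `simulation_truth`.
#' @export
simulation_truth <- function(n_patients = 38,
                             followup_months_per_patient = NULL,
                             fixed_intercepts = c(
                               positive = 8, negative = 15.5,
                               cognitive_disorganization = 10.5,
                               depression_anxiety = 7.5,
                               excitement_hostility = 6.7),
                             fixed_slopes = NULL,
                             random_intercept_sd = 3,
                             random_slope_sd = 0,
                             intercept_slope_corr = 0,
                             residual_sd = 2.5,
                             ar1_rho = 0.2,
                             missingness = list(window_drop_prob = 0.05,
                                                nonwear_day_prob = 0.05,
                                                month_visit_miss_prob = 0.05),
                             wake_hours_mean = 16,
                             sleep_hours_mean = 8,
                             score_floors = PANSS_FLOORS,
                             round_scores = FALSE,
                             seed = 1L) {
  if (is.null(fixed_slopes)) fixed_slopes <- default_fixed_slopes()
  truth <- structure(list(
    n_patients = as.integer(n_patients),
    followup_months_per_patient = followup_months_per_patient,
    fixed_intercepts = fixed_intercepts,
    fixed_slopes = fixed_slopes,
    random_intercept_sd = random_intercept_sd,
    random_slope_sd = random_slope_sd,
    intercept_slope_corr = intercept_slope_corr,
    residual_sd = residual_sd,
    ar1_rho = ar1_rho,
    missingness = missingness,
    wake_hours_mean = wake_hours_mean,
    sleep_hours_mean = sleep_hours_mean,
    score_floors = score_floors,
    round_scores = isTRUE(round_scores),
    seed = as.integer(seed)
  ), class = "simulation_truth")
  validate_truth(truth)
  truth
}

#' Default planted phenotype-to-dimension slope map
#'
#' One phenotype per dimension, mirroring the qualitative pattern of the
#' reference findings (lower sleep RMSSD with positive symptoms, lower wake
#' motility with negative symptoms, lower wake NN-count variability with
#' cognitive/disorganization, higher sleep motility with depression/anxiety,
#' higher sleep NN count with excitement/hostility). Slope magnitudes are
#' 0.55 score units per SD of the phenotype, sized so the marginal Cohen f2
#' under the default variance components is about 0.02.
#'
#' @param effect_per_sd Standardized slope magnitude (score units per
#'   phenotype SD).
#' @return data.frame with columns `phenotype`, `dimension`, `slope`.
#' @export
default_fixed_slopes <- function(effect_per_sd = 0.55) {
  map <- data.frame(
    phenotype = c("rmssd_sleep_mean", "acc_ste_wake_mean",
                  "nn_count_wake_sd", "acc_ste_sleep_mean",
                  "nn_count_sleep_mean"),
    dimension = PANSS_DIMENSIONS,
    sign = c(-1, -1, -1, 1, 1),
    stringsAsFactors = FALSE
  )
  sds <- .latent_phenotype_sds()
  map$slope <- map$sign * effect_per_sd / sds[map$phenotype]
  map$sign <- NULL
  map
}

# reference (cohort-typical) level of each latent monthly phenotype; the
# forward symptom model applies slopes to deviations from these levels so
# that the fixed intercept is the score at a typical phenotype value and the
# dimension floor stays far from the bulk of the scores
.phenotype_ref_means <- function() {
  prof <- .window_profiles()
  out <- c()
  for (st in c("wake", "sleep")) {
    for (f in unique(prof$feature)) {
      b <- prof$base[prof$feature == f & prof$state == st]
      s <- prof$shape[prof$feature == f & prof$state == st]
      out[paste(f, st, "mean", sep = "_")] <- b
      out[paste(f, st, "sd", sep = "_")] <- b / sqrt(s)
    }
  }
  out["sleep_wake_ratio_mean"] <- 0.5
  out["sleep_wake_ratio_sd"] <- 0.08
  out["steps_per_minute_mean"] <- (16 * 12 * 30 + 8 * 12 * 1) / 1440
  out["steps_per_minute_sd"] <- 0.5
  out
}

# marginal SD of each latent monthly phenotype under the generator
.latent_phenotype_sds <- function() {
  prof <- .window_profiles()
  cv <- sqrt(exp(.LN_PATIENT_SD^2 + .LN_MONTH_SD^2) - 1)
  out <- c()
  for (st in c("wake", "sleep")) {
    for (f in unique(prof$feature)) {
      b <- prof$base[prof$feature == f & prof$state == st]
      s <- prof$shape[prof$feature == f & prof$state == st]
      out[paste(f, st, "mean", sep = "_")] <- b * cv
      out[paste(f, st, "sd", sep = "_")] <- (b / sqrt(s)) * cv
    }
  }
  out["sleep_wake_ratio_mean"] <- 0.5 * cv
  out["sleep_wake_ratio_sd"] <- 0.08 * cv
  out["steps_per_minute_mean"] <- 4 * cv
  out["steps_per_minute_sd"] <- 0.5 * cv
  out
}

#' Validate a simulation truth
#'
#' @param truth A `simulation_truth`.
#' @return `truth`, invisibly; signals a configuration error naming the
#'   violated field otherwise.
#' @export
validate_truth <- function(truth) {
  chk <- function(ok, field, why) {
    if (!ok) .stopf("invalid simulation truth: field '%s' %s", field, why)
  }
  chk(truth$n_patients >= 1, "n_patients", "must be >= 1")
  fu <- truth$followup_months_per_patient
  if (!is.null(fu)) {
    chk(length(fu) == truth$n_patients, "followup_months_per_patient",
        "must have one entry per patient")
    chk(all(fu >= 1 & fu <= 26), "followup_months_per_patient",
        "entries must lie in [1, 26]")
  }
  chk(all(PANSS_DIMENSIONS %in% names(truth$fixed_intercepts)),
      "fixed_intercepts", "must name all five dimensions")
  fs <- truth$fixed_slopes
  chk(is.data.frame(fs) &&
        (nrow(fs) == 0 ||
           all(c("phenotype", "dimension", "slope") %in% names(fs))),
      "fixed_slopes", "must be a data.frame(phenotype, dimension, slope)")
  if (nrow(fs)) {
    chk(all(fs$phenotype %in% phenotype_names()), "fixed_slopes",
        "phenotype names must be among phenotype_names()")
    chk(all(fs$dimension %in% PANSS_DIMENSIONS), "fixed_slopes",
        "dimension names must be among panss_dimensions()")
  }
  chk(truth$random_intercept_sd >= 0, "random_intercept_sd", "must be >= 0")
  chk(truth$random_slope_sd >= 0, "random_slope_sd", "must be >= 0")
  chk(truth$residual_sd >= 0, "residual_sd", "must be >= 0")
  chk(abs(truth$intercept_slope_corr) <= 1, "intercept_slope_corr",
      "must lie in [-1, 1]")
  chk(abs(truth$ar1_rho) < 1, "ar1_rho", "must satisfy |rho| < 1")
  for (f in c("window_drop_prob", "nonwear_day_prob", "month_visit_miss_prob")) {
    p <- truth$missingness[[f]]
    chk(!is.null(p) && p >= 0 && p <= 1, paste0("missingness$", f),
        "must lie in [0, 1]")
  }
  chk(truth$wake_hours_mean > 0 && truth$sleep_hours_mean > 0 &&
        truth$wake_hours_mean + truth$sleep_hours_mean <= 24,
      "wake_hours_mean/sleep_hours_mean", "must be positive and sum to <= 24")
  invisible(truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("<simulation_truth>\n")
  cat(sprintf("  patients: %d, seed: %d\n", x$n_patients, x$seed))
  cat(sprintf("  random intercept SD %.3g, slope SD %.3g (corr %.2f)\n",
              x$random_intercept_sd, x$random_slope_sd,
              x$intercept_slope_corr))
  cat(sprintf("  residual SD %.3g, AR(1) rho %.2f\n",
              x$residual_sd, x$ar1_rho))
  cat(sprintf("  planted slopes: %d pair(s)\n", nrow(x$fixed_slopes)))
  invisible(x)
}
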