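# Seeded synthetic-cohort generator.
#
# Random-number streams are partitioned per patient (seed derived from the
# cohort seed and the patient index), so adding a patient never perturbs the
# data of the others. Two fidelity levels are supported:
#   level = "windows": a full 5-minute window grid per followed month with
#     circadian wake/sleep labels, state-dependent motility/cardiac features,
#     steps, and device-nonwear missingness;
#   level = "monthly": the 20 latent monthly phenotypes drawn directly, for
#     calibration studies that need many replicate cohorts.
# Monthly symptom scores always come from simulate_panss_from_lmm(), i.e. the
# largest analysis model run forward.

# discretized follow-up distribution on 1..26 months; center solved so the
# discrete mean equals 11.8
.FOLLOWUP_CENTER <- 11.0342
.FOLLOWUP_SD <- 7.2

.followup_weights <- function() {
  w <- stats::dnorm(1:26, .FOLLOWUP_CENTER, .FOLLOWUP_SD)
  w / sum(w)
}

#' Generate a synthetic cohort with known ground truth
#'
#' @param truth A [simulation_truth()].
#' @param level `"windows"` for raw 5-minute streams plus clinical table,
#'   `"monthly"` for directly drawn monthly phenotypes (fast; used by
#'   replicate simulation studies).
#' @param raw_signals If `TRUE` (windows level only), emit raw 3-axis sample
#'   blocks and interpulse-interval lists instead of precomputed features;
#'   intended for small cohorts exercising the feature extractors.
#' @param samples_per_window Raw samples per axis per 5-minute window when
#'   `raw_signals = TRUE`.
#' @return A `cohort_bundle`: list with `windows` (window table or `NULL`),
#'   `monthly` (latent monthly phenotype table), `clinical` (monthly symptom
#'   scores and covariates), `truth`, and `level`.
#' @export
generate_cohort <- function(truth, level = c("windows", "monthly"),
                            raw_signals = FALSE, samples_per_window = 30L) {
  validate_truth(truth)
  level <- match.arg(level)
  n <- truth$n_patients
  ids <- sprintf("P%03d", seq_len(n))

  followup <- truth$followup_months_per_patient
  if (is.null(followup)) {
    w <- .followup_weights()
    followup <- vapply(seq_len(n), function(i) {
      .set_stream(truth$seed, i, 0L)
      sample.int(26L, 1L, prob = w)
    }, integer(1))
  }
  followup <- as.integer(followup)

  covars <- do.call(rbind, lapply(seq_len(n), function(i) {
    .patient_covariates(truth, i, ids[[i]])
  }))

  monthly <- do.call(rbind, lapply(seq_len(n), function(i) {
    .latent_monthly(truth, i, ids[[i]], followup[[i]])
  }))

  windows <- NULL
  if (level == "windows") {
    windows <- data.table::rbindlist(lapply(seq_len(n), function(i) {
      .patient_windows(truth, i, ids[[i]], followup[[i]], monthly,
                       raw_signals, samples_per_window)
    }))
    data.table::setDF(windows)
  }

  panss <- simulate_panss_from_lmm(monthly, truth)
  clinical <- merge(panss, covars, by = "patient_id", sort = FALSE)
  clinical$followup_month <- clinical$month_index
  # monthly visit missingness
  keep <- unlist(lapply(seq_len(n), function(i) {
    .set_stream(truth$seed, i, 6L)
    stats::runif(followup[[i]]) >= truth$missingness$month_visit_miss_prob
  }))
  ord <- order(match(clinical$patient_id, ids), clinical$month_index)
  clinical <- clinical[ord, , drop = FALSE]
  clinical <- clinical[keep, , drop = FALSE]
  rownames(clinical) <- NULL

  structure(list(windows = windows, monthly = monthly, clinical = clinical,
                 truth = truth, level = level),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle>\n")
  cat(sprintf("  level: %s; patients: %d; clinical rows: %d\n",
              x$level, x$truth$n_patients, nrow(x$clinical)))
  if (!is.null(x$windows)) cat(sprintf("  windows: %d\n", nrow(x$windows)))
  invisible(x)
}

.patient_covariates <- function(truth, i, id) {
  .set_stream(truth$seed, i, 1L)
  male <- stats::runif(1) < 0.684
  schiz <- stats::runif(1) < 0.553
  on_ap <- stats::runif(1) < 0.895
  cpz <- if (on_ap) stats::rlnorm(1, meanlog = 5.94, sdlog = 0.79) else 0
  on_ad <- stats::runif(1) < 0.447
  fluox <- if (on_ad) stats::rlnorm(1, meanlog = log(18) - 0.18, sdlog = 0.6)
           else 0
  data.frame(patient_id = id,
             gender = if (male) "male" else "female",
             diagnosis = if (schiz) "schizophrenia" else "affective",
             chlorpromazine_equivalents = cpz,
             fluoxetine_equivalents = fluox,
             stringsAsFactors = FALSE)
}

# latent monthly phenotype table for one patient; also carries the monthly
# sleep-duration target (hours) used by the window generator
.latent_monthly <- function(truth, i, id, n_months) {
  .set_stream(truth$seed, i, 2L)
  prof <- .window_profiles()
  key <- paste(prof$feature, prof$state, sep = "_")
  eta <- stats::rnorm(nrow(prof), 0, .LN_PATIENT_SD)       # patient effects
  eta_steps <- stats::rnorm(1, 0, .LN_PATIENT_SD)
  nu <- matrix(stats::rnorm(n_months * nrow(prof), 0, .LN_MONTH_SD),
               n_months, nrow(prof))                        # month effects
  nu_sleep <- stats::rnorm(n_months, 0, 0.01)
  nu_steps <- stats::rnorm(n_months, 0, .LN_MONTH_SD)
  nu_ratio_sd <- stats::rnorm(n_months, 0, .LN_MONTH_SD)
  nu_steps_sd <- stats::rnorm(n_months, 0, .LN_MONTH_SD)

  out <- data.frame(patient_id = rep(id, n_months),
                    month_index = seq_len(n_months),
                    stringsAsFactors = FALSE)
  mu <- matrix(NA_real_, n_months, nrow(prof))
  for (k in seq_len(nrow(prof))) {
    mu[, k] <- prof$base[[k]] * exp(eta[[k]] + nu[, k])
    out[[paste0(key[[k]], "_mean")]] <- mu[, k]
    out[[paste0(key[[k]], "_sd")]] <- mu[, k] / sqrt(prof$shape[[k]])
  }
  sleep_target <- pmin(pmax(truth$sleep_hours_mean * exp(nu_sleep), 4), 14)
  out$sleep_wake_ratio_mean <- sleep_target / (24 - sleep_target)
  out$sleep_wake_ratio_sd <- 0.08 * exp(nu_ratio_sd)
  lambda <- 30 * exp(eta_steps + nu_steps)
  out$steps_per_minute_mean <-
    ((24 - sleep_target) * 12 * lambda + sleep_target * 12 * 1) / 1440
  out$steps_per_minute_sd <- 0.5 * exp(nu_steps_sd)
  attr_cols <- data.frame(sleep_target_hours = sleep_target,
                          steps_lambda = lambda)
  out$.sleep_target_hours <- attr_cols$sleep_target_hours
  out$.steps_lambda <- attr_cols$steps_lambda
  # canonical column order
  out[, c("patient_id", "month_index", phenotype_names(),
          ".sleep_target_hours", ".steps_lambda")]
}

.patient_windows <- function(truth, i, id, n_months, monthly, raw_signals,
                             samples_per_window) {
  prof <- .window_profiles()
  lat <- monthly[monthly$patient_id == id, , drop = FALSE]
  miss <- truth$missingness
  .set_stream(truth$seed, i, 3L)
  origin <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")

  month_parts <- vector("list", n_months)
  for (m in seq_len(n_months)) {
    s_target <- lat$.sleep_target_hours[[m]]
    lambda <- lat$.steps_lambda[[m]]
    nonwear <- stats::runif(30) < miss$nonwear_day_prob
    s_d <- pmin(pmax(stats::rnorm(30, s_target, 0.5), 3), 14)
    start_idx <- pmax(0L, pmin(36L, round(stats::rnorm(30, 6, 4))))
    day_keep <- which(!nonwear)
    if (!length(day_keep)) next
    sleep_len <- pmax(1L, round(s_d * 12))

    widx <- rep(0:287, times = length(day_keep))
    day <- rep(day_keep, each = 288L)
    st <- widx >= start_idx[day] & widx < (start_idx[day] + sleep_len[day])
    drop <- stats::runif(length(widx)) < miss$window_drop_prob
    keep <- !drop
    widx <- widx[keep]; day <- day[keep]; st <- st[keep]
    n_w <- length(widx)
    if (!n_w) next

    state <- ifelse(st, "sleep", "wake")
    date <- as.Date(origin) + (m - 1L) * 30L + (day - 1L)
    window_start <- origin + ((m - 1L) * 30 + (day - 1)) * 86400 + widx * 300

    part <- data.table::data.table(
      patient_id = id, month_index = m, date = date,
      window_start = window_start, state = state)

    mu_for <- function(feature) {
      b_w <- lat[[paste0(feature, "_wake_mean")]][[m]]
      b_s <- lat[[paste0(feature, "_sleep_mean")]][[m]]
      ifelse(st, b_s, b_w)
    }
    shape_for <- function(feature) {
      sh <- prof$shape[prof$feature == feature]
      ifelse(st, sh[prof$state[prof$feature == feature] == "sleep"],
             sh[prof$state[prof$feature == feature] == "wake"])
    }
    steps <- stats::rpois(n_w, ifelse(st, 1, lambda))

    if (raw_signals) {
      mu_acc <- mu_for("acc_ste"); mu_gyro <- mu_for("gyro_ste")
      mu_nn <- pmin(pmax(round(mu_for("nn_count")), 2), 1100)
      mu_rmssd <- mu_for("rmssd")
      part$acc <- lapply(seq_len(n_w), function(j) {
        sd_ax <- sqrt(mu_acc[[j]] / (3 * samples_per_window))
        matrix(stats::rnorm(3 * samples_per_window, 0, sd_ax),
               ncol = 3)
      })
      part$gyro <- lapply(seq_len(n_w), function(j) {
        sd_ax <- sqrt(mu_gyro[[j]] / (3 * samples_per_window))
        matrix(stats::rnorm(3 * samples_per_window, 0, sd_ax), ncol = 3)
      })
      part$ipi_ms <- lapply(seq_len(n_w), function(j) {
        cnt <- mu_nn[[j]]
        mu_int <- 300000 / cnt
        ipi <- mu_int + stats::rnorm(cnt, 0, mu_rmssd[[j]] / sqrt(2))
        ipi <- pmax(ipi, 250)
        # inject occasional artifacts for the cleaning rule to remove
        art <- stats::runif(cnt) < 0.02
        ipi[art] <- ipi[art] * 3
        ipi
      })
      part$steps <- steps
    } else {
      draw <- function(feature) {
        sh <- shape_for(feature); mu <- mu_for(feature)
        stats::rgamma(n_w, shape = sh, rate = sh / mu)
      }
      part$acc_ste <- draw("acc_ste")
      part$gyro_ste <- draw("gyro_ste")
      part$nn_count <- pmin(pmax(round(draw("nn_count")), 0), 1100)
      part$rmssd <- draw("rmssd")
      part$steps <- steps
    }
    month_parts[[m]] <- part
  }
  data.table::rbindlist(month_parts[!vapply(month_parts, is.null, logical(1))])
}

#' Simulate monthly symptom scores from the forward mixed model
#'
#' For each dimension, `score_it = b0 + u0_i + sum_k (b1_k + u1_ik) x_ikt +
#' e_it` where the sum runs over the truth's planted (phenotype, dimension)
#' slopes, `x_ikt` is the phenotype's deviation from its cohort reference
#' level (so `b0` is the score at a typical phenotype value), `(u0, u1)` are
#' bivariate normal with the truth's SDs and correlation (additional slopes
#' for the same dimension get independent `u1`), and `e` is an AR(1) process
#' with parameter `ar1_rho` and marginal SD `residual_sd`. Scores are
#' clipped at the dimension floor and rounded to integers only when the
#' truth requests it (default: continuous).
#'
#' @param monthly_phenotypes Patient-month table containing the phenotype
#'   columns named in `truth$fixed_slopes` plus `patient_id`, `month_index`.
#' @param truth A [simulation_truth()].
#' @return data.frame: `patient_id`, `month_index`, and one column per
#'   symptom dimension.
#' @export
simulate_panss_from_lmm <- function(monthly_phenotypes, truth) {
  validate_truth(truth)
  fs <- truth$fixed_slopes
  used <- unique(fs$phenotype)
  for (ph in used) {
    if (!ph %in% names(monthly_phenotypes)) {
      .stopf("phenotype column '%s' named in fixed_slopes is absent", ph)
    }
    if (any(!is.finite(monthly_phenotypes[[ph]]))) {
      .stopf("non-finite values in phenotype column '%s'", ph)
    }
  }
  ids <- sort(unique(monthly_phenotypes$patient_id))
  rho <- truth$ar1_rho
  sd_e <- truth$residual_sd
  sd0 <- truth$random_intercept_sd
  sd1 <- truth$random_slope_sd
  r01 <- truth$intercept_slope_corr

  res <- lapply(seq_along(ids), function(i) {
    rows <- monthly_phenotypes[monthly_phenotypes$patient_id == ids[[i]], ,
                               drop = FALSE]
    rows <- rows[order(rows$month_index), , drop = FALSE]
    m <- nrow(rows)
    .set_stream(truth$seed, i, 5L)
    out <- data.frame(patient_id = rep(ids[[i]], m),
                      month_index = rows$month_index,
                      stringsAsFactors = FALSE)
    for (d in PANSS_DIMENSIONS) {
      z0 <- stats::rnorm(1)
      u0 <- sd0 * z0
      score <- truth$fixed_intercepts[[d]] + u0
      maps <- fs[fs$dimension == d, , drop = FALSE]
      if (nrow(maps)) {
        for (k in seq_len(nrow(maps))) {
          zk <- stats::rnorm(1)
          u1 <- if (k == 1L) sd1 * (r01 * z0 + sqrt(1 - r01^2) * zk)
                else sd1 * zk
          # slopes act on deviations from the phenotype's reference level so
          # the intercept is the score at a typical phenotype value
          xc <- rows[[maps$phenotype[[k]]]] -
            .phenotype_ref_means()[[maps$phenotype[[k]]]]
          score <- score + (maps$slope[[k]] + u1) * xc
        }
      }
      z <- stats::rnorm(m)
      e <- numeric(m)
      if (m >= 1L) e[[1L]] <- sd_e * z[[1L]]
      if (m >= 2L) {
        for (t in 2:m) e[[t]] <- rho * e[[t - 1L]] + sd_e * sqrt(1 - rho^2) * z[[t]]
      }
      score <- score + e
      score <- pmax(score, truth$score_floors[[d]])
      if (truth$round_scores) score <- round(score)
      out[[d]] <- score
    }
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a cohort bundle to plain-text artifacts
#'
#' Emits `windows.csv` (when present; ISO-8601 UTC timestamps),
#' `clinical.csv`, `monthly_latent.csv` and `truth.json` under `dir`.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(bundle$windows)) {
    w <- data.table::as.data.table(bundle$windows)
    if ("window_start" %in% names(w)) {
      w[, window_start := format(window_start, "%Y-%m-%dT%H:%M:%SZ",
                                 tz = "UTC")]
    }
    listcols <- names(w)[vapply(w, is.list, logical(1))]
    if (length(listcols)) w[, (listcols) := NULL]
    data.table::fwrite(w, file.path(dir, "windows.csv"))
  }
  data.table::fwrite(data.table::as.data.table(bundle$clinical),
                     file.path(dir, "clinical.csv"))
  mon <- bundle$monthly[, c("patient_id", "month_index", phenotype_names())]
  data.table::fwrite(data.table::as.data.table(mon),
                     file.path(dir, "monthly_latent.csv"))
  tr <- bundle$truth
  class(tr) <- NULL
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
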