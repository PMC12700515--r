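# Collapse window/day features into the 20 monthly digital phenotypes, apply
# the recording-completeness filters, and join with the clinical table.
#
# A follow-up month is a 30-day block from enrollment (uniform window counts
# keep the completeness thresholds comparable across months). A month is
# included when it has at least 720 wake and 480 sleep 5-minute windows.
# Sample SDs use the n-1 denominator throughout; the SD phenotypes for
# sleep:wake ratio and steps/min are computed across valid days in the month.

.sdna <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) < 2L) return(NA_real_)
  stats::sd(v)
}
.meanna <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Aggregate one patient-month of window records into phenotype values
#'
#' Means and SDs of the four window features are computed separately over
#' wake and sleep windows; windows with missing RMSSD (fewer than two NN
#' intervals) are omitted from the RMSSD aggregates only. Daily sleep:wake
#' ratio and steps/min aggregates run over valid days only.
#'
#' @param windows Window records for one patient-month.
#' @param days Day summaries for the same patient-month
#'   (as from [day_summaries()]).
#' @param patient_id,month_index Identifiers for the produced row.
#' @param min_wake,min_sleep Inclusion thresholds on window counts.
#' @return One-row data.frame: 20 phenotype values, window/day counts, and
#'   the `included` flag.
#' @export
aggregate_month <- function(windows, days, patient_id, month_index,
                            min_wake = 720L, min_sleep = 480L) {
  out <- data.frame(patient_id = patient_id, month_index = month_index,
                    stringsAsFactors = FALSE)
  wake <- windows[!is.na(windows$state) & windows$state == "wake", ,
                  drop = FALSE]
  sleep <- windows[!is.na(windows$state) & windows$state == "sleep", ,
                   drop = FALSE]
  for (f in c("acc_ste", "gyro_ste", "nn_count", "rmssd")) {
    out[[paste0(f, "_wake_mean")]] <- .meanna(wake[[f]])
    out[[paste0(f, "_wake_sd")]] <- .sdna(wake[[f]])
    out[[paste0(f, "_sleep_mean")]] <- .meanna(sleep[[f]])
    out[[paste0(f, "_sleep_sd")]] <- .sdna(sleep[[f]])
  }
  vd <- days[days$valid, , drop = FALSE]
  out$sleep_wake_ratio_mean <- .meanna(vd$sleep_wake_ratio)
  out$sleep_wake_ratio_sd <- .sdna(vd$sleep_wake_ratio)
  out$steps_per_minute_mean <- .meanna(vd$steps_per_minute)
  out$steps_per_minute_sd <- .sdna(vd$steps_per_minute)
  out$n_wake_windows <- nrow(wake)
  out$n_sleep_windows <- nrow(sleep)
  out$n_valid_days <- nrow(vd)
  out$included <- nrow(wake) >= min_wake && nrow(sleep) >= min_sleep
  out
}

#' Aggregate every patient-month in a windows table
#'
#' Vectorized driver over [aggregate_month()] semantics.
#'
#' @param windows Window feature table (`month_index` column required).
#' @param days Day summaries from [day_summaries()].
#' @param min_wake,min_sleep Inclusion thresholds on window counts.
#' @return data.frame, one row per patient-month (a month with zero windows
#'   for a followed patient simply has no row and is thereby excluded).
#' @export
aggregate_months <- function(windows, days, min_wake = 720L,
                             min_sleep = 480L) {
  dt <- data.table::as.data.table(windows)
  agg <- dt[, {
    wake <- state == "wake"
    res <- list()
    for (f in c("acc_ste", "gyro_ste", "nn_count", "rmssd")) {
      v <- get(f)
      res[[paste0(f, "_wake_mean")]] <- .meanna(v[wake])
      res[[paste0(f, "_wake_sd")]] <- .sdna(v[wake])
      res[[paste0(f, "_sleep_mean")]] <- .meanna(v[!wake])
      res[[paste0(f, "_sleep_sd")]] <- .sdna(v[!wake])
    }
    res$n_wake_windows <- sum(wake)
    res$n_sleep_windows <- sum(!wake)
    res
  }, by = list(patient_id, month_index)]
  dd <- data.table::as.data.table(days)
  dagg <- dd[valid == TRUE, list(
    sleep_wake_ratio_mean = .meanna(sleep_wake_ratio),
    sleep_wake_ratio_sd = .sdna(sleep_wake_ratio),
    steps_per_minute_mean = .meanna(steps_per_minute),
    steps_per_minute_sd = .sdna(steps_per_minute),
    n_valid_days = .N), by = list(patient_id, month_index)]
  out <- merge(agg, dagg, by = c("patient_id", "month_index"), all.x = TRUE)
  out[is.na(n_valid_days), n_valid_days := 0L]
  out[, included := n_wake_windows >= min_wake & n_sleep_windows >= min_sleep]
  data.table::setorder(out, patient_id, month_index)
  data.table::setDF(out)
  out[, c("patient_id", "month_index", phenotype_names(),
          "n_wake_windows", "n_sleep_windows", "n_valid_days", "included")]
}

#' Build the modelling table from patient-months and the clinical table
#'
#' Inner join on `(patient_id, month_index)` keeping only included sensor
#' months that have a symptom record. With the default `alignment =
#' "preceding"`, monthly ratings made at the end of follow-up month `m` are
#' paired with the sensor data of block `m` (the 30 days preceding the
#' rating); `alignment = "same"` pairs them with the block starting at the
#' visit instead.
#'
#' @param patient_months Output of [aggregate_months()] (or the monthly table
#'   of a `"monthly"`-level cohort via [monthly_to_patient_months()]).
#' @param clinical Clinical table with `patient_id`, `month_index`, the five
#'   dimension scores, and covariates.
#' @param alignment `"preceding"` (default) or `"same"`.
#' @return data.frame with 20 phenotype columns, 5 outcome columns, and
#'   covariates; attribute `"dropped_clinical"` counts rating visits without
#'   an included sensor month.
#' @export
build_analysis_table <- function(patient_months, clinical,
                                 alignment = c("preceding", "same")) {
  alignment <- match.arg(alignment)
  pm <- data.table::as.data.table(patient_months)
  cl <- data.table::as.data.table(clinical)
  for (d in list(pm, cl)) {
    dup <- duplicated(d, by = c("patient_id", "month_index"))
    if (any(dup)) {
      off <- unique(d[dup, paste(patient_id, month_index)])
      .stopf("duplicate (patient, month) keys: %s",
             paste(utils::head(off, 5), collapse = ", "))
    }
  }
  if (alignment == "same") pm[, month_index := month_index - 1L]
  inc <- pm[included == TRUE]
  out <- merge(inc, cl, by = c("patient_id", "month_index"))
  dropped <- nrow(cl) - nrow(out)
  data.table::setorder(out, patient_id, month_index)
  data.table::setDF(out)
  attr(out, "dropped_clinical") <- dropped
  out
}

#' Promote a monthly-level cohort to the patient-month schema
#'
#' Monthly-level cohorts carry the latent phenotypes directly; this marks all
#' months as included so [build_analysis_table()] can consume them.
#'
#' @param monthly The `monthly` element of a `cohort_bundle`.
#' @return data.frame in the [aggregate_months()] schema.
#' @export
monthly_to_patient_months <- function(monthly) {
  out <- monthly[, c("patient_id", "month_index", phenotype_names())]
  out$n_wake_windows <- NA_integer_
  out$n_sleep_windows <- NA_integer_
  out$n_valid_days <- NA_integer_
  out$included <- TRUE
  out
}

#' Analysis table straight from a cohort bundle
#'
#' Runs the full feature/day/month chain for `"windows"`-level bundles, or
#' the monthly promotion for `"monthly"`-level bundles, then joins with the
#' bundle's clinical table.
#'
#' @param bundle A `cohort_bundle`.
#' @param alignment Passed to [build_analysis_table()].
#' @param min_wake,min_sleep,min_hours Filter thresholds.
#' @return Modelling table (see [build_analysis_table()]).
#' @export
analysis_table_from_bundle <- function(bundle, alignment = "preceding",
                                       min_wake = 720L, min_sleep = 480L,
                                       min_hours = 18) {
  pm <- if (bundle$level == "windows") {
    days <- day_summaries(bundle$windows, min_hours = min_hours)
    aggregate_months(bundle$windows, days, min_wake, min_sleep)
  } else {
    monthly_to_patient_months(bundle$monthly)
  }
  build_analysis_table(pm, bundle$clinical, alignment)
}
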