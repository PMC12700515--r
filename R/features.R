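# Per-window and per-day digital phenotype features from raw smartwatch streams.
#
# The motility measure is the short-time energy (STE) of the Euclidean norm of
# the 3-axis accelerometer/gyroscope signal over a 5-minute window,
# STE = sum_j x_j^2 — an activity-count-like quantity without thresholding.
# Cardiac features are the count of normal-to-normal (NN) interpulse intervals
# per window (sympathovagal-balance proxy) and the RMSSD of successive NN
# differences (parasympathetic proxy).

#' Euclidean norm of a 3-axis signal
#'
#' @param x,y,z Equal-length numeric vectors of axis samples.
#' @return Numeric vector of per-sample norms `sqrt(x^2 + y^2 + z^2)`.
#' @export
#' @examples
#' euclidean_norm(3, 4, 0) # 5
euclidean_norm <- function(x, y, z) {
  if (length(x) != length(y) || length(x) != length(z)) {
    .stopf("euclidean_norm: axis streams have unequal lengths (%d, %d, %d)",
           length(x), length(y), length(z))
  }
  sqrt(x^2 + y^2 + z^2)
}

#' Short-time energy of a windowed signal
#'
#' Sum of squared norm samples over one 5-minute window. Invariant to sample
#' order and additive over any partition of the window; scaling samples by `c`
#' scales the energy by `c^2`.
#'
#' @param norm_samples Nonnegative numeric vector of norm samples in one window.
#' @return The energy, or `NA_real_` for an empty window (dropped, not zero).
#' @export
#' @examples
#' compute_ste(c(1, 2, 3)) # 14
compute_ste <- function(norm_samples) {
  if (length(norm_samples) == 0L) return(NA_real_)
  if (any(!is.finite(norm_samples))) .stopf("compute_ste: non-finite samples")
  sum(norm_samples^2)
}

#' Artifact removal for interpulse interval series
#'
#' Retains intervals inside an absolute physiological band and within a
#' relative tolerance of the running median of the previous `window` retained
#' intervals. Order is preserved and the output is a subset of the input; the
#' rule is idempotent.
#'
#' @param ipi_ms Numeric vector of positive interpulse intervals (ms).
#' @param band Length-2 numeric, absolute retention band in ms.
#' @param tolerance Relative deviation allowed from the running median.
#' @param window Number of previous retained intervals in the running median.
#' @return Cleaned NN-interval vector (ms).
#' @export
clean_interpulse <- function(ipi_ms, band = c(300, 2000), tolerance = 0.2,
                             window = 10L) {
  if (length(ipi_ms) == 0L) return(numeric(0))
  if (any(!is.finite(ipi_ms)) || any(ipi_ms <= 0)) {
    .stopf("clean_interpulse: intervals must be positive and finite")
  }
  keep <- logical(length(ipi_ms))
  recent <- numeric(0)
  for (i in seq_along(ipi_ms)) {
    v <- ipi_ms[[i]]
    ok <- v >= band[[1]] && v <= band[[2]]
    if (ok && length(recent)) {
      m <- stats::median(recent)
      ok <- abs(v - m) <= tolerance * m
    }
    if (ok) {
      keep[[i]] <- TRUE
      recent <- c(recent, v)
      if (length(recent) > window) recent <- recent[-1L]
    }
  }
  ipi_ms[keep]
}

#' NN count and RMSSD for one 5-minute window
#'
#' @param nn_ms Cleaned NN intervals (ms) within one window.
#' @return List with `nn_count` (length of the series) and `rmssd`
#'   (`sqrt(mean(diff^2))` of successive differences, `NA` when fewer than 2
#'   intervals).
#' @export
#' @examples
#' window_heart_features(c(800, 810, 800)) # nn_count 3, rmssd 10
window_heart_features <- function(nn_ms) {
  n <- length(nn_ms)
  rmssd <- if (n >= 2L) sqrt(mean(diff(nn_ms)^2)) else NA_real_
  list(nn_count = n, rmssd = rmssd)
}

#' Compute window features from raw sensor blocks
#'
#' Maps a raw windows table (as produced by [generate_cohort()] with
#' `raw_signals = TRUE`: list-columns `acc`, `gyro` of 3-column sample
#' matrices and `ipi_ms` interval lists) to the standard per-window feature
#' schema used by the rest of the pipeline.
#'
#' @param windows_raw data.frame with columns `patient_id`, `month_index`,
#'   `date`, `window_start`, `state`, `steps` and list-columns `acc`, `gyro`,
#'   `ipi_ms`.
#' @param band,tolerance,window Passed to [clean_interpulse()].
#' @return data.frame of window records with `acc_ste`, `gyro_ste`,
#'   `nn_count`, `rmssd` columns.
#' @export
compute_window_features <- function(windows_raw, band = c(300, 2000),
                                    tolerance = 0.2, window = 10L) {
  stopifnot(all(c("acc", "gyro", "ipi_ms", "state") %in% names(windows_raw)))
  ste_of <- function(block) {
    if (is.null(block) || nrow(block) == 0L) return(NA_real_)
    compute_ste(euclidean_norm(block[, 1L], block[, 2L], block[, 3L]))
  }
  acc_ste <- vapply(windows_raw$acc, ste_of, numeric(1))
  gyro_ste <- vapply(windows_raw$gyro, ste_of, numeric(1))
  hf <- lapply(windows_raw$ipi_ms, function(ipi) {
    window_heart_features(clean_interpulse(ipi, band, tolerance, window))
  })
  out <- windows_raw[, setdiff(names(windows_raw), c("acc", "gyro", "ipi_ms")),
                     drop = FALSE]
  out$acc_ste <- acc_ste
  out$gyro_ste <- gyro_ste
  out$nn_count <- vapply(hf, function(h) as.numeric(h$nn_count), numeric(1))
  out$rmssd <- vapply(hf, function(h) h$rmssd, numeric(1))
  validate_windows(out)
  out
}

#' Validate a per-window feature table
#'
#' Checks the window-record invariants: nonnegative energies and RMSSD, and an
#' NN-count ceiling implied by a maximum plausible heart rate.
#'
#' @param windows Window feature table.
#' @param max_hr_bpm Maximum heart rate used for the NN-count ceiling
#'   (default 220 bpm, i.e. at most 1100 NN intervals per 5 minutes).
#' @return `windows`, invisibly.
#' @export
validate_windows <- function(windows, max_hr_bpm = 220) {
  need <- c("patient_id", "window_start", "state", "acc_ste", "gyro_ste",
            "nn_count", "rmssd")
  miss <- setdiff(need, names(windows))
  if (length(miss)) .stopf("windows table lacks columns: %s",
                           paste(miss, collapse = ", "))
  if (!all(windows$state %in% c("wake", "sleep"))) {
    .stopf("state must be 'wake' or 'sleep'")
  }
  bad <- function(v) any(!is.na(v) & v < 0)
  if (bad(windows$acc_ste) || bad(windows$gyro_ste) || bad(windows$rmssd)) {
    .stopf("energies and rmssd must be nonnegative where present")
  }
  ceiling_nn <- max_hr_bpm * 5
  if (any(!is.na(windows$nn_count) & windows$nn_count > ceiling_nn)) {
    .stopf("nn_count exceeds ceiling %d implied by max heart rate %g bpm",
           ceiling_nn, max_hr_bpm)
  }
  invisible(windows)
}

#' Daily summary for one patient-day
#'
#' A day is valid when at least `min_hours` (default 18) of 5-minute windows
#' were recorded; sleep:wake ratio and steps-per-minute phenotypes are later
#' aggregated over valid days only. "Recorded" counts windows with any sensor
#' payload; device non-wear shows up as absent windows.
#'
#' @param windows_day Window records sharing one patient-local calendar date.
#' @param min_hours Validity threshold in hours.
#' @return One-row data.frame: `patient_id`, `date`, `hours_recorded`,
#'   `sleep_wake_ratio` (NA when no wake hours), `steps_per_minute`, `valid`.
#' @export
daily_summary <- function(windows_day, min_hours = 18) {
  stopifnot(nrow(windows_day) >= 1L)
  if (length(unique(as.Date(windows_day$date))) != 1L) {
    .stopf("daily_summary: windows span more than one calendar date")
  }
  n <- nrow(windows_day)
  sleep_h <- sum(windows_day$state == "sleep") / 12
  wake_h <- sum(windows_day$state == "wake") / 12
  data.frame(
    patient_id = windows_day$patient_id[[1L]],
    date = as.Date(windows_day$date[[1L]]),
    hours_recorded = n / 12,
    sleep_wake_ratio = if (wake_h > 0) sleep_h / wake_h else NA_real_,
    steps_per_minute = sum(windows_day$steps, na.rm = TRUE) / (5 * n),
    valid = (n / 12) >= min_hours,
    stringsAsFactors = FALSE
  )
}

#' Daily summaries for a whole windows table
#'
#' Vectorized equivalent of [daily_summary()] over every patient-day.
#'
#' @param windows Window feature table with `date` and `steps` columns.
#' @param min_hours Validity threshold in hours.
#' @return data.frame, one row per patient-day.
#' @export
day_summaries <- function(windows, min_hours = 18) {
  dt <- data.table::as.data.table(windows)
  out <- dt[, {
    n <- .N
    sleep_h <- sum(state == "sleep") / 12
    wake_h <- sum(state == "wake") / 12
    list(hours_recorded = n / 12,
         sleep_wake_ratio = if (wake_h > 0) sleep_h / wake_h else NA_real_,
         steps_per_minute = sum(steps, na.rm = TRUE) / (5 * n),
         valid = (n / 12) >= min_hours,
         month_index = month_index[[1L]])
  }, by = list(patient_id, date)]
  data.table::setDF(out)
  out
}
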