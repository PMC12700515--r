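# The 3-step model-selection procedure per (phenotype, dimension) pair:
#
#   step 1  random-intercept screen of all 20 x 5 pairs; a pair is retained
#           when the phenotype's two-tailed p < alpha AND Cohen f2 >= 0.01
#           (no multiplicity correction, by design: exploratory screen);
#   step 2  AR(1) residual correlation added; chi-square(1 df) LRT vs step 1;
#   step 3  random slope added to the current best structure; equal-weight
#           half-half chi-square(1)/chi-square(2) mixture LRT (variance on
#           the boundary plus a covariance). If the random-slope model fails
#           to converge without AR(1), it is retried with AR(1) included and
#           flagged.
#
# Also: random-intercept screening of demographic/clinical/medication/time
# covariates against phenotypes and dimensions, and confounder-interaction
# models for covariates significant on both sides of a retained pair.

#' Step-1 exploratory random-intercept screen
#'
#' Fits one random-intercept model per (phenotype, dimension) pair with the
#' phenotype as fixed covariate and patient as random intercept, and applies
#' the double gate `p < alpha` and `f2 >= f2_min`.
#'
#' @param table Modelling table from [build_analysis_table()].
#' @param phenotypes,dimensions Columns to cross (defaults: all 20 x 5).
#' @param alpha,f2_min Gate thresholds.
#' @param control Optimizer control for [fit_lmm()].
#' @return List of `selection_trace` objects (step 1 populated); pairs whose
#'   phenotype column is all-missing or constant are skipped with a reason.
#'   Summarize with [selection_summary()].
#' @export
step1_screen <- function(table, phenotypes = phenotype_names(),
                         dimensions = panss_dimensions(), alpha = 0.05,
                         f2_min = 0.01, control = lmm_control()) {
  traces <- list()
  for (ph in phenotypes) {
    v <- table[[ph]]
    skip <- NULL
    if (is.null(v) || all(is.na(v))) {
      skip <- "phenotype column absent or all missing"
    } else if (stats::sd(v, na.rm = TRUE) == 0 || !is.finite(stats::sd(v, na.rm = TRUE))) {
      skip <- "phenotype column has no variance"
    }
    for (dim in dimensions) {
      tr <- structure(list(phenotype = ph, dimension = dim, step1 = NULL,
                           step2 = NULL, step3 = NULL, best_model = NULL,
                           final_fixed_effect = NULL, fallback = FALSE,
                           skipped = skip),
                      class = "selection_trace")
      if (is.null(skip)) {
        fit <- fit_lmm(lmm_spec(dim, ph, "RI"), table, control)
        pv <- fit$p_values[[ph]]
        retained <- is.finite(pv) && pv < alpha && fit$f2 >= f2_min
        tr$step1 <- list(fit = fit, retained = retained,
                         reasons = c(if (!is.finite(pv) || pv >= alpha)
                                       sprintf("p = %.3g >= %.2g", pv, alpha),
                                     if (fit$f2 < f2_min)
                                       sprintf("f2 = %.3g < %.2g", fit$f2,
                                               f2_min)))
      }
      traces[[paste(ph, dim, sep = ".")]] <- tr
    }
  }
  traces
}

#' Complete steps 2-3 for a retained pair
#'
#' @param trace A `selection_trace` with `step1$retained` `TRUE`.
#' @param table The same modelling table used for step 1.
#' @param alpha Significance level for the LRTs.
#' @param control Optimizer control.
#' @return The completed `selection_trace`: step-2/step-3 fits and LRTs,
#'   `best_model` label, and final fixed-effect inference from the winning
#'   model.
#' @export
select_best_model <- function(trace, table, alpha = 0.05,
                              control = lmm_control()) {
  stopifnot(inherits(trace, "selection_trace"))
  if (is.null(trace$step1) || !trace$step1$retained) {
    .stopf("select_best_model: pair (%s, %s) was not retained at step 1",
           trace$phenotype, trace$dimension)
  }
  ph <- trace$phenotype; dim <- trace$dimension
  fit1 <- trace$step1$fit

  fit2 <- fit_lmm(lmm_spec(dim, ph, "RI_AR1"), table, control,
                  start = c(fit1$theta, atanh(0.2)))
  lrt2 <- lrt(fit2, fit1, "chi2_1")
  trace$step2 <- list(fit = fit2, lrt = lrt2)
  step2_won <- fit2$converged && lrt2$p_value < alpha
  best <- if (step2_won) fit2 else fit1
  best_label <- if (step2_won) "autocorrelation" else "random_intercept"

  struct3 <- if (step2_won) "RI_RS_AR1" else "RI_RS"
  warm <- if (step2_won) c(fit2$theta[1L], -5, 0, fit2$theta[2L])
          else c(fit1$theta, -5, 0)
  fit3 <- tryCatch(fit_lmm(lmm_spec(dim, ph, struct3, slope = ph), table,
                           control, start = warm),
                   error = function(e) NULL)
  if ((is.null(fit3) || !fit3$converged) && struct3 == "RI_RS") {
    # random-slope-only model failed: retry with AR(1) included, flagged
    fit3 <- tryCatch(fit_lmm(lmm_spec(dim, ph, "RI_RS_AR1", slope = ph),
                             table, control,
                             start = c(fit1$theta, -5, 0, atanh(0.2))),
                     error = function(e) NULL)
    struct3 <- "RI_RS_AR1"
    trace$fallback <- TRUE
  }
  if (!is.null(fit3) && fit3$converged &&
      fit3$minus2_loglik <= best$minus2_loglik + 1e-6) {
    lrt3 <- lrt(fit3, best, "mix_half_chi2_1_chi2_2")
    trace$step3 <- list(fit = fit3, lrt = lrt3, structure = struct3)
    if (lrt3$p_value < alpha) {
      best <- fit3
      best_label <- if (struct3 == "RI_RS_AR1" && step2_won)
        "autocorrelation_plus_random_slope"
      else if (trace$fallback) "autocorrelation_plus_random_slope"
      else "random_slope"
    }
  } else {
    trace$step3 <- list(fit = NULL, lrt = NULL, structure = struct3,
                        note = "step-3 model did not converge")
  }

  trace$best_model <- best_label
  est <- best$beta[[ph]]; se <- best$se[[ph]]
  df <- best$satterthwaite_df[[ph]]
  wt <- wald_t_test(est, se, df)
  trace$final_fixed_effect <- list(estimate = est, se = se, t = wt$t,
                                   df = df, p = wt$p)
  trace
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %s -> %s\n", x$phenotype, x$dimension))
  if (!is.null(x$skipped)) {
    cat("  skipped:", x$skipped, "\n"); return(invisible(x))
  }
  if (!is.null(x$step1)) {
    cat(sprintf("  step1: p = %s, f2 = %.3f, retained = %s\n",
                format_p(x$step1$fit$p_values[[x$phenotype]]),
                x$step1$fit$f2, x$step1$retained))
  }
  if (!is.null(x$best_model)) {
    fe <- x$final_fixed_effect
    cat(sprintf("  best model: %s%s | %.4g (%.4g), t(%.1f) = %.2f, p = %s\n",
                x$best_model, if (x$fallback) " [fallback]" else "",
                fe$estimate, fe$se, fe$df, fe$t, format_p(fe$p)))
  }
  invisible(x)
}

#' Flat summary of selection traces
#'
#' @param traces List of `selection_trace` objects.
#' @return data.frame, one row per pair, in the shape of a final
#'   model-selection report table (estimate, SE, t, df, p, f2, LRT rows,
#'   best-model label).
#' @export
selection_summary <- function(traces) {
  rows <- lapply(traces, function(tr) {
    base <- data.frame(phenotype = tr$phenotype, dimension = tr$dimension,
                       skipped = !is.null(tr$skipped),
                       retained = !is.null(tr$step1) && tr$step1$retained,
                       stringsAsFactors = FALSE)
    if (!is.null(tr$step1)) {
      f <- tr$step1$fit
      base$step1_p <- f$p_values[[tr$phenotype]]
      base$f2 <- f$f2
    } else {
      base$step1_p <- NA_real_; base$f2 <- NA_real_
    }
    base$step2_lambda <- if (!is.null(tr$step2)) tr$step2$lrt$statistic else NA_real_
    base$step2_p <- if (!is.null(tr$step2)) tr$step2$lrt$p_value else NA_real_
    has3 <- !is.null(tr$step3) && !is.null(tr$step3$lrt)
    base$step3_lambda <- if (has3) tr$step3$lrt$statistic else NA_real_
    base$step3_p <- if (has3) tr$step3$lrt$p_value else NA_real_
    base$best_model <- tr$best_model %||% NA_character_
    base$fallback <- isTRUE(tr$fallback)
    if (!is.null(tr$final_fixed_effect)) {
      fe <- tr$final_fixed_effect
      base$estimate <- fe$estimate; base$se <- fe$se; base$t <- fe$t
      base$df <- fe$df; base$p <- fe$p
    } else {
      base$estimate <- base$se <- base$t <- base$df <- base$p <- NA_real_
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full per-pair selection over a modelling table
#'
#' Convenience driver: step-1 screen of every pair, then steps 2-3 for the
#' retained ones.
#'
#' @inheritParams step1_screen
#' @return List of `selection_trace` objects, completed where retained.
#' @export
run_model_selection <- function(table, phenotypes = phenotype_names(),
                                dimensions = panss_dimensions(),
                                alpha = 0.05, f2_min = 0.01,
                                control = lmm_control()) {
  traces <- step1_screen(table, phenotypes, dimensions, alpha, f2_min,
                         control)
  for (nm in names(traces)) {
    if (!is.null(traces[[nm]]$step1) && traces[[nm]]$step1$retained) {
      traces[[nm]] <- select_best_model(traces[[nm]], table, alpha, control)
    }
  }
  traces
}

#' Random-intercept screening of covariates
#'
#' Tests each covariate as the sole predictor of each of the 20 phenotypes
#' and each of the 5 dimensions in random-intercept models (more complex
#' structures are not attempted for these between-patient variables). Factors
#' with 3 or more levels get Wald F-tests, others t-tests; the same
#' `p < alpha` and `f2 >= f2_min` gate applies.
#'
#' @param table Modelling table.
#' @param covariates Character vector of covariate columns.
#' @param phenotypes,dimensions Outcome rosters.
#' @param alpha,f2_min Gate thresholds.
#' @param control Optimizer control.
#' @return A `covariate_screen`: data.frame `results` (one row per covariate
#'   x outcome with statistic, p, f2, significance) plus `phenotype_hits` and
#'   `dimension_hits` maps.
#' @export
screen_covariates <- function(table, covariates,
                              phenotypes = phenotype_names(),
                              dimensions = panss_dimensions(),
                              alpha = 0.05, f2_min = 0.01,
                              control = lmm_control()) {
  rows <- list()
  for (cov in covariates) {
    v <- table[[cov]]
    if (is.null(v)) next
    is_factor <- is.character(v) || is.factor(v)
    lv <- if (is_factor) length(unique(stats::na.omit(v))) else NA_integer_
    skip <- NULL
    if (is_factor && lv < 2L) skip <- "factor with one observed level"
    if (!is_factor && (all(is.na(v)) || stats::sd(v, na.rm = TRUE) == 0)) {
      skip <- "covariate has no variance"
    }
    for (out_name in c(phenotypes, dimensions)) {
      kind <- if (out_name %in% dimensions) "dimension" else "phenotype"
      if (!is.null(skip)) {
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = cov, outcome = out_name, kind = kind,
          statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
          p = NA_real_, f2 = NA_real_, significant = FALSE, skipped = skip,
          stringsAsFactors = FALSE)
        next
      }
      fit <- fit_lmm(lmm_spec(out_name, cov, "RI"), table, control)
      cidx <- which(names(fit$beta) != "(Intercept)")
      if (is_factor && lv >= 3L) {
        ft <- .wald_F(fit, cidx)
        stat <- ft$F; df1 <- ft$df1; df2 <- ft$df2; p <- ft$p
      } else {
        stat <- fit$t_values[[cidx[[1L]]]]
        df1 <- 1; df2 <- fit$satterthwaite_df[[cidx[[1L]]]]
        p <- fit$p_values[[cidx[[1L]]]]
      }
      sig <- is.finite(p) && p < alpha && fit$f2 >= f2_min
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cov, outcome = out_name, kind = kind, statistic = stat,
        df1 = df1, df2 = df2, p = p, f2 = fit$f2, significant = sig,
        skipped = NA_character_, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(list(
    results = res,
    phenotype_hits = res[res$kind == "phenotype" & res$significant,
                         c("covariate", "outcome")],
    dimension_hits = res[res$kind == "dimension" & res$significant,
                         c("covariate", "outcome")]),
    class = "covariate_screen")
}

#' @export
print.covariate_screen <- function(x, ...) {
  cat(sprintf("<covariate_screen> %d tests, %d significant on phenotypes, %d on dimensions\n",
              nrow(x$results), nrow(x$phenotype_hits),
              nrow(x$dimension_hits)))
  invisible(x)
}

#' Is a covariate an eligible potential confounder for a pair?
#'
#' Eligibility requires significance in predicting both the digital phenotype
#' and the symptom dimension of the pair.
#'
#' @param screen A `covariate_screen`.
#' @param covariate,phenotype,dimension Names.
#' @return Logical scalar.
#' @export
confounder_eligible <- function(screen, covariate, phenotype, dimension) {
  ph_ok <- any(screen$phenotype_hits$covariate == covariate &
                 screen$phenotype_hits$outcome == phenotype)
  dim_ok <- any(screen$dimension_hits$covariate == covariate &
                  screen$dimension_hits$outcome == dimension)
  ph_ok && dim_ok
}

#' Confounder-interaction model for a retained pair
#'
#' Fits the pair's best random structure with fixed terms {phenotype,
#' covariate, phenotype x covariate} and reports the interaction and both
#' main effects. The pair is labelled `"confounded"` when the interaction or
#' the covariate main effect is significant while the phenotype effect loses
#' significance, `"robust"` otherwise.
#'
#' @param trace A completed `selection_trace`.
#' @param covariate Covariate name; must be eligible per the screening maps.
#' @param table Modelling table.
#' @param screen A `covariate_screen` for the eligibility check.
#' @param alpha Significance level.
#' @param control Optimizer control.
#' @return List: the fit, per-term inference rows, and the `conclusion`.
#' @export
interaction_analysis <- function(trace, covariate, table, screen,
                                 alpha = 0.05, control = lmm_control()) {
  stopifnot(inherits(trace, "selection_trace"))
  if (!confounder_eligible(screen, covariate, trace$phenotype,
                           trace$dimension)) {
    .stopf(paste("covariate '%s' is not an eligible confounder for",
                 "(%s, %s): it must be significant in predicting both the",
                 "digital phenotype and the symptom dimension"),
           covariate, trace$phenotype, trace$dimension)
  }
  struct <- switch(trace$best_model %||% "random_intercept",
                   random_intercept = "RI", autocorrelation = "RI_AR1",
                   random_slope = "RI_RS",
                   autocorrelation_plus_random_slope = "RI_RS_AR1")
  ph <- trace$phenotype
  spec <- lmm_spec(trace$dimension,
                   c(ph, covariate, paste(ph, covariate, sep = ":")),
                   struct, slope = ph)
  fit <- fit_lmm(spec, table, control)
  nm <- names(fit$beta)
  i_ph <- which(nm == ph)
  i_int <- which(grepl(":", nm, fixed = TRUE))
  i_cov <- which(startsWith(nm, covariate) & !grepl(":", nm, fixed = TRUE))
  row_of <- function(i) {
    if (!length(i)) return(NULL)
    i <- i[[1L]]
    data.frame(term = nm[[i]], estimate = fit$beta[[i]], se = fit$se[[i]],
               t = fit$t_values[[i]], df = fit$satterthwaite_df[[i]],
               p = fit$p_values[[i]], stringsAsFactors = FALSE)
  }
  terms <- do.call(rbind, list(row_of(i_ph), row_of(i_cov), row_of(i_int)))
  p_ph <- if (length(i_ph)) fit$p_values[[i_ph[[1L]]]] else NA_real_
  p_cov <- if (length(i_cov)) min(fit$p_values[i_cov]) else NA_real_
  p_int <- if (length(i_int)) min(fit$p_values[i_int]) else NA_real_
  confounded <- ((is.finite(p_int) && p_int < alpha) ||
                   (is.finite(p_cov) && p_cov < alpha)) &&
    (!is.finite(p_ph) || p_ph >= alpha)
  list(phenotype = ph, dimension = trace$dimension, covariate = covariate,
       structure = struct, fit = fit, terms = terms,
       conclusion = if (confounded) "confounded" else "robust")
}
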