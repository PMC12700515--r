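# Configuration, orchestration, logging and reporting for the end-to-end
# pipeline: simulate -> features -> aggregate -> analyze.

#' Build and validate a pipeline configuration
#'
#' @param truth A [simulation_truth()] (or a plain list of its fields) for
#'   simulate mode.
#' @param alignment Feature-to-rating alignment (see
#'   [build_analysis_table()]).
#' @param min_wake,min_sleep Monthly inclusion thresholds (5-minute windows).
#' @param min_hours Daily validity threshold (hours).
#' @param alpha Significance level for every gate.
#' @param f2_min Effect-size gate.
#' @param covariates Covariate roster for screening.
#' @param seed Seed; overrides the truth's seed so one value drives all
#'   randomness.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(truth = simulation_truth(),
                            alignment = "preceding",
                            min_wake = 720L, min_sleep = 480L,
                            min_hours = 18, alpha = 0.05, f2_min = 0.01,
                            covariates = c("gender", "diagnosis",
                                           "chlorpromazine_equivalents",
                                           "fluoxetine_equivalents",
                                           "followup_month"),
                            seed = NULL) {
  if (!inherits(truth, "simulation_truth")) {
    truth <- do.call(simulation_truth, truth)
  }
  if (!is.null(seed)) {
    truth$seed <- as.integer(seed)
  }
  cfg <- structure(list(truth = truth, alignment = alignment,
                        min_wake = as.integer(min_wake),
                        min_sleep = as.integer(min_sleep),
                        min_hours = min_hours, alpha = alpha,
                        f2_min = f2_min, covariates = covariates,
                        seed = truth$seed),
                   class = "pipeline_config")
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#' @param cfg A `pipeline_config`.
#' @return `cfg`, invisibly; errors before any computation otherwise.
#' @export
validate_config <- function(cfg) {
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) {
    .stopf("invalid config: alpha must lie in (0, 1), got %g", cfg$alpha)
  }
  if (cfg$min_wake <= 0 || cfg$min_sleep <= 0 || cfg$min_hours <= 0) {
    .stopf("invalid config: thresholds must be positive")
  }
  if (!cfg$alignment %in% c("preceding", "same")) {
    .stopf("invalid config: alignment must be 'preceding' or 'same'")
  }
  validate_truth(cfg$truth)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path File path; top-level keys are [pipeline_config()] arguments,
#'   with `truth` holding [simulation_truth()] fields (`fixed_slopes` as a
#'   list of `{phenotype, dimension, slope}` records).
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.null(raw$truth)) {
    tr <- raw$truth
    if (!is.null(tr$fixed_slopes)) {
      tr$fixed_slopes <- as.data.frame(tr$fixed_slopes,
                                       stringsAsFactors = FALSE)
    }
    if (!is.null(tr$fixed_intercepts)) {
      tr$fixed_intercepts <- unlist(tr$fixed_intercepts)
    }
    if (!is.null(tr$score_floors)) tr$score_floors <- unlist(tr$score_floors)
    raw$truth <- tr
  }
  do.call(pipeline_config, raw)
}

#' Demo configuration for a fast end-to-end run
#'
#' A reduced cohort (12 patients, at most 8 months) so the full window-level
#' pipeline completes in minutes on one CPU.
#'
#' @param seed Seed.
#' @return A `pipeline_config`.
#' @export
default_demo_config <- function(seed = 7L) {
  .set_stream(seed, 1L, 99L)
  fu <- pmin(sample.int(26L, 12L, replace = TRUE,
                        prob = .followup_weights()), 8L)
  pipeline_config(truth = simulation_truth(n_patients = 12,
                                           followup_months_per_patient = fu,
                                           seed = seed),
                  seed = seed)
}

#' Run the full pipeline
#'
#' Executes simulate -> features -> aggregate -> analyze, writing
#' `windows.csv`, `clinical.csv`, `features.csv`, `days.csv`,
#' `analysis_table.csv` (+ schema), `table2_like.csv`, `screening.csv`,
#' `interactions.csv`, a JSON audit log, a run log, and a MANIFEST stamped
#' with the config hash, seed and package version. On stage failure the
#' partial artifacts are kept and the MANIFEST records the incomplete state
#' before the error is re-signalled.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory.
#' @param verbose Log progress to stderr.
#' @return Invisibly, a list with the analysis table, selection traces,
#'   screening results and interaction reports.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (verbose) message(line)
  }
  cfg_json <- jsonlite::toJSON(list(
    alignment = config$alignment, min_wake = config$min_wake,
    min_sleep = config$min_sleep, min_hours = config$min_hours,
    alpha = config$alpha, f2_min = config$f2_min, seed = config$seed,
    truth = unclass(config$truth)), auto_unbox = TRUE, digits = NA,
    null = "null")
  manifest <- list(config_hash = .hash_chr(as.character(cfg_json)),
                   seed = config$seed,
                   version = as.character(utils::packageVersion("phenolmm")),
                   complete = FALSE, stages = character(0))
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                         auto_unbox = TRUE)
  }
  write_manifest()

  result <- tryCatch({
    logf("stage simulate: %d patients, seed %d", config$truth$n_patients,
         config$seed)
    bundle <- generate_cohort(config$truth, level = "windows")
    write_cohort(bundle, out_dir)
    logf("simulated %d windows, %d clinical rows", nrow(bundle$windows),
         nrow(bundle$clinical))
    manifest$stages <- c(manifest$stages, "simulate"); write_manifest()

    logf("stage features")
    validate_windows(bundle$windows)
    days <- day_summaries(bundle$windows, min_hours = config$min_hours)
    data.table::fwrite(data.table::as.data.table(bundle$windows),
                       file.path(out_dir, "features.csv"))
    data.table::fwrite(data.table::as.data.table(days),
                       file.path(out_dir, "days.csv"))
    logf("%d patient-days, %d valid (>= %g h)", nrow(days), sum(days$valid),
         config$min_hours)
    manifest$stages <- c(manifest$stages, "features"); write_manifest()

    logf("stage aggregate")
    pm <- aggregate_months(bundle$windows, days, config$min_wake,
                           config$min_sleep)
    tab <- build_analysis_table(pm, bundle$clinical, config$alignment)
    if (nrow(tab) == 0) {
      .stopf("no modelling rows remain after the completeness filters and join")
    }
    logf("%d patient-months, %d included, %d modelling rows (%d ratings unmatched)",
         nrow(pm), sum(pm$included), nrow(tab),
         attr(tab, "dropped_clinical"))
    data.table::fwrite(data.table::as.data.table(tab),
                       file.path(out_dir, "analysis_table.csv"))
    schema <- lapply(names(tab), function(nm) list(
      name = nm, type = class(tab[[nm]])[[1L]]))
    jsonlite::write_json(schema, file.path(out_dir,
                                           "analysis_table.schema.json"),
                         auto_unbox = TRUE)
    manifest$stages <- c(manifest$stages, "aggregate"); write_manifest()

    logf("stage analyze: step-1 screen of %d pairs",
         length(phenotype_names()) * length(panss_dimensions()))
    traces <- run_model_selection(tab, alpha = config$alpha,
                                  f2_min = config$f2_min)
    summ <- selection_summary(traces)
    n_ret <- sum(summ$retained, na.rm = TRUE)
    logf("retained %d pairs at p < %g and f2 >= %g (expect ~%.1f false positives among %d null screens)",
         n_ret, config$alpha, config$f2_min,
         config$alpha * nrow(summ), nrow(summ))
    data.table::fwrite(data.table::as.data.table(summ[summ$retained, ,
                                                      drop = FALSE]),
                       file.path(out_dir, "table2_like.csv"))

    screen <- screen_covariates(tab, config$covariates,
                                alpha = config$alpha,
                                f2_min = config$f2_min)
    data.table::fwrite(data.table::as.data.table(screen$results),
                       file.path(out_dir, "screening.csv"))
    logf("covariate screening: %d phenotype hits, %d dimension hits",
         nrow(screen$phenotype_hits), nrow(screen$dimension_hits))

    inter <- list()
    for (nm in names(traces)) {
      tr <- traces[[nm]]
      if (is.null(tr$best_model)) next
      for (cov in config$covariates) {
        if (confounder_eligible(screen, cov, tr$phenotype, tr$dimension)) {
          rep <- interaction_analysis(tr, cov, tab, screen,
                                      alpha = config$alpha)
          inter[[paste(nm, cov, sep = ".")]] <- rep
          logf("interaction %s x %s on %s: %s", tr$phenotype, cov,
               tr$dimension, rep$conclusion)
        }
      }
    }
    if (length(inter)) {
      irows <- do.call(rbind, lapply(inter, function(r) {
        data.frame(phenotype = r$phenotype, dimension = r$dimension,
                   covariate = r$covariate, structure = r$structure,
                   conclusion = r$conclusion,
                   interaction_p = r$terms$p[nrow(r$terms)],
                   stringsAsFactors = FALSE)
      }))
      data.table::fwrite(data.table::as.data.table(irows),
                         file.path(out_dir, "interactions.csv"))
    } else {
      data.table::fwrite(data.table::data.table(
        phenotype = character(0), dimension = character(0),
        covariate = character(0)), file.path(out_dir, "interactions.csv"))
    }

    audit <- list(
      config_hash = manifest$config_hash, seed = config$seed,
      traces = lapply(traces, function(tr) list(
        phenotype = tr$phenotype, dimension = tr$dimension,
        skipped = tr$skipped,
        retained = !is.null(tr$step1) && tr$step1$retained,
        step1 = if (!is.null(tr$step1)) fit_to_list(tr$step1$fit),
        step2 = if (!is.null(tr$step2)) list(
          fit = fit_to_list(tr$step2$fit), lrt = unclass(tr$step2$lrt)),
        step3 = if (!is.null(tr$step3) && !is.null(tr$step3$fit)) list(
          fit = fit_to_list(tr$step3$fit), lrt = unclass(tr$step3$lrt),
          structure = tr$step3$structure),
        best_model = tr$best_model, fallback = tr$fallback,
        final_fixed_effect = tr$final_fixed_effect)))
    jsonlite::write_json(audit, file.path(out_dir, "audit.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")

    manifest$stages <- c(manifest$stages, "analyze")
    manifest$complete <- TRUE
    write_manifest()
    logf("pipeline complete")
    list(table = tab, traces = traces, screening = screen,
         interactions = inter)
  }, error = function(e) {
    manifest$error <<- conditionMessage(e)
    write_manifest()
    logf("pipeline FAILED: %s", conditionMessage(e))
    stop(e)
  })
  invisible(result)
}
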