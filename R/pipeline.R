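#' Pipeline configuration
#'
#' Bundles every input of [run_pipeline()].  Either file paths to the three
#' canonical tables or `synthetic = TRUE` (the default, using the synthetic
#' generator) must be given.
#'
#' @param synthetic generate the cohort instead of reading files.
#' @param synthetic_cfg [synthetic_config()] when synthetic.
#' @param patient_path,visit_path,resource_path input tables otherwise.
#' @param column_map optional header renaming for file input.
#' @param unit_table,cpi costing inputs.
#' @param prior,mcmc model settings.
#' @param scenarios sensitivity suite (NULL to skip).
#' @param lambda_grid CEAC willingness-to-pay grid.
#' @param out_dir output directory.
#' @param seed master seed (also used for scenario seeds).
#' @param credible_level interval mass.
#' @param figures render CE-plane / CEAC figures as PDF (the data behind
#'   them is always written as CSV).
#' @export
pipeline_config <- function(synthetic = TRUE,
                            synthetic_cfg = synthetic_config(),
                            patient_path = NULL, visit_path = NULL,
                            resource_path = NULL, column_map = NULL,
                            unit_table = default_unit_costs(),
                            cpi = default_cpi(),
                            prior = prior_spec(),
                            mcmc = mcmc_config(),
                            scenarios = default_scenarios(),
                            lambda_grid = seq(0, 2000, length.out = 101),
                            out_dir = "sevocea_out",
                            seed = 1L,
                            credible_level = 0.95,
                            figures = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Loads or generates the cohort, computes per-patient outcomes and costs,
#' fits the bivariate Bayesian regression, summarizes the
#' cost-effectiveness results, optionally runs the sensitivity suite, and
#' writes a report bundle (CSV/JSON + optional PDF figures + run log) to the
#' configured output directory.  Re-running with the same configuration is
#' bit-identical.
#'
#' @param config [pipeline_config()].
#' @return invisibly, a list with `outcomes`, `costs`, `rows`, `draws`,
#'   `posterior_summary`, `cea`, `sensitivity` and `paths`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  log_line <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                                ..., "\n", sep = "", file = logf,
                                append = TRUE)
  cat("", file = logf)
  log_line("sevocea ", as.character(utils::packageVersion("sevocea")),
           "; master seed ", config$seed)

  stage <- "input"
  res <- tryCatch({
    aggregate_mode <- FALSE
    if (isTRUE(config$synthetic)) {
      cohort <- generate_cohort(config$synthetic_cfg, seed = config$seed,
                                unit_table = config$unit_table)
      log_line("synthetic cohort: ", nrow(cohort$patients), " patients (",
               attr(cohort, "n_resampled"), " SPID target resamples)")
    } else if (is.null(config$visit_path)) {
      # pre-aggregated input: the patient table already carries spid and
      # annual_cost, so the outcomes and costing stages are bypassed
      df <- read.csv(config$patient_path, stringsAsFactors = FALSE)
      if (!is.null(config$column_map)) {
        hit <- names(df) %in% names(config$column_map)
        names(df)[hit] <- unname(config$column_map[names(df)[hit]])
      }
      .require_columns(df, c("spid", "annual_cost"),
                       "aggregate patient table")
      cohort <- list(patients = patient_records(df), visits = NULL,
                     resources = NULL)
      aggregate_mode <- TRUE
      log_line("aggregate input: ", nrow(cohort$patients),
               " patients; outcomes and costing stages skipped")
    } else {
      cohort <- load_study_tables(config$patient_path, config$visit_path,
                                  config$resource_path, config$column_map)
      log_line("loaded cohort: ", nrow(cohort$patients), " patients")
    }
    if (!aggregate_mode) {
      vrep <- validate_cohort(cohort$patients, cohort$visits,
                              cohort$resources)
      jsonlite::write_json(
        vrep, file.path(config$out_dir, "validation_report.json"),
        dataframe = "rows")
      if (nrow(vrep) > 0)
        stop("cohort validation produced ", nrow(vrep), " finding(s); see ",
             file.path(config$out_dir, "validation_report.json"))
    }

    if (aggregate_mode) {
      pt <- cohort$patients
      outcomes <- data.frame(patient_id = pt$patient_id, spid = pt$spid)
      costs <- data.frame(patient_id = pt$patient_id,
                          annual_cost = pt$annual_cost)
    } else {
      stage <- "outcomes"
      outcomes <- compute_outcomes(cohort$patients, cohort$visits)
      write.csv(outcomes, file.path(config$out_dir, "outcomes.csv"),
                row.names = FALSE)

      stage <- "costing"
      costs <- compute_costs(cohort$patients, cohort$resources,
                             config$unit_table, config$cpi)
      write.csv(costs, file.path(config$out_dir, "costs.csv"),
                row.names = FALSE)
    }

    stage <- "model"
    rows <- build_analysis_rows(cohort$patients, outcomes, costs)
    md <- build_design(rows)
    draws <- gibbs_sample(md, config$prior,
                          mcmc_config(config$mcmc$burn_in,
                                      config$mcmc$kept_iterations,
                                      seed = config$seed,
                                      thin = config$mcmc$thin))
    psum <- summarize_posterior(draws, config$credible_level)
    write.csv(psum, file.path(config$out_dir, "posterior_summary.csv"),
              row.names = FALSE)

    stage <- "cea"
    cea_res <- cea_summary(draws, config$lambda_grid,
                           credible_level = config$credible_level)
    jsonlite::write_json(
      list(costs_ratio = cea_res$costs_ratio,
           incremental_effectiveness = cea_res$incremental_effectiveness,
           dominance = cea_res$dominance,
           icer = cea_res$icer[c("mean", "dominant", "n_excluded")]),
      file.path(config$out_dir, "cea_summary.json"),
      auto_unbox = TRUE, digits = NA)
    write.csv(cea_res$ceac, file.path(config$out_dir, "ceac.csv"),
              row.names = FALSE)
    write.csv(cea_res$ce_plane, file.path(config$out_dir, "ce_plane.csv"),
              row.names = FALSE)
    if (isTRUE(config$figures)) .render_figures(cea_res, config$out_dir)

    stage <- "sensitivity"
    sens <- NULL
    if (!is.null(config$scenarios)) {
      sens <- run_sensitivity_suite(rows, cohort, config$scenarios,
                                    config$prior, config$mcmc,
                                    config$unit_table, config$cpi,
                                    master_seed = config$seed)
      write.csv(sens$table,
                file.path(config$out_dir, "sensitivity_summary.csv"),
                row.names = FALSE)
    }
    log_line("pipeline complete")
    list(outcomes = outcomes, costs = costs, rows = rows, draws = draws,
         posterior_summary = psum, cea = cea_res, sensitivity = sens,
         paths = list(out_dir = config$out_dir, log = logf))
  }, error = function(e) {
    log_line("FAILED at stage '", stage, "': ", conditionMessage(e))
    writeLines(paste("FAILED at stage:", stage),
               file.path(config$out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

# CE plane and CEAC as PDF (device available headless everywhere)
.render_figures <- function(cea_res, out_dir) {
  grDevices::pdf(file.path(out_dir, "ce_plane.pdf"), width = 6, height = 5)
  plot(cea_res$ce_plane$incremental_effectiveness,
       cea_res$ce_plane$costs_ratio, pch = ".", col = "steelblue",
       xlab = "Incremental effectiveness (SPID units)",
       ylab = "Costs ratio", main = "Cost-effectiveness plane")
  graphics::abline(h = 1, lty = 2)   # cost neutrality is ratio = 1, not 0
  graphics::abline(v = 0, lty = 2)
  grDevices::dev.off()

  grDevices::pdf(file.path(out_dir, "ceac.pdf"), width = 6, height = 5)
  plot(cea_res$ceac$lambda, cea_res$ceac$probability, type = "l",
       lwd = 2, col = "steelblue", ylim = c(0, 1),
       xlab = "Willingness to pay (EUR per SPID unit)",
       ylab = "Probability cost-effective",
       main = "Cost-effectiveness acceptability curve")
  grDevices::dev.off()
  invisible(NULL)
}
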