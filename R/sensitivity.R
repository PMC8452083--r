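#' Define a sensitivity-analysis scenario
#'
#' Three mutually exclusive scenario families, mirroring the analysis plan:
#' one-way hospitalization-cost variants (re-cost every patient under an
#' alternative admission costing), a subgroup analysis excluding patients who
#' died or underwent leg amputation, and the extreme scenario (costs +25% for
#' the sevoflurane arm / -25% for the conventional arm, SPID -25% / +25%).
#' The base case is all families inactive.
#'
#' @param name scenario label.
#' @param cost_variant one of the [cost_admission()] variants, or NULL.
#' @param exclude_events drop patients with a death or amputation month.
#' @param extreme_multipliers NULL or a named list
#'   `list(sev_cost, conv_cost, sev_spid, conv_spid)`; the conventional
#'   default is `extreme_scenario()`'s 25% set.
#' @export
scenario <- function(name, cost_variant = NULL, exclude_events = FALSE,
                     extreme_multipliers = NULL) {
  active <- c(!is.null(cost_variant), isTRUE(exclude_events),
              !is.null(extreme_multipliers))
  if (sum(active) > 1)
    stop("at most one scenario family may be active")
  if (!is.null(cost_variant))
    cost_variant <- match.arg(cost_variant, COST_VARIANTS)
  structure(list(name = name, cost_variant = cost_variant,
                 exclude_events = isTRUE(exclude_events),
                 extreme_multipliers = extreme_multipliers),
            class = "scenario")
}

#' The conventional 25% extreme-scenario multipliers
#'
#' The 25% figure is data, not code: it was chosen post hoc by rounding up
#' the limits of the 95% confidence intervals for costs and SPID.
#' @param pct percent swing (default 25).
#' @export
extreme_scenario <- function(pct = 25) {
  f <- pct / 100
  list(sev_cost = 1 + f, conv_cost = 1 - f,
       sev_spid = 1 - f, conv_spid = 1 + f)
}

#' The full scenario suite of the analysis plan
#'
#' Base case, the three one-way hospitalization variants plus the two
#' attribution restrictions, the event-free subgroup, and the 25% extreme
#' scenario.
#' @export
default_scenarios <- function() {
  list(scenario("base_case"),
       scenario("drg_all_complications",
                cost_variant = "drg_all_complications"),
       scenario("drg_no_complications",
                cost_variant = "drg_no_complications"),
       scenario("admissions_ulcer_only",
                cost_variant = "admissions_ulcer_only"),
       scenario("admissions_pain_only",
                cost_variant = "admissions_pain_only"),
       scenario("per_diem", cost_variant = "per_diem"),
       scenario("exclude_events", exclude_events = TRUE),
       scenario("extreme_25pct",
                extreme_multipliers = extreme_scenario(25)))
}

#' Apply a scenario to base-case analysis rows
#'
#' Cost variants re-cost every patient from the resource-level records;
#' the subgroup scenario drops patients with death or amputation events;
#' the extreme scenario multiplies each arm's cost and SPID by its factors.
#' The base case returns the rows unchanged.
#'
#' @param rows base-case analysis rows.
#' @param cohort list with `patients` and `resources` (needed by cost
#'   variants and the exclusion rule; may be NULL for the extreme and base
#'   scenarios when `rows` carries `death_month` / `amputation_month`).
#' @param scen [scenario()].
#' @param unit_table,cpi costing inputs for the cost variants.
#' @return modified analysis rows.
#' @export
apply_scenario <- function(rows, cohort = NULL, scen = scenario("base_case"),
                           unit_table = default_unit_costs(),
                           cpi = default_cpi()) {
  if (!is.null(scen$cost_variant) && scen$cost_variant != "base_case") {
    if (is.null(cohort) || is.null(cohort$resources))
      stop("scenario '", scen$name,
           "' requires resource-level records to re-cost")
    costs <- compute_costs(cohort$patients, cohort$resources, unit_table,
                           cpi, variant = scen$cost_variant)
    idx <- match(rows$patient_id, costs$patient_id)
    rows$annual_cost <- costs$annual_cost[idx]
    # log-cost model needs strictly positive totals; attribution filters can
    # zero a patient's admissions but other components keep totals positive
    rows <- rows[rows$annual_cost > 0, , drop = FALSE]
    return(rows)
  }
  if (scen$exclude_events) {
    ev <- !is.na(rows$death_month) | !is.na(rows$amputation_month)
    return(rows[!ev, , drop = FALSE])
  }
  if (!is.null(scen$extreme_multipliers)) {
    m <- scen$extreme_multipliers
    sev <- rows$treatment == 1
    rows$annual_cost[sev] <- rows$annual_cost[sev] * m$sev_cost
    rows$annual_cost[!sev] <- rows$annual_cost[!sev] * m$conv_cost
    rows$spid[sev] <- rows$spid[sev] * m$sev_spid
    rows$spid[!sev] <- rows$spid[!sev] * m$conv_spid
    return(rows)
  }
  rows
}

#' Run the scenario sensitivity suite
#'
#' One fresh MCMC run per scenario on that scenario's rows.  Each scenario
#' gets an independent, reproducible seed derived from the master seed and a
#' hash of the scenario name, so suites are reproducible but scenarios are
#' not artificially correlated.  A scenario that fails (e.g. cannot re-cost)
#' is marked failed and the suite continues.
#'
#' @param rows base-case analysis rows.
#' @param cohort cohort list (see [apply_scenario()]).
#' @param scenarios list of [scenario()] objects
#'   (default [default_scenarios()]).
#' @param prior,mcmc model settings; the same chain length is used for every
#'   scenario.
#' @param unit_table,cpi costing inputs.
#' @param master_seed integer master seed.
#' @return list: `table` (data.frame scenario x {n, costs_ratio,
#'   incremental_effectiveness, p_cheaper, p_more_effective, p_dominant,
#'   status}), `summaries` (named list of [cea_summary()] objects).
#' @export
run_sensitivity_suite <- function(rows, cohort = NULL,
                                  scenarios = default_scenarios(),
                                  prior = prior_spec(),
                                  mcmc = mcmc_config(),
                                  unit_table = default_unit_costs(),
                                  cpi = default_cpi(),
                                  master_seed = 1L) {
  summaries <- list()
  recs <- lapply(scenarios, function(scen) {
    seed <- scenario_seed(master_seed, scen$name)
    out <- tryCatch({
      srows <- apply_scenario(rows, cohort, scen, unit_table, cpi)
      md <- build_design(srows)
      dr <- gibbs_sample(md, prior,
                         mcmc_config(mcmc$burn_in, mcmc$kept_iterations,
                                     seed = seed, thin = mcmc$thin))
      s <- cea_summary(dr)
      summaries[[scen$name]] <<- s
      data.frame(scenario = scen$name, n = nrow(srows),
                 costs_ratio = s$costs_ratio$mean,
                 incremental_effectiveness =
                   s$incremental_effectiveness$mean,
                 p_cheaper = s$dominance$p_cheaper,
                 p_more_effective = s$dominance$p_more_effective,
                 p_dominant = s$dominance$p_dominant,
                 status = "ok")
    }, error = function(e) {
      data.frame(scenario = scen$name, n = NA_integer_,
                 costs_ratio = NA_real_,
                 incremental_effectiveness = NA_real_,
                 p_cheaper = NA_real_, p_more_effective = NA_real_,
                 p_dominant = NA_real_,
                 status = paste("failed:", conditionMessage(e)))
    })
    out
  })
  list(table = do.call(rbind, recs), summaries = summaries)
}

#' Deterministic per-scenario seed below 2^31
#' @param master_seed integer master seed.
#' @param name scenario name.
#' @export
scenario_seed <- function(master_seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(master_seed) * 7919 + h * 104729) %% 2147483647)
}
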