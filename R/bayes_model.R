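COVARIATE_NAMES <- c("intercept", "aht", "ulcer_duration", "ulcer_number",
                     "ulcer_depth", "ulcer_pain", "treatment")

#' Build per-patient analysis rows from outcomes and costs
#'
#' Joins the per-patient SPID and annual cost to the baseline covariates,
#' producing the model's unit of analysis.
#'
#' @param patients validated patient table.
#' @param outcomes output of [compute_outcomes()].
#' @param costs output of [compute_costs()] (or any data.frame with
#'   `patient_id` and `annual_cost`).
#' @return data.frame of analysis rows: covariates, `annual_cost`, `spid`.
#' @export
build_analysis_rows <- function(patients, outcomes, costs) {
  df <- merge(patients[, c("patient_id", "group", "aht", "ulcer_duration",
                           "ulcer_number", "ulcer_depth", "baseline_pain",
                           "death_month", "amputation_month")],
              outcomes[, c("patient_id", "spid")], by = "patient_id")
  df <- merge(df, costs[, c("patient_id", "annual_cost")], by = "patient_id")
  names(df)[names(df) == "group"] <- "treatment"
  names(df)[names(df) == "baseline_pain"] <- "ulcer_pain"
  df[order(df$patient_id), , drop = FALSE]
}

#' Design matrix and bivariate response for the regression model
#'
#' Response column 1 is the natural log of annual cost (costs are
#' log-transformed as they are right-skewed), column 2 the untransformed
#' SPID.  The design is
#' `[1, AHT, UlcerDuration, min(UlcerNumber, 4), UlcerDepth, UlcerPain,
#' Treatment]`; the ulcer count is truncated at 4 here, never in the stored
#' records.
#'
#' @param rows analysis rows from [build_analysis_rows()] (columns
#'   `treatment`, `aht`, `ulcer_duration`, `ulcer_number`, `ulcer_depth`,
#'   `ulcer_pain`, `annual_cost`, `spid`).
#' @return list of class `model_data`: `X` (n x 7), `Y` (n x 2, log cost and
#'   SPID), `patient_id`, and `xbar_control` (covariate means over the
#'   conventional arm, used by the cost retransformation).
#' @export
build_design <- function(rows) {
  bad <- rows$annual_cost <= 0
  if (any(bad))
    stop("non-positive annual cost (log undefined) for patient(s): ",
         paste(rows$patient_id[bad], collapse = ", "))
  X <- cbind(1, rows$aht, rows$ulcer_duration, pmin(rows$ulcer_number, 4),
             rows$ulcer_depth, rows$ulcer_pain, rows$treatment)
  colnames(X) <- COVARIATE_NAMES
  Y <- cbind(log_cost = log(rows$annual_cost), spid = rows$spid)
  ctrl <- rows$treatment == 0
  xbar <- colMeans(X[ctrl, , drop = FALSE])
  xbar["treatment"] <- 0
  structure(list(X = X, Y = Y, patient_id = rows$patient_id,
                 xbar_control = xbar),
            class = "model_data")
}

#' Diffuse prior used by the analysis
#'
#' Independent normal priors on each equation's 7 coefficients, mean zero and
#' covariance `prior_var * I(7)` (default 1e5), and a Wishart prior on the
#' 2x2 error PRECISION matrix with `wishart_df` degrees of freedom and scale
#' parameter `wishart_scale` in the BUGS `dwish(R, k)` convention (defaults
#' df = 2, R = Identity(2)).
#'
#' @param prior_var coefficient prior variance (> 0).
#' @param wishart_df Wishart degrees of freedom (>= dimension).
#' @param wishart_scale 2x2 positive-definite scale matrix R.
#' @export
prior_spec <- function(prior_var = 1e5, wishart_df = 2,
                       wishart_scale = diag(2)) {
  stopifnot(prior_var > 0, wishart_df >= 2,
            all(dim(wishart_scale) == c(2, 2)))
  structure(list(prior_var = prior_var, wishart_df = wishart_df,
                 wishart_scale = wishart_scale), class = "prior_spec")
}

#' MCMC run configuration
#'
#' Defaults follow the analysis: a 10,000-iteration burn-in discarded, then
#' 100,000 retained iterations, single chain.
#'
#' @param burn_in discarded iterations (>= 0).
#' @param kept_iterations retained iterations (>= 1).
#' @param seed integer RNG seed.
#' @param thin thinning interval.
#' @export
mcmc_config <- function(burn_in = 10000, kept_iterations = 100000,
                        seed = 1L, thin = 1L) {
  stopifnot(burn_in >= 0, kept_iterations >= 1, thin >= 1)
  structure(list(burn_in = as.integer(burn_in),
                 kept_iterations = as.integer(kept_iterations),
                 seed = as.integer(seed), thin = as.integer(thin)),
            class = "mcmc_config")
}

#' Gibbs sampler for the bivariate cost/effectiveness regression
#'
#' Alternates the two full conditionals: the 14 coefficients given the error
#' precision (multivariate normal) and the error precision given the
#' coefficients (Wishart with df = prior df + n and scale updated by the
#' residual cross-products).  Identical seeds give bit-identical draws.
#'
#' @param model_data from [build_design()].
#' @param prior [prior_spec()].
#' @param config [mcmc_config()].
#' @return object of class `posterior_draws`: matrices `beta1` (cost
#'   equation), `beta2` (effectiveness equation), `sigma` (columns `s11`,
#'   `s22`, `s12` of the error covariance), plus `xbar_control`.
#' @export
gibbs_sample <- function(model_data, prior = prior_spec(),
                         config = mcmc_config()) {
  X <- model_data$X; Y <- model_data$Y
  if (nrow(X) <= ncol(X))
    stop("need more observations than covariates (n = ", nrow(X),
         ", p = ", ncol(X), ")")
  set.seed(config$seed)
  res <- .gibbs_bivariate_cpp(X, Y, prior$prior_var, prior$wishart_df,
                              prior$wishart_scale, config$burn_in,
                              config$kept_iterations, config$thin)
  colnames(res$beta1) <- colnames(res$beta2) <- colnames(X)
  colnames(res$sigma) <- c("s11", "s22", "s12")
  structure(list(beta1 = res$beta1, beta2 = res$beta2, sigma = res$sigma,
                 xbar_control = model_data$xbar_control,
                 config = config),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("posterior_draws:", nrow(x$beta1), "retained draws,",
      ncol(x$beta1), "coefficients per equation\n")
  invisible(x)
}

#' Posterior summary table
#'
#' Mean, SD and equal-tailed credible interval (2.5th / 97.5th percentiles at
#' the default level) for every coefficient of both equations, the costs
#' ratio `exp(beta_treatment)` of the cost equation, and the error covariance
#' entries.
#'
#' @param draws [gibbs_sample()] output.
#' @param credible_level interval mass (default 0.95).
#' @return data.frame: `parameter`, `mean`, `sd`, `lower`, `upper`.
#' @export
summarize_posterior <- function(draws, credible_level = 0.95) {
  mat <- cbind(
    setNames(as.data.frame(draws$beta1),
             paste0("cost.", colnames(draws$beta1))),
    setNames(as.data.frame(draws$beta2),
             paste0("spid.", colnames(draws$beta2))),
    costs_ratio = exp(draws$beta1[, "treatment"]),
    as.data.frame(draws$sigma))
  if (nrow(mat) < 2) stop("need at least 2 draws to summarize")
  a <- (1 - credible_level) / 2
  out <- data.frame(
    parameter = names(mat),
    mean = vapply(mat, mean, 0),
    sd = vapply(mat, sd, 0),
    lower = vapply(mat, quantile, 0, probs = a),
    upper = vapply(mat, quantile, 0, probs = 1 - a))
  rownames(out) <- NULL
  out
}
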