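#' Per-draw expected comparator-arm cost in euros
#'
#' The cost equation is on the log scale, so a euro-scale incremental cost
#' needs a retransformation convention.  The default evaluates the lognormal
#' mean at the conventional-arm covariate means for each draw:
#' `exp(xbar' beta1 + s11 / 2)`.  Dominance probabilities never depend on
#' this choice (the sign of the incremental cost is the sign of the treatment
#' coefficient).
#'
#' @param draws [gibbs_sample()] output.
#' @param xbar covariate-mean vector with `treatment` = 0; defaults to the
#'   one carried by the draws.
#' @return numeric vector, one euro value per draw.
#' @export
expected_comparator_cost <- function(draws, xbar = draws$xbar_control) {
  lp <- drop(draws$beta1 %*% xbar) + draws$sigma[, "s11"] / 2
  exp(lp)
}

#' Costs ratio summary
#'
#' Summarizes `exp(beta_treatment)` of the cost equation over the draws
#' (mean of the exponentials, not the exponential of the mean) together with
#' the relative incremental cost `(exp(beta_treatment) - 1) * 100` percent.
#'
#' @inheritParams expected_comparator_cost
#' @param credible_level interval mass (default 0.95).
#' @return list: `mean`, `sd`, `lower`, `upper` of the ratio, and
#'   `relative_incremental_cost_pct` (its mean, in percent).
#' @export
costs_ratio <- function(draws, credible_level = 0.95) {
  r <- exp(draws$beta1[, "treatment"])
  c(.summary_stats(r, credible_level),
    list(relative_incremental_cost_pct = (mean(r) - 1) * 100))
}

#' Incremental effectiveness summary
#'
#' Mean, SD and credible interval of the treatment coefficient of the
#' effectiveness (SPID) equation.
#'
#' @inheritParams costs_ratio
#' @export
incremental_effectiveness <- function(draws, credible_level = 0.95) {
  .summary_stats(draws$beta2[, "treatment"], credible_level)
}

#' Dominance probabilities
#'
#' Fractions of draws in which the intervention is cheaper (cost-equation
#' treatment coefficient < 0), more effective (effectiveness treatment
#' coefficient > 0), and both at once (dominant).
#'
#' @inheritParams costs_ratio
#' @return list: `p_cheaper`, `p_more_effective`, `p_dominant`.
#' @export
dominance_probabilities <- function(draws) {
  cheaper <- draws$beta1[, "treatment"] < 0
  effective <- draws$beta2[, "treatment"] > 0
  list(p_cheaper = mean(cheaper),
       p_more_effective = mean(effective),
       p_dominant = mean(cheaper & effective))
}

#' Incremental cost-effectiveness ratio (euros per SPID unit)
#'
#' Per-draw incremental cost is the comparator cost times
#' `exp(beta_treatment) - 1`; the ICER divides it by the per-draw incremental
#' effectiveness.  When the posterior probability of dominance exceeds
#' `dominance_threshold` the ICER is flagged uninformative (a dominant
#' intervention has a negative-over-positive ratio).
#'
#' @inheritParams costs_ratio
#' @param baseline_cost per-draw comparator cost vector or a single euro
#'   value; defaults to [expected_comparator_cost()].
#' @param dominance_threshold probability above which the ICER is flagged
#'   "dominant" (default 0.5).
#' @return list: summary stats of the ICER draws, `dominant` flag,
#'   `n_excluded` (draws with exactly zero incremental effectiveness).
#' @export
icer <- function(draws, baseline_cost = expected_comparator_cost(draws),
                 dominance_threshold = 0.5, credible_level = 0.95) {
  inc_cost <- baseline_cost * (exp(draws$beta1[, "treatment"]) - 1)
  de <- draws$beta2[, "treatment"]
  keep <- de != 0
  ratio <- inc_cost[keep] / de[keep]
  dom <- dominance_probabilities(draws)$p_dominant > dominance_threshold
  c(.summary_stats(ratio, credible_level),
    list(dominant = dom, n_excluded = sum(!keep)))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value `lambda` (euros per SPID unit), the
#' probability that the intervention's incremental net monetary benefit is
#' positive: the fraction of draws with
#' `lambda * incremental_effectiveness - incremental_cost > 0`.
#' At `lambda = 0` the curve equals the probability of being cheaper; as
#' `lambda` grows it approaches the probability of being more effective.
#'
#' @inheritParams icer
#' @param lambda_grid non-negative euro values (default 0 to 2000 in 101
#'   steps).
#' @return data.frame: `lambda`, `probability`.
#' @export
ceac <- function(draws, lambda_grid = seq(0, 2000, length.out = 101),
                 baseline_cost = expected_comparator_cost(draws)) {
  if (any(lambda_grid < 0)) stop("willingness-to-pay values must be >= 0")
  inc_cost <- baseline_cost * (exp(draws$beta1[, "treatment"]) - 1)
  de <- draws$beta2[, "treatment"]
  prob <- vapply(lambda_grid, function(l) mean(l * de - inc_cost > 0), 0)
  data.frame(lambda = lambda_grid, probability = prob)
}

#' Cost-effectiveness plane point set
#'
#' One point per draw: x = incremental effectiveness, y = costs ratio.  Note
#' the cost-neutrality line is y = 1 (a ratio), not y = 0.
#'
#' @inheritParams costs_ratio
#' @return data.frame `incremental_effectiveness`, `costs_ratio`, with
#'   attribute `neutral_cost_line = 1`.
#' @export
ce_plane <- function(draws) {
  out <- data.frame(incremental_effectiveness = draws$beta2[, "treatment"],
                    costs_ratio = exp(draws$beta1[, "treatment"]))
  attr(out, "neutral_cost_line") <- 1
  out
}

#' Full cost-effectiveness summary
#'
#' Bundles the costs ratio, incremental effectiveness, dominance
#' probabilities, ICER (flagged under dominance), CE plane points and CEAC
#' into one object.
#'
#' @inheritParams ceac
#' @inheritParams icer
#' @export
cea_summary <- function(draws,
                        lambda_grid = seq(0, 2000, length.out = 101),
                        baseline_cost = expected_comparator_cost(draws),
                        credible_level = 0.95,
                        dominance_threshold = 0.5) {
  structure(list(
    costs_ratio = costs_ratio(draws, credible_level),
    incremental_effectiveness =
      incremental_effectiveness(draws, credible_level),
    dominance = dominance_probabilities(draws),
    icer = icer(draws, baseline_cost, dominance_threshold, credible_level),
    ce_plane = ce_plane(draws),
    ceac = ceac(draws, lambda_grid, baseline_cost)
  ), class = "cea_summary")
}

#' @export
print.cea_summary <- function(x, ...) {
  cat("Cost-effectiveness summary\n")
  cat(sprintf("  costs ratio:               %.2f (SD %.2f), 95%% CrI (%.2f, %.2f)\n",
              x$costs_ratio$mean, x$costs_ratio$sd,
              x$costs_ratio$lower, x$costs_ratio$upper))
  cat(sprintf("  relative incremental cost: %+.0f%%\n",
              x$costs_ratio$relative_incremental_cost_pct))
  cat(sprintf("  incremental effectiveness: %.2f (SD %.2f), 95%% CrI (%.2f, %.2f)\n",
              x$incremental_effectiveness$mean, x$incremental_effectiveness$sd,
              x$incremental_effectiveness$lower,
              x$incremental_effectiveness$upper))
  cat(sprintf("  P(cheaper) = %.0f%%  P(more effective) = %.0f%%  P(dominant) = %.0f%%\n",
              100 * x$dominance$p_cheaper, 100 * x$dominance$p_more_effective,
              100 * x$dominance$p_dominant))
  if (isTRUE(x$icer$dominant))
    cat("  ICER: dominant - ICER not informative\n")
  else
    cat(sprintf("  ICER: %.0f EUR per SPID unit\n", x$icer$mean))
  invisible(x)
}

.summary_stats <- function(x, credible_level = 0.95) {
  a <- (1 - credible_level) / 2
  list(mean = mean(x), sd = sd(x),
       lower = unname(quantile(x, a)), upper = unname(quantile(x, 1 - a)))
}
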