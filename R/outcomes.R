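#' Extend a patient's pain trajectory to the end of follow-up
#'
#' Implements last-observation-carried-forward: patients whose observation was
#' cut short (death or leg amputation before month 12) keep their last
#' recorded pain score as the final score.  A terminal visit at
#' `horizon_months` carrying the last observed pain is appended; observed
#' visits are returned unchanged.  If a visit at the horizon already exists
#' the trajectory is returned as-is.
#'
#' @param visits data.frame with `time` and `pain` for ONE patient, times
#'   strictly increasing from 0.
#' @param horizon_months follow-up horizon (default 12).
#' @return data.frame (`time`, `pain`) ending at the horizon.
#' @export
carry_forward_final_pain <- function(visits, horizon_months = 12) {
  if (nrow(visits) == 0L) stop("empty visit sequence: cannot carry forward")
  v <- visits[order(visits$time), c("time", "pain"), drop = FALSE]
  last <- v[nrow(v), ]
  if (last$time < horizon_months)
    v <- rbind(v, data.frame(time = horizon_months, pain = last$pain))
  rownames(v) <- NULL
  v
}

#' Sum of Pain Intensity Difference
#'
#' Time-weighted sum of pain differences from baseline over the follow-up
#' horizon: the pain at each follow-up visit is subtracted from the pain at
#' the first (time-0) visit and the difference weighted by the time elapsed
#' since the previous evaluation, in months:
#' \deqn{SPID = \sum_v (P_0 - P_v)\,(t_v - t_{v-1}).}
#' Higher SPID means greater cumulative pain relief; the attainable range for
#' a 12-month horizon on the 0-10 NRS is \[-120, 120\].
#'
#' @param visits data.frame (`time`, `pain`) for one patient, complete to the
#'   horizon (apply [carry_forward_final_pain()] first).
#' @param horizon_months follow-up horizon in months (default 12).
#' @return numeric SPID in NRS-point-months.
#' @export
compute_spid <- function(visits, horizon_months = 12) {
  v <- visits[order(visits$time), , drop = FALSE]
  if (nrow(v) < 1L || v$time[1] != 0)
    stop("visits must start with the baseline (time-0) visit")
  if (max(v$time) < horizon_months)
    stop("visits do not reach the ", horizon_months,
         "-month horizon; apply carry_forward_final_pain() first")
  p0 <- v$pain[1]
  dt <- diff(v$time)
  sum((p0 - v$pain[-1]) * dt)
}

#' Percent pain reduction from baseline to final score
#'
#' @param baseline baseline NRS (> 0 for a defined rate).
#' @param final final NRS.
#' @return `100 * (baseline - final) / baseline`, or `NA` (flagged missing)
#'   when baseline is 0.
#' @export
pain_reduction_rate <- function(baseline, final) {
  ifelse(baseline > 0, 100 * (baseline - final) / baseline, NA_real_)
}

#' Daily oral morphine equivalents
#'
#' Converts a set of opioid regimens to a common mg/day oral-morphine scale
#' using a user-supplied conversion table (the factors themselves are not part
#' of this package).
#'
#' @param regimens data.frame with `opioid` and `daily_dose` (mg/day in the
#'   drug's own units).
#' @param conversion_table data.frame with `opioid` and `factor`.
#' @return total mg/day oral morphine equivalents.
#' @export
daily_ome <- function(regimens, conversion_table) {
  if (nrow(regimens) == 0L) return(0)
  idx <- match(regimens$opioid, conversion_table$opioid)
  if (anyNA(idx))
    stop("no conversion factor for opioid(s): ",
         paste(unique(regimens$opioid[is.na(idx)]), collapse = ", "))
  sum(regimens$daily_dose * conversion_table$factor[idx])
}

#' Post hoc power for a two-sample difference in means
#'
#' Normal-approximation power of the two-sided two-sample test at the observed
#' group means, a common SD and the achieved group sizes (the formula used by
#' sample-size calculators such as GRANMO's two-means module).  A noncentral-t
#' variant is available; both agree to the integer percent at study-like
#' inputs.
#'
#' @param mean_a,mean_b group means.
#' @param common_sd assumed common standard deviation (> 0).
#' @param n_a,n_b group sizes (>= 2).
#' @param alpha significance level (default 0.05).
#' @param two_sided logical (default TRUE).
#' @param method "normal" (default) or "t" (noncentral t).
#' @return power as a percent rounded to the nearest integer.
#' @export
posthoc_power <- function(mean_a, mean_b, common_sd, n_a, n_b,
                          alpha = 0.05, two_sided = TRUE,
                          method = c("normal", "t")) {
  method <- match.arg(method)
  if (common_sd <= 0) stop("common_sd must be > 0")
  if (n_a < 2 || n_b < 2) stop("group sizes must be >= 2")
  se <- common_sd * sqrt(1 / n_a + 1 / n_b)
  ncp <- (mean_a - mean_b) / se
  a <- if (two_sided) alpha / 2 else alpha
  if (method == "normal") {
    z <- qnorm(1 - a)
    pow <- pnorm(ncp - z) + if (two_sided) pnorm(-ncp - z) else 0
  } else {
    df <- n_a + n_b - 2
    tc <- stats::qt(1 - a, df)
    pow <- stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
      if (two_sided) stats::pt(-tc, df, ncp = ncp) else 0
  }
  round(100 * pow)
}

#' Per-patient outcome set
#'
#' Applies carry-forward and computes SPID, final pain, percent pain
#' reduction and follow-up completion for every patient in the cohort.
#'
#' @param patients,visits validated record tables.
#' @param horizon_months follow-up horizon (default 12).
#' @return data.frame, one row per patient: `patient_id`, `group`, `spid`,
#'   `baseline_pain`, `final_pain`, `pain_reduction_rate`,
#'   `completed_followup` (0 when death or amputation occurred before the
#'   horizon).
#' @export
compute_outcomes <- function(patients, visits, horizon_months = 12) {
  out <- lapply(seq_len(nrow(patients)), function(i) {
    id <- patients$patient_id[i]
    v <- visits[visits$patient_id == id, c("time", "pain"), drop = FALSE]
    if (nrow(v) == 0L)
      stop("patient ", id, " has no visits")
    v <- carry_forward_final_pain(v, horizon_months)
    p0 <- v$pain[v$time == 0]
    pf <- v$pain[nrow(v)]
    data.frame(
      patient_id = id,
      group = patients$group[i],
      spid = compute_spid(v, horizon_months),
      baseline_pain = p0,
      final_pain = pf,
      pain_reduction_rate = pain_reduction_rate(p0, pf),
      completed_followup = as.integer(is.na(patients$death_month[i]) &&
                                        is.na(patients$amputation_month[i]))
    )
  })
  do.call(rbind, out)
}

#' Group descriptive summaries with standard two-group tests
#'
#' Per-arm mean (SD) for continuous variables with a Mann-Whitney U test, and
#' n (%) for binary variables with a chi-square or Fisher exact test
#' (Fisher when any expected cell count is below 5).
#'
#' @param df data.frame containing `group` plus the variables to summarize.
#' @param continuous,binary character vectors of column names.
#' @return data.frame: variable, per-group summary strings, test used,
#'   p-value.
#' @export
group_descriptives <- function(df, continuous = character(),
                               binary = character()) {
  g1 <- df$group == 1; g0 <- df$group == 0
  rows <- list()
  fmt <- function(x) sprintf("%.1f (%.1f)", mean(x), sd(x))
  for (v in continuous) {
    x1 <- df[[v]][g1]; x0 <- df[[v]][g0]
    p <- if (length(unique(c(x1, x0))) == 1L) 1 else
      suppressWarnings(wilcox.test(x1, x0)$p.value)
    rows[[v]] <- data.frame(variable = v, sevoflurane = fmt(x1),
                            conventional = fmt(x0), test = "mann-whitney",
                            p_value = p)
  }
  for (v in binary) {
    tab <- table(factor(df$group, levels = c(1, 0)),
                 factor(df[[v]], levels = c(0, 1)))
    use_fisher <- any(suppressWarnings(chisq.test(tab)$expected) < 5)
    p <- if (use_fisher) fisher.test(tab)$p.value else
      suppressWarnings(chisq.test(tab)$p.value)
    pct <- function(g) sprintf("%d (%.0f%%)", sum(df[[v]][g] == 1),
                               100 * mean(df[[v]][g] == 1))
    rows[[v]] <- data.frame(variable = v, sevoflurane = pct(g1),
                            conventional = pct(g0),
                            test = if (use_fisher) "fisher" else "chi-square",
                            p_value = p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
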