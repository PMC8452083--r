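test_that("carry-forward extends truncated trajectories with the last pain", {
  v <- data.frame(time = c(0, 6), pain = c(8, 3))       # death at month 7
  got <- carry_forward_final_pain(v)
  expect_equal(got[nrow(got), ], data.frame(time = 12, pain = 3),
               ignore_attr = TRUE)
  expect_equal(got[1:2, ], v, ignore_attr = TRUE)       # observed unchanged

  done <- data.frame(time = c(0, 12), pain = c(8, 2))
  expect_equal(carry_forward_final_pain(done), done, ignore_attr = TRUE)

  single <- carry_forward_final_pain(data.frame(time = 0, pain = 8))
  expect_equal(compute_spid(single), 0)                 # constant pain

  expect_error(carry_forward_final_pain(data.frame(time = numeric(),
                                                   pain = numeric())),
               "empty")
})

test_that("compute_spid matches the hand-summed oracle and errors early", {
  expect_equal(compute_spid(data.frame(time = c(0, 6, 12),
                                       pain = c(6, 6, 6))), 0)
  expect_equal(compute_spid(data.frame(time = c(0, 12), pain = c(8, 0))), 96)
  # irregular schedule, term-by-term: 2*3 + 4*6 + 5*3 = 45
  expect_equal(compute_spid(data.frame(time = c(0, 3, 9, 12),
                                       pain = c(6, 4, 2, 1))), 45)
  expect_error(compute_spid(data.frame(time = c(0, 6), pain = c(8, 3))),
               "carry_forward")
  expect_error(compute_spid(data.frame(time = c(1, 12), pain = c(8, 3))),
               "baseline")
})

test_that("SPID invariance properties hold on random trajectories", {
  set.seed(42)
  for (rep in 1:25) {
    k <- sample(2:6, 1)
    times <- c(0, sort(runif(k, 0.5, 11.5)), 12)
    pains <- sample(0:10, k + 2, replace = TRUE)
    v <- data.frame(time = times, pain = pains)
    s <- compute_spid(v)

    # inserting a redundant visit between two equal-pain visits is a no-op
    j <- sample(seq_len(k + 1), 1)
    v2 <- v; v2$pain[j + 1] <- v2$pain[j]
    mid <- (v2$time[j] + v2$time[j + 1]) / 2
    v3 <- rbind(v2[1:j, ],
                data.frame(time = mid, pain = v2$pain[j]),
                v2[(j + 1):nrow(v2), ])
    expect_equal(compute_spid(v3), compute_spid(v2))

    # shifting every pain (baseline included) leaves differences unchanged
    v4 <- v; v4$pain <- v4$pain + 5
    expect_equal(compute_spid(v4), s)

    # monotone non-increasing pain: 0 <= SPID <= (P0 - Pmin) * horizon
    vm <- data.frame(time = times, pain = sort(pains, decreasing = TRUE))
    sm <- compute_spid(vm)
    expect_gte(sm, 0)
    expect_lte(sm, (vm$pain[1] - min(vm$pain)) * 12)
  }
})

test_that("carry-forward + SPID equals step-function integration", {
  # death at month m with constant pain thereafter; oracle integrates the
  # step function (P0 - P(t)) on a fine grid
  set.seed(7)
  for (rep in 1:10) {
    m <- runif(1, 2, 11)
    times <- c(0, sort(runif(2, 0.2, m - 0.1)))
    pains <- sample(0:10, 3, replace = TRUE)
    v <- carry_forward_final_pain(data.frame(time = times, pain = pains))
    # the difference at a visit applies over the interval ENDING there, so
    # the step function carries each visit's pain backwards to the previous
    # visit time
    grid <- seq(0, 12, by = 1e-3)
    pain_at <- vapply(grid[-1], function(t) {
      v$pain[min(which(v$time >= t - 1e-12))]
    }, 0)
    oracle <- sum((pains[1] - pain_at) * diff(grid))
    expect_equal(compute_spid(v), oracle, tolerance = 1e-2)
  }
})

test_that("pain reduction rate follows its definition and flags baseline 0", {
  expect_equal(pain_reduction_rate(5, 5), 0)
  expect_equal(pain_reduction_rate(8, 0), 100)
  expect_equal(pain_reduction_rate(6.7, 1.1), 100 * (6.7 - 1.1) / 6.7)
  expect_true(is.na(pain_reduction_rate(0, 0)))
})

test_that("daily OME sums dose times factor and names missing opioids", {
  tab <- data.frame(opioid = c("morphine_oral", "oxycodone_oral"),
                    factor = c(1, 2))
  expect_equal(daily_ome(data.frame(opioid = "morphine_oral",
                                    daily_dose = 60), tab), 60)
  expect_equal(daily_ome(data.frame(opioid = c("morphine_oral",
                                               "oxycodone_oral"),
                                    daily_dose = c(30, 10)), tab), 50)
  expect_equal(daily_ome(data.frame(opioid = character(),
                                    daily_dose = numeric()), tab), 0)
  expect_error(daily_ome(data.frame(opioid = "fentanyl_td",
                                    daily_dose = 1), tab), "fentanyl_td")
})

test_that("post hoc power: null case, t-method simulation oracle, errors", {
  expect_equal(posthoc_power(10, 10, 5, 20, 20), 5)   # power = alpha
  expect_error(posthoc_power(1, 0, 0, 20, 20), "common_sd")
  expect_error(posthoc_power(1, 0, 1, 1, 20), "group sizes")

  # Monte-Carlo oracle: simulate the pooled two-sample t-test at the same
  # inputs, 1e5 replicates (vectorized)
  set.seed(123)
  nsim <- 1e5
  x <- matrix(rnorm(20 * nsim, 1, 1), 20)
  y <- matrix(rnorm(20 * nsim, 0, 1), 20)
  sp2 <- (19 * apply(x, 2, var) + 19 * apply(y, 2, var)) / 38
  tstat <- (colMeans(x) - colMeans(y)) / sqrt(sp2 * (2 / 20))
  pvals <- 2 * stats::pt(-abs(tstat), df = 38)
  mc_power <- round(100 * mean(pvals < 0.05))
  expect_lte(abs(posthoc_power(1, 0, 1, 20, 20, method = "t") - mc_power), 1)
  # normal approximation is close but may differ by a point or two here
  expect_lte(abs(posthoc_power(1, 0, 1, 20, 20) - mc_power), 3)
})

test_that("group descriptives: degenerate SD, symmetry, Fisher enumeration", {
  df <- data.frame(group = rep(c(1, 0), c(8, 12)),
                   val = rep(3, 20),
                   sym = c(rep(1:4, 2), rep(1:4, 3)),
                   event = rep(c(1, 0), c(8, 12)))
  out <- group_descriptives(df, continuous = c("val", "sym"),
                            binary = "event")
  expect_match(out$sevoflurane[out$variable == "val"], "3.0 \\(0.0\\)")
  expect_equal(out$p_value[out$variable == "val"], 1)     # identical groups
  expect_gt(out$p_value[out$variable == "sym"], 0.9)      # same distribution

  # exact test against full hypergeometric enumeration: 8/8 vs 0/12 events
  p_obs <- out$p_value[out$variable == "event"]
  probs <- stats::dhyper(0:8, 8, 12, 8)   # events in the treated row
  oracle <- sum(probs[probs <= probs[9] * (1 + 1e-7)])
  expect_equal(p_obs, oracle, tolerance = 1e-10)
  expect_equal(out$test[out$variable == "event"], "fisher")
})

test_that("compute_outcomes assembles SPID and completion per patient", {
  out <- compute_outcomes(toy_patients(), toy_visits())
  # A: (8-3)*6 + (8-1)*6 = 72
  expect_equal(out$spid[out$patient_id == "A"], 72)
  # B truncated by death at 7: (6-5)*6 + (6-5)*6 = 12
  expect_equal(out$spid[out$patient_id == "B"], 12)
  expect_equal(out$completed_followup, c(1, 0, 1))
  expect_equal(out$final_pain[out$patient_id == "C"], 2)  # carried forward
})
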