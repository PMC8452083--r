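test_that("costs ratio summarizes exp draws, not exp of the summary", {
  d0 <- make_draws(beta17 = rep(0, 5), beta27 = rep(1, 5))
  r0 <- costs_ratio(d0)
  expect_equal(r0$mean, 1)
  expect_equal(r0$relative_incremental_cost_pct, 0)

  d3 <- make_draws(beta17 = c(-0.5, 0, 0.5), beta27 = rep(1, 3))
  expect_equal(costs_ratio(d3)$mean, (exp(-0.5) + 1 + exp(0.5)) / 3)

  # Jensen: mean of exponentials >= exponential of the mean, strict when
  # draws vary
  set.seed(21)
  for (rep in 1:10) {
    b <- rnorm(200, -0.6, 0.3)
    dr <- make_draws(b, rep(1, 200))
    expect_gt(costs_ratio(dr)$mean, exp(mean(b)))
  }
})

test_that("incremental effectiveness summarizes the raw draws", {
  d <- make_draws(rep(0, 4), rep(1, 4))
  ie <- incremental_effectiveness(d)
  expect_equal(ie$mean, 1); expect_equal(ie$sd, 0)

  set.seed(22)
  dn <- make_draws(rep(0, 2e4), rnorm(2e4, 5, 1))
  expect_equal(incremental_effectiveness(dn)$mean, 5, tolerance = 0.05)
})

test_that("dominance probabilities count draw signs jointly", {
  d <- make_draws(beta17 = c(-1, -1, 1, -1), beta27 = c(1, -1, 1, 1))
  p <- dominance_probabilities(d)
  expect_equal(p, list(p_cheaper = 0.75, p_more_effective = 0.75,
                       p_dominant = 0.5))

  all_dom <- make_draws(rep(-0.2, 8), rep(3, 8))
  expect_equal(dominance_probabilities(all_dom),
               list(p_cheaper = 1, p_more_effective = 1, p_dominant = 1))

  # invariant on random draw sets
  set.seed(23)
  for (rep in 1:20) {
    dr <- make_draws(rnorm(100), rnorm(100))
    p <- dominance_probabilities(dr)
    expect_lte(p$p_dominant, min(p$p_cheaper, p$p_more_effective))
    expect_true(all(unlist(p) >= 0 & unlist(p) <= 1))
  }
})

test_that("ICER retransforms the ratio and is suppressed under dominance", {
  d1 <- make_draws(c(0, 0), c(1, 1), s11 = c(0, 0))  # ratio 1 -> inc cost 0
  expect_equal(icer(d1, baseline_cost = 10000)$mean, 0)

  d2 <- make_draws(c(log(0.5), log(0.5)), c(25, 25), s11 = c(0, 0))
  i2 <- icer(d2, baseline_cost = 10000)
  expect_equal(i2$mean, (10000 * (0.5 - 1)) / 25)      # -200 EUR per unit
  expect_true(i2$dominant)                              # p_dominant = 1
  expect_equal(i2$n_excluded, 0)

  d3 <- make_draws(c(-1, -1, -1), c(25, 0, 25))
  expect_equal(icer(d3, baseline_cost = 1)$n_excluded, 1)
})

test_that("comparator-cost retransformation is the lognormal mean", {
  d <- make_draws(beta17 = c(-0.5, -0.5), beta27 = c(1, 1),
                  s11 = c(2, 2), intercept1 = c(9, 9))
  # xbar = intercept only -> exp(9 + 2/2) = exp(10)
  expect_equal(expected_comparator_cost(d), rep(exp(10), 2))
})

test_that("CEAC limit identities hold exactly and curve enumerates", {
  # five crafted draws, baseline cost 100 each
  b17 <- c(log(0.5), log(2), log(0.8), log(1.5), log(0.4))
  b27 <- c(10, 5, -2, 1, 8)
  d <- make_draws(b17, b27, s11 = rep(0, 5))
  base <- rep(100, 5)
  inc_cost <- base * (exp(b17) - 1)         # -50, 100, -20, 50, -60

  p <- dominance_probabilities(d)
  curve <- ceac(d, lambda_grid = c(0, 100, 1e6), baseline_cost = base)
  # enumeration oracle at each lambda
  expect_equal(curve$probability,
               vapply(c(0, 100, 1e6),
                      function(l) mean(l * b27 - inc_cost > 0), 0))
  expect_equal(curve$probability[1], p$p_cheaper)          # CEAC(0)
  expect_equal(curve$probability[3], p$p_more_effective)   # CEAC(infinity)
  expect_error(ceac(d, lambda_grid = c(-1, 0)), ">= 0")

  # monotone non-decreasing in lambda when all effectiveness draws positive
  set.seed(24)
  dm <- make_draws(rnorm(300, -0.5, 0.5), abs(rnorm(300, 20, 5)) + 0.1)
  cc <- ceac(dm, lambda_grid = seq(0, 500, by = 25))
  expect_true(all(diff(cc$probability) >= 0))
})

test_that("CE plane maps draws to (effectiveness, ratio) points", {
  d <- make_draws(0, 0)
  pl <- ce_plane(d)
  expect_equal(unlist(pl[1, ]), c(incremental_effectiveness = 0,
                                  costs_ratio = 1))
  expect_equal(attr(pl, "neutral_cost_line"), 1)

  set.seed(25)
  dn <- make_draws(rnorm(1000), rnorm(1000))
  pln <- ce_plane(dn)
  expect_equal(nrow(pln), 1000)                          # cardinality
  dom_quadrant <- pln$costs_ratio < 1 & pln$incremental_effectiveness > 0
  expect_equal(mean(dom_quadrant),
               dominance_probabilities(dn)$p_dominant)   # cross-check
})

test_that("cea_summary bundles consistent components", {
  set.seed(26)
  d <- make_draws(rnorm(500, -0.6, 0.2), rnorm(500, 28, 4))
  s <- cea_summary(d)
  expect_s3_class(s, "cea_summary")
  expect_equal(s$dominance, dominance_probabilities(d))
  expect_equal(s$ceac$probability[1], s$dominance$p_cheaper)
  expect_output(print(s), "dominant")
})
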