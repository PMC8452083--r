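test_that("unit-cost table derives the syringe-filling cost from the wage", {
  tab <- default_unit_costs()
  expect_equal(tab$unit_costs[["syringe_fill"]], 41 / 200)  # 0.205 EUR
  expect_equal(tab$unit_costs[["syringe_10mL"]], 0.17)

  uc <- c(sevoflurane_mL = 0.30, syringe_10mL = 0.17, opioid = 1,
          nonopioid = 1, pc_sched_medical_first = 44,
          pc_sched_medical_next = 18, pc_sched_mednurse_first = 52,
          pc_sched_mednurse_next = 23, pc_sched_nurse = 21,
          pc_nonsched_simple = 49, pc_nonsched_observation = 86,
          pc_nonsched_referral = 111, hosp_sched_first = 114,
          hosp_sched_next = 55, hosp_nonsched_discharge = 144,
          hosp_nonsched_admitted = 392, hyperbaric_session = 65)
  zero_wage <- build_unit_cost_table(uc, 8000, 5000,
                                     pharmacist_hourly_wage = 0)
  expect_equal(zero_wage$unit_costs[["syringe_fill"]], 0)
  expect_error(build_unit_cost_table(uc[-1], 8000, 5000),
               "missing tariff.*sevoflurane_mL")
  expect_error(build_unit_cost_table(uc, 8000, 5000, syringes_per_hour = 0),
               "syringes_per_hour")
})

test_that("CPI adjustment rescales by the reference-year index ratio", {
  cpi <- cpi_index(c("2013" = 100, "2016" = 103), reference_year = 2016)
  expect_equal(adjust_to_reference_year(100, 2016, cpi), 100)
  expect_equal(adjust_to_reference_year(100, 2013, cpi), 103)
  expect_equal(adjust_to_reference_year(0, 2013, cpi), 0)
  expect_error(adjust_to_reference_year(100, 2011, cpi), "2011")
  expect_error(cpi_index(c("2013" = 100), reference_year = 2016),
               "reference year")
})

test_that("admission costing honours flags, overrides and per-diem", {
  tab <- build_unit_cost_table(
    default_unit_costs()$unit_costs[setdiff(names(default_unit_costs()$unit_costs), "syringe_fill")],
    drg_cost_with_complications = 5000,
    drg_cost_without_complications = 3000, per_diem_rate = 400)
  adm <- data.frame(patient_id = "A", category = "hospital_admission",
                    quantity = 1, attribution = "any", complication = 1,
                    length_of_stay = 10, year = 2016)
  expect_equal(cost_admission(adm, tab, "base_case"), 5000)
  expect_equal(cost_admission(adm, tab, "drg_no_complications"), 3000)
  expect_equal(cost_admission(adm, tab, "drg_all_complications"), 5000)
  expect_equal(cost_admission(adm, tab, "per_diem"), 4000)
  expect_equal(cost_admission(adm, tab, "admissions_ulcer_only"), 0)
  expect_equal(cost_admission(adm, tab, "admissions_pain_only"), 0)
  adm$attribution <- "pain"
  expect_equal(cost_admission(adm, tab, "admissions_ulcer_only"), 5000)
  adm$length_of_stay <- NA
  expect_error(cost_admission(adm, tab, "per_diem"), "length_of_stay")
})

test_that("annual patient cost matches the hand summation", {
  tab <- default_unit_costs(); cpi <- default_cpi()
  res <- resource_use_records(data.frame(
    patient_id = "A",
    category = c("sevoflurane_mL", "syringe_10mL", "syringe_fill"),
    quantity = c(300, 30, 30)))
  b <- annual_patient_cost(res, tab, cpi)
  # 300*0.30 + 30*0.17 + 30*0.205 = 90 + 5.10 + 6.15
  expect_equal(b$total, 101.25)
  expect_equal(b$total_analgesics, 101.25)
  expect_equal(b$total_excluding_analgesics, 0)

  empty <- annual_patient_cost(res[0, ], tab, cpi)
  expect_equal(empty$total, 0)
  expect_true(all(empty$components == 0))

  one <- resource_use_records(data.frame(
    patient_id = "A", category = "pc_sched_medical_first", quantity = 1))
  expect_equal(annual_patient_cost(one, tab, cpi)$total, 44)
})

test_that("bottle costing rounds sevoflurane up to whole 250 mL bottles", {
  tab <- default_unit_costs(bottle_costing = TRUE)
  res <- resource_use_records(data.frame(
    patient_id = "A", category = "sevoflurane_mL", quantity = 300))
  # ceiling(300/250) = 2 bottles of 250 mL at 0.30 EUR/mL
  expect_equal(annual_patient_cost(res, tab, default_cpi())$total,
               2 * 250 * 0.30)
})

test_that("cost invariants: currency scaling, variant order, attribution", {
  cpi <- default_cpi()
  base <- default_unit_costs()
  k <- 3.5
  scaled <- build_unit_cost_table(
    base$unit_costs[setdiff(names(base$unit_costs), "syringe_fill")] * k,
    base$drg_cost_with_complications * k,
    base$drg_cost_without_complications * k,
    per_diem_rate = base$per_diem_rate * k,
    pharmacist_hourly_wage = base$pharmacist_hourly_wage * k)

  set.seed(11)
  for (rep in 1:10) {
    cats <- sample(resource_categories(), 6)
    res <- resource_use_records(data.frame(
      patient_id = "A", category = cats,
      quantity = round(runif(6, 0, 20), 1),
      attribution = sample(c("any", "ulcer", "pain"), 6, replace = TRUE),
      complication = ifelse(cats == "hospital_admission",
                            rbinom(6, 1, 0.5), NA),
      length_of_stay = ifelse(cats == "hospital_admission",
                              sample(1:20, 6, replace = TRUE), NA),
      year = sample(2013:2016, 6, replace = TRUE)))
    expect_equal(annual_patient_cost(res, scaled, cpi)$total,
                 k * annual_patient_cost(res, base, cpi)$total)

    tot <- function(v) annual_patient_cost(res, base, cpi, v)$total
    expect_lte(tot("drg_no_complications"), tot("base_case") + 1e-9)
    expect_lte(tot("base_case"), tot("drg_all_complications") + 1e-9)
    expect_lte(tot("admissions_pain_only"),
               tot("admissions_ulcer_only") + 1e-9)
    expect_lte(tot("admissions_ulcer_only"), tot("base_case") + 1e-9)
  }

  expect_error(annual_patient_cost(
    data.frame(patient_id = "A", category = "sevoflurane_mL",
               quantity = -1, attribution = "any",
               complication = NA, length_of_stay = NA, year = 2016),
    base, cpi), "negative")
})
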