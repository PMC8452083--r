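COST_VARIANTS <- c("base_case", "drg_all_complications",
                   "drg_no_complications", "admissions_ulcer_only",
                   "admissions_pain_only", "per_diem")

#' Build the unit-cost table
#'
#' Assembles per-category unit costs in reference-year euros.  The
#' syringe-filling labor cost is derived from the pharmacist's hourly wage and
#' throughput (`hourly_wage / syringes_per_hour`); sevoflurane can be costed
#' per mL (default) or per whole 250 mL bottle.
#'
#' @param unit_costs named numeric vector of per-unit costs for the consult /
#'   analgesic / hyperbaric categories (see [resource_categories()]).
#'   `sevoflurane_mL` is the per-mL drug cost; `syringe_fill` is derived and
#'   must not be supplied.
#' @param drg_cost_with_complications,drg_cost_without_complications DRG
#'   tariff per admission, by complication status.
#' @param per_diem_rate euros per hospitalization day (per-diem variant).
#' @param pharmacist_hourly_wage euros per working hour (default 41, 2016).
#' @param syringes_per_hour syringes a pharmacist fills per hour
#'   (default 200).
#' @param sevoflurane_bottle_mL,bottle_costing bottle size and whether
#'   sevoflurane is costed per whole bottle (ceiling of bottles) instead of
#'   per mL.
#' @return object of class `unit_cost_table`.
#' @export
build_unit_cost_table <- function(unit_costs,
                                  drg_cost_with_complications,
                                  drg_cost_without_complications,
                                  per_diem_rate = NA_real_,
                                  pharmacist_hourly_wage = 41,
                                  syringes_per_hour = 200,
                                  sevoflurane_bottle_mL = 250,
                                  bottle_costing = FALSE) {
  if (syringes_per_hour <= 0) stop("syringes_per_hour must be > 0")
  if (pharmacist_hourly_wage < 0) stop("costs must be >= 0")
  uc <- as.list(unit_costs)
  uc$syringe_fill <- pharmacist_hourly_wage / syringes_per_hour
  if (any(unlist(uc) < 0)) stop("unit costs must be >= 0")
  if (drg_cost_with_complications < 0 || drg_cost_without_complications < 0)
    stop("DRG tariffs must be >= 0")
  needed <- setdiff(RESOURCE_CATEGORIES, "hospital_admission")
  missing <- setdiff(needed, names(uc))
  if (length(missing))
    stop("missing tariff for category: ", paste(missing, collapse = ", "))
  structure(list(
    unit_costs = unlist(uc)[needed],
    drg_cost_with_complications = drg_cost_with_complications,
    drg_cost_without_complications = drg_cost_without_complications,
    per_diem_rate = per_diem_rate,
    pharmacist_hourly_wage = pharmacist_hourly_wage,
    syringes_per_hour = syringes_per_hour,
    sevoflurane_bottle_mL = sevoflurane_bottle_mL,
    bottle_costing = bottle_costing
  ), class = "unit_cost_table")
}

#' Default (synthetic) unit-cost table
#'
#' Unit costs for analgesics and consults follow the published 2016 tariffs
#' used by the analysis (sevoflurane 0.30 EUR/mL, 10 mL syringe 0.17 EUR,
#' filling 41/200 EUR, primary-care and hospital consult prices).  DRG and
#' per-diem figures are SYNTHETIC stand-ins of realistic Spanish-2016
#' magnitude, since the official tariff catalogues are user-supplied inputs.
#'
#' @inheritParams build_unit_cost_table
#' @export
default_unit_costs <- function(bottle_costing = FALSE) {
  build_unit_cost_table(
    unit_costs = c(
      sevoflurane_mL = 0.30, syringe_10mL = 0.17,
      opioid = 1, nonopioid = 1,     # quantities recorded directly in euros
      pc_sched_medical_first = 44, pc_sched_medical_next = 18,
      pc_sched_mednurse_first = 52, pc_sched_mednurse_next = 23,
      pc_sched_nurse = 21,
      pc_nonsched_simple = 49, pc_nonsched_observation = 86,
      pc_nonsched_referral = 111,
      hosp_sched_first = 114, hosp_sched_next = 55,
      hosp_nonsched_discharge = 144, hosp_nonsched_admitted = 392,
      hyperbaric_session = 65),
    drg_cost_with_complications = 8000,
    drg_cost_without_complications = 5000,
    per_diem_rate = 550,
    bottle_costing = bottle_costing)
}

#' Default (synthetic) Spanish CPI table, reference year 2016
#' @export
default_cpi <- function() {
  cpi_index(c("2013" = 100.9, "2014" = 100.7, "2015" = 100.2,
              "2016" = 100.0), reference_year = 2016)
}

#' Adjust a nominal amount to reference-year euros with the CPI
#'
#' @param amount nominal euros of `year`.
#' @param year calendar year of expenditure.
#' @param cpi [cpi_index()] table.
#' @return amount in reference-year euros:
#'   `amount * index(reference) / index(year)`.
#' @export
adjust_to_reference_year <- function(amount, year, cpi) {
  idx <- cpi$index[as.character(year)]
  if (anyNA(idx))
    stop("year(s) missing from CPI table: ",
         paste(unique(year[is.na(idx)]), collapse = ", "))
  ref <- unname(cpi$index[as.character(cpi$reference_year)])
  amount * ref / unname(idx)
}

#' Cost of one hospital admission record under a costing variant
#'
#' Base case uses the complication-flag-specific DRG tariff; the
#' `drg_all_complications` / `drg_no_complications` variants override the
#' flag; the attribution variants return 0 for admissions outside the filter
#' ("pain" implies "ulcer" implies "any", nested); `per_diem` multiplies the
#' per-day rate by the length of stay.  `quantity` scales the result (a
#' record may bundle several identical admissions).
#'
#' @param admission one `hospital_admission` resource row.
#' @param table [build_unit_cost_table()] output.
#' @param variant one of `r paste(COST_VARIANTS, collapse = ", ")`.
#' @return euros (nominal, in the record's expenditure year).
#' @export
cost_admission <- function(admission, table, variant = "base_case") {
  variant <- match.arg(variant, COST_VARIANTS)
  if (admission$category != "hospital_admission")
    stop("cost_admission() expects a hospital_admission record")
  q <- admission$quantity
  if (variant == "admissions_ulcer_only" &&
      !admission$attribution %in% c("ulcer", "pain")) return(0)
  if (variant == "admissions_pain_only" &&
      admission$attribution != "pain") return(0)
  if (variant == "per_diem") {
    if (is.na(admission$length_of_stay))
      stop("per_diem costing requires length_of_stay")
    if (is.na(table$per_diem_rate))
      stop("missing tariff for category: per_diem_rate")
    return(admission$length_of_stay * table$per_diem_rate)
  }
  with_c <- switch(variant,
                   drg_all_complications = TRUE,
                   drg_no_complications = FALSE,
                   isTRUE(admission$complication == 1))
  tariff <- if (with_c) table$drg_cost_with_complications else
    table$drg_cost_without_complications
  q * tariff
}

#' Annual per-patient cost breakdown
#'
#' Multiplies each consumed resource by its unit cost (admissions via
#' [cost_admission()]), adjusts every nominal amount to reference-year euros
#' with the CPI, and totals by Table-3 blocks.  Sevoflurane is costed per mL,
#' or per whole 250 mL bottle when the unit-cost table says so.
#'
#' @param resources resource rows for ONE patient.
#' @param unit_table [build_unit_cost_table()] output.
#' @param cpi [cpi_index()] table.
#' @param variant hospitalization costing variant (see [cost_admission()]).
#' @return list of class `cost_breakdown`: `components` (named euros),
#'   `total_analgesics`, `total_excluding_analgesics`, `total`.
#' @export
annual_patient_cost <- function(resources, unit_table, cpi,
                                variant = "base_case") {
  variant <- match.arg(variant, COST_VARIANTS)
  comp <- setNames(numeric(length(RESOURCE_CATEGORIES)), RESOURCE_CATEGORIES)
  if (nrow(resources) > 0) {
    if (any(resources$quantity < 0)) stop("negative resource quantity")
    unknown <- setdiff(unique(resources$category), RESOURCE_CATEGORIES)
    if (length(unknown))
      stop("unknown category: ", paste(unknown, collapse = ", "))
    for (i in seq_len(nrow(resources))) {
      r <- resources[i, ]
      nominal <- if (r$category == "hospital_admission") {
        cost_admission(r, unit_table, variant)
      } else if (r$category == "sevoflurane_mL" && unit_table$bottle_costing) {
        ceiling(r$quantity / unit_table$sevoflurane_bottle_mL) *
          unit_table$sevoflurane_bottle_mL *
          unit_table$unit_costs[["sevoflurane_mL"]]
      } else {
        r$quantity * unit_table$unit_costs[[r$category]]
      }
      comp[[r$category]] <- comp[[r$category]] +
        adjust_to_reference_year(nominal, r$year, cpi)
    }
  }
  analgesics <- sum(comp[ANALGESIC_CATEGORIES])
  other <- sum(comp) - analgesics
  structure(list(components = comp,
                 total_analgesics = analgesics,
                 total_excluding_analgesics = other,
                 total = analgesics + other),
            class = "cost_breakdown")
}

#' Annual cost for every patient in a cohort
#'
#' @param patients,resources validated record tables.
#' @inheritParams annual_patient_cost
#' @return data.frame: `patient_id`, `group`, `total_analgesics`,
#'   `total_excluding_analgesics`, `annual_cost` (reference-year euros).
#' @export
compute_costs <- function(patients, resources, unit_table, cpi,
                          variant = "base_case") {
  rows <- lapply(seq_len(nrow(patients)), function(i) {
    id <- patients$patient_id[i]
    b <- annual_patient_cost(
      resources[resources$patient_id == id, , drop = FALSE],
      unit_table, cpi, variant)
    data.frame(patient_id = id, group = patients$group[i],
               total_analgesics = b$total_analgesics,
               total_excluding_analgesics = b$total_excluding_analgesics,
               annual_cost = b$total)
  })
  do.call(rbind, rows)
}
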