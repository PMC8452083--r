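#' @useDynLib sevocea, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rbinom rlnorm runif quantile sd setNames
#'   pnorm qnorm wilcox.test chisq.test fisher.test rchisq
#' @importFrom utils read.csv write.csv
NULL

# Canonical resource-use categories (Table-3-shaped).  Admission-only fields
# (attribution detail, complication flag, length of stay) are meaningful only
# for "hospital_admission".
RESOURCE_CATEGORIES <- c(
  "sevoflurane_mL", "syringe_10mL", "syringe_fill",
  "opioid", "nonopioid",
  "pc_sched_medical_first", "pc_sched_medical_next",
  "pc_sched_mednurse_first", "pc_sched_mednurse_next",
  "pc_sched_nurse",
  "pc_nonsched_simple", "pc_nonsched_observation", "pc_nonsched_referral",
  "hosp_sched_first", "hosp_sched_next",
  "hosp_nonsched_discharge", "hosp_nonsched_admitted",
  "hospital_admission", "hyperbaric_session"
)

ANALGESIC_CATEGORIES <- c("sevoflurane_mL", "syringe_10mL", "syringe_fill",
                          "opioid", "nonopioid")

ATTRIBUTION_LEVELS <- c("any", "ulcer", "pain")

#' Construct a validated patient-level table
#'
#' One row per patient: treatment arm, the six baseline covariates used by the
#' regression model, and optional death / amputation months within the one-year
#' horizon.  `ulcer_number` is stored raw; truncation at 4 happens only when
#' the design matrix is built.
#'
#' @param df data.frame with columns `patient_id`, `group` (1 = sevoflurane
#'   add-on, 0 = conventional), `aht` (0/1), `ulcer_duration` (months, >= 0),
#'   `ulcer_number` (integer >= 1), `ulcer_depth` (0 superficial / 1 beyond
#'   dermis), `baseline_pain` (NRS 0-10), and optional `death_month`,
#'   `amputation_month` (months in (0, 12], NA when absent).
#' @return the data.frame with class `patient_records`.
#' @export
patient_records <- function(df) {
  req <- c("patient_id", "group", "aht", "ulcer_duration", "ulcer_number",
           "ulcer_depth", "baseline_pain")
  .require_columns(df, req, "patient table")
  if (!"death_month" %in% names(df)) df$death_month <- NA_real_
  if (!"amputation_month" %in% names(df)) df$amputation_month <- NA_real_
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id values: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", "))
  .check_binary(df$group, "group")
  .check_binary(df$aht, "aht")
  .check_binary(df$ulcer_depth, "ulcer_depth")
  if (any(df$ulcer_duration < 0))
    stop("ulcer_duration must be non-negative")
  if (any(df$ulcer_number < 1 | df$ulcer_number != round(df$ulcer_number)))
    stop("ulcer_number must be an integer count >= 1")
  .check_nrs(df$baseline_pain, "baseline_pain")
  for (col in c("death_month", "amputation_month")) {
    v <- df[[col]]
    bad <- !is.na(v) & (v <= 0 | v > 12)
    if (any(bad))
      stop(col, " must lie in (0, 12] when present; offending patients: ",
           paste(df$patient_id[bad], collapse = ", "))
  }
  structure(as.data.frame(df), class = c("patient_records", "data.frame"))
}

#' Construct a validated visit-level pain table
#'
#' @param df data.frame with columns `patient_id`, `time` (months since first
#'   Pain Clinic visit, 0 <= time <= 12) and `pain` (NRS integer 0-10).
#' @return the data.frame with class `visit_records`, ordered by patient and
#'   time.
#' @export
visit_records <- function(df) {
  .require_columns(df, c("patient_id", "time", "pain"), "visit table")
  df$patient_id <- as.character(df$patient_id)
  if (any(df$time < 0 | df$time > 12))
    stop("visit times must lie in [0, 12] months")
  .check_nrs(df$pain, "pain")
  df <- df[order(df$patient_id, df$time), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("visit_records", "data.frame"))
}

#' Construct a validated resource-use table
#'
#' @param df data.frame with columns `patient_id`, `category` (one of the
#'   Table-3 categories, see [resource_categories()]), `quantity` (>= 0 in the
#'   category's natural unit), and optional `attribution`
#'   ("any"/"ulcer"/"pain"), `complication` (0/1), `length_of_stay` (days) and
#'   `year` (calendar year of expenditure, default 2016).  The last three are
#'   admission-only fields.
#' @export
resource_use_records <- function(df) {
  .require_columns(df, c("patient_id", "category", "quantity"),
                   "resource table")
  df$patient_id <- as.character(df$patient_id)
  bad <- !df$category %in% RESOURCE_CATEGORIES
  if (any(bad))
    stop("unknown resource category: ",
         paste(unique(df$category[bad]), collapse = ", "))
  if (any(df$quantity < 0)) stop("resource quantities must be >= 0")
  if (!"attribution" %in% names(df)) df$attribution <- "any"
  df$attribution[is.na(df$attribution)] <- "any"
  if (!all(df$attribution %in% ATTRIBUTION_LEVELS))
    stop("attribution must be one of: ",
         paste(ATTRIBUTION_LEVELS, collapse = ", "))
  if (!"complication" %in% names(df)) df$complication <- NA_real_
  if (!"length_of_stay" %in% names(df)) df$length_of_stay <- NA_real_
  if (!"year" %in% names(df)) df$year <- 2016
  non_adm <- df$category != "hospital_admission"
  if (any(non_adm & (!is.na(df$complication) | !is.na(df$length_of_stay))))
    stop("complication and length_of_stay are only valid for ",
         "category 'hospital_admission'")
  rownames(df) <- NULL
  structure(as.data.frame(df), class = c("resource_use_records", "data.frame"))
}

#' Table-3 resource categories understood by the costing module
#' @return character vector of category codes.
#' @export
resource_categories <- function() RESOURCE_CATEGORIES

#' Consumer Price Index table
#'
#' @param index named numeric vector mapping calendar year to index value.
#' @param reference_year year whose euros all costs are expressed in
#'   (default 2016).
#' @export
cpi_index <- function(index, reference_year = 2016) {
  years <- as.integer(names(index))
  if (anyNA(years)) stop("index must be named by calendar year")
  if (any(index <= 0)) stop("CPI index values must be > 0")
  if (!reference_year %in% years)
    stop("reference year ", reference_year, " missing from CPI table")
  structure(list(index = setNames(as.numeric(index), years),
                 reference_year = as.integer(reference_year)),
            class = "cpi_index")
}

#' Load the three canonical study tables from delimited text
#'
#' Reads patient, visit and resource tables (comma- or tab-delimited, header
#' row required), applies an optional `column_map` renaming file headers to
#' canonical field names, validates each level, and cross-references ids.
#'
#' @param patient_path,visit_path,resource_path file paths.
#' @param column_map optional named character vector `c(file_header =
#'   "canonical_name")` applied to all three tables.
#' @param sep field separator; `""` (default) auto-detects comma vs tab from
#'   the header line.
#' @return list with elements `patients`, `visits`, `resources`.
#' @export
load_study_tables <- function(patient_path, visit_path, resource_path,
                              column_map = NULL, sep = "") {
  rd <- function(path) {
    s <- sep
    if (identical(s, "")) {
      hdr <- readLines(path, n = 1L)
      s <- if (grepl("\t", hdr)) "\t" else ","
    }
    df <- read.csv(path, sep = s, stringsAsFactors = FALSE,
                   check.names = FALSE)
    if (!is.null(column_map)) {
      hit <- names(df) %in% names(column_map)
      names(df)[hit] <- unname(column_map[names(df)[hit]])
    }
    df
  }
  patients  <- patient_records(rd(patient_path))
  visits    <- visit_records(rd(visit_path))
  resources <- resource_use_records(rd(resource_path))
  .check_refs(patients, visits, "visit")
  .check_refs(patients, resources, "resource")
  list(patients = patients, visits = visits, resources = resources)
}

#' Write the canonical tables back to CSV
#' @param cohort list as returned by [load_study_tables()] or
#'   [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_study_tables <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "visits.csv", "resources.csv"))
  write.csv(cohort$patients,  paths[1], row.names = FALSE)
  write.csv(cohort$visits,    paths[2], row.names = FALSE)
  write.csv(cohort$resources, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Validate a loaded cohort
#'
#' Report-producing (never throws): lists, per patient, a missing time-0
#' visit, non-monotone visit times, and negative resource quantities.  The
#' report is empty iff all invariants hold.
#'
#' @param patients,visits,resources validated record tables.
#' @return data.frame of findings (`patient_id`, `check`, `detail`) with class
#'   `validation_report`.
#' @export
validate_cohort <- function(patients, visits, resources) {
  findings <- list()
  add <- function(id, check, detail)
    findings[[length(findings) + 1L]] <<-
      data.frame(patient_id = id, check = check, detail = detail)
  for (id in patients$patient_id) {
    v <- visits[visits$patient_id == id, , drop = FALSE]
    if (nrow(v) == 0L || min(v$time) != 0)
      add(id, "missing_baseline", "no visit at time 0")
    if (nrow(v) > 1L && any(diff(v$time) <= 0))
      add(id, "non_monotone_times",
          paste("times:", paste(v$time, collapse = ", ")))
  }
  neg <- resources$quantity < 0
  if (any(neg))
    for (id in unique(resources$patient_id[neg]))
      add(id, "negative_quantity", "resource quantity < 0")
  rep <- if (length(findings)) do.call(rbind, findings) else
    data.frame(patient_id = character(), check = character(),
               detail = character())
  structure(rep, class = c("validation_report", "data.frame"))
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) cat("cohort valid: no findings\n")
  else {
    cat(nrow(x), "finding(s):\n")
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("schema error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "))
  invisible(df)
}

.check_binary <- function(v, name) {
  if (!all(v %in% c(0, 1)))
    stop(name, " must be 0/1")
}

.check_nrs <- function(v, name) {
  if (any(is.na(v)) || any(v < 0 | v > 10 | v != round(v)))
    stop("validation error: ", name, " must be an integer NRS score in 0-10")
}

.check_refs <- function(patients, child, what) {
  orphan <- setdiff(unique(child$patient_id), patients$patient_id)
  if (length(orphan))
    stop("referential error: ", what, " table has patient_id(s) absent from ",
         "patient table: ", paste(orphan, collapse = ", "))
  invisible(NULL)
}
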