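# Shared fixtures: crafted posterior-draw objects and a tiny three-level toy
# cohort, all built in code.

COVS <- c("intercept", "aht", "ulcer_duration", "ulcer_number",
          "ulcer_depth", "ulcer_pain", "treatment")

# posterior_draws with prescribed treatment-coefficient draws; all other
# coefficients zero unless supplied.
make_draws <- function(beta17, beta27, s11 = rep(1, length(beta17)),
                       intercept1 = rep(0, length(beta17))) {
  n <- length(beta17)
  b1 <- matrix(0, n, 7, dimnames = list(NULL, COVS))
  b2 <- matrix(0, n, 7, dimnames = list(NULL, COVS))
  b1[, "treatment"] <- beta17
  b1[, "intercept"] <- intercept1
  b2[, "treatment"] <- beta27
  sigma <- cbind(s11 = s11, s22 = rep(1, n), s12 = rep(0, n))
  structure(list(beta1 = b1, beta2 = b2, sigma = sigma,
                 xbar_control = c(intercept = 1, aht = 0, ulcer_duration = 0,
                                  ulcer_number = 1, ulcer_depth = 0,
                                  ulcer_pain = 0, treatment = 0)),
            class = "posterior_draws")
}

toy_patients <- function() {
  patient_records(data.frame(
    patient_id = c("A", "B", "C"),
    group = c(1, 0, 1), aht = c(1, 0, 1),
    ulcer_duration = c(10, 24, 3), ulcer_number = c(1, 2, 7),
    ulcer_depth = c(0, 1, 0), baseline_pain = c(8, 6, 7),
    death_month = c(NA, 7, NA), amputation_month = c(NA, NA, NA)))
}

toy_visits <- function() {
  visit_records(data.frame(
    patient_id = c("A", "A", "A", "B", "B", "C", "C"),
    time = c(0, 6, 12, 0, 6, 0, 4),
    pain = c(8, 3, 1, 6, 5, 7, 2)))
}

toy_resources <- function() {
  resource_use_records(data.frame(
    patient_id = c("A", "A", "B", "C"),
    category = c("sevoflurane_mL", "pc_sched_nurse", "hospital_admission",
                 "opioid"),
    quantity = c(300, 4, 1, 120),
    attribution = c("any", "any", "pain", "any"),
    complication = c(NA, NA, 1, NA),
    length_of_stay = c(NA, NA, 9, NA),
    year = c(2016, 2016, 2016, 2016)))
}

# model_data wrapper for arbitrary design/response (used by oracle tests)
manual_model_data <- function(X, Y) {
  xbar <- colMeans(X)
  structure(list(X = X, Y = Y, patient_id = as.character(seq_len(nrow(X))),
                 xbar_control = xbar), class = "model_data")
}
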