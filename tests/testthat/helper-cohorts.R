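# Shared fixture builders: tiny hand-checkable cohorts constructed in code.

toy_vs <- eq5d3l_value_set("toy_linear")
dutch_vs <- eq5d3l_value_set("dutch_tariff_3l")
default_waves <- c(0, 6, 9, 12, 15, 18)

empty_resource_use <- function() {
  tibble::tibble(patient_id = character(), wave_month = numeric(),
                 category = character(), count = numeric())
}
empty_medications <- function() {
  tibble::tibble(patient_id = character(), class = character(),
                 product = character(), dose_per_day = numeric(),
                 days = numeric())
}
empty_productivity <- function() {
  tibble::tibble(patient_id = character(), wave_month = numeric(),
                 absence_start_week = numeric(), absence_weeks = numeric(),
                 presenteeism_hours = numeric())
}

make_patients <- function(arms, employed = TRUE, hours = 40) {
  n <- length(arms)
  tibble::tibble(
    patient_id = sprintf("T%02d", seq_len(n)),
    arm = arms,
    age = 55,
    sex = "f",
    employed = rep_len(employed, n),
    contracted_hours = ifelse(rep_len(employed, n), rep_len(hours, n), NA_real_),
    treatment_weeks = ifelse(arms == "intervention", 26, NA_real_),
    therapist_minutes = ifelse(arms == "intervention", 300, NA_real_),
    therapist_tier = ifelse(arms == "intervention", "basic", NA_character_),
    intake_travel_km = ifelse(arms == "intervention", 28, NA_real_)
  )
}

# Fully observed cohort: everyone at full health, no resource use.
blank_cohort <- function(arms = c("control", "control",
                                  "intervention", "intervention"),
                         waves = default_waves, ...) {
  patients <- make_patients(arms, ...)
  eq5d <- tidyr::crossing(patient_id = patients$patient_id,
                          wave_month = waves) |>
    dplyr::mutate(mobility = 1, self_care = 1, usual_activities = 1,
                  pain_discomfort = 1, anxiety_depression = 1)
  structure(
    list(patients = patients, eq5d = eq5d,
         resource_use = empty_resource_use(),
         medications = empty_medications(),
         productivity = empty_productivity()),
    class = "cua_cohort"
  )
}

# Mark waves as missing (dropout) for one patient.
drop_waves <- function(cohort, patient_id, waves) {
  sel <- cohort$eq5d$patient_id == patient_id &
    cohort$eq5d$wave_month %in% waves
  cohort$eq5d[sel, eq5d_dims()] <- NA_real_
  cohort
}

eq5d_dims <- function() {
  c("mobility", "self_care", "usual_activities", "pain_discomfort",
    "anxiety_depression")
}

# Small generator configuration for fast property tests.
small_config <- function(...) {
  cohort_config(n_control = 12, n_intervention = 12, ...)
}
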