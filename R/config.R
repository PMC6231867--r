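#' Load the pipeline configuration
#'
#' All unit prices, travel distances, friction parameters, the intervention
#' cost model, analysis settings and the synthetic-cohort calibration live
#' in a single YAML configuration. The bundled default describes a two-arm
#' trial of 62 intervention and 71 control patients measured at months
#' 0, 6, 9, 12, 15 and 18, priced in 2015 euros.
#'
#' @param file Path to a configuration YAML; `NULL` loads the bundled
#'   default.
#' @return A named list with classes `cua_config`.
#' @export
cua_config <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "default_config.yaml", package = "trialcua")
  }
  cfg <- yaml::read_yaml(file)
  cfg$prices <- unlist(cfg$prices)
  cfg$medication_prices <- unlist(cfg$medication_prices)
  cfg$travel$distances <- unlist(cfg$travel$distances)
  class(cfg) <- "cua_config"
  cfg
}

#' Synthetic cohort configuration
#'
#' Returns the generator calibration (the `simulate` section of the
#' configuration) with optional field overrides, validated against the
#' generator's invariants.
#'
#' @param ... Named overrides of top-level simulate fields (e.g.
#'   `n_control = 10`, `dropout_hazard = list(control = 0, intervention = 0)`).
#' @param config A [cua_config()]; its `simulate` section supplies defaults.
#' @return A validated list of class `cohort_config`, including the wave
#'   schedule and value-set name from the parent configuration.
#' @export
cohort_config <- function(..., config = cua_config()) {
  sim <- config$simulate
  sim$wave_months <- config$wave_months
  sim$value_set <- config$value_set
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), c(names(sim)))
    if (length(bad)) {
      stop("unknown cohort_config field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    sim[names(dots)] <- dots
  }
  class(sim) <- "cohort_config"
  validate_cohort_config(sim)
  sim
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid cohort configuration: field '", field, "' ", why,
         call. = FALSE)
  }
  if (!is.numeric(cfg$n_control) || cfg$n_control < 2) {
    fail("n_control", "must be a count >= 2")
  }
  if (!is.numeric(cfg$n_intervention) || cfg$n_intervention < 2) {
    fail("n_intervention", "must be a count >= 2")
  }
  w <- cfg$wave_months
  if (w[1] != 0 || is.unsorted(w, strictly = TRUE)) {
    fail("wave_months", "must be strictly increasing and start at 0")
  }
  probs <- c(
    female_fraction = cfg$female_fraction,
    employment_fraction = cfg$employment$fraction,
    dropout_control = cfg$dropout_hazard$control,
    dropout_intervention = cfg$dropout_hazard$intervention,
    weekly_contact_fraction = cfg$weekly_contact_fraction,
    postacademic_fraction = cfg$postacademic_fraction,
    two_intake_fraction = cfg$two_intake_fraction,
    healthcare_zero_fraction = cfg$healthcare_zero_fraction,
    presenteeism_prob = cfg$productivity$presenteeism_prob,
    within_patient_correlation = cfg$utility$within_patient_correlation,
    unlist(cfg$medication$user_fraction),
    unlist(cfg$productivity$absence_prob_quarter)
  )
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    fail(names(probs)[bad][1], "is a probability and must lie in [0, 1]")
  }
  sds <- c(
    sd_baseline = unlist(cfg$utility$sd_baseline),
    sd_followup = cfg$utility$sd_followup,
    healthcare_sdlog = cfg$healthcare_sdlog,
    presenteeism_sdlog = cfg$productivity$presenteeism_sdlog,
    treatment_weeks_sd = cfg$treatment_weeks$sd
  )
  if (any(sds < 0)) {
    fail(names(sds)[sds < 0][1], "must be a nonnegative SD")
  }
  tw <- cfg$treatment_weeks
  if (!(tw$min <= tw$mean && tw$mean <= tw$max)) {
    fail("treatment_weeks", "requires min <= mean <= max")
  }
  if (length(cfg$utility$mean$control) != length(w) ||
      length(cfg$utility$mean$intervention) != length(w)) {
    fail("utility$mean", "must give one mean per wave for each arm")
  }
  euros <- c(unlist(cfg$healthcare_annual_euro), unlist(cfg$medication$annual_euro))
  if (any(euros < 0)) fail("annual_euro", "must be nonnegative")
  invisible(cfg)
}

#' Analysis settings for the cost-utility engine
#'
#' @param bootstrap_replications Number of bootstrap replicates.
#' @param percentiles Lower/upper interval bounds (percent).
#' @param wtp Willingness-to-pay grid in euro per QALY.
#' @param exclude Character vector of cost categories to exclude from
#'   patient totals (e.g. `"medication"` for the secondary analysis).
#' @param seed Integer seed for the bootstrap, or `NULL`.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(bootstrap_replications = 1000,
                            percentiles = c(2.5, 97.5),
                            wtp = seq(0, 100000, by = 1000),
                            exclude = character(),
                            seed = NULL) {
  stopifnot(
    bootstrap_replications >= 1,
    length(percentiles) == 2,
    percentiles[1] >= 0, percentiles[1] < percentiles[2], percentiles[2] <= 100,
    all(wtp >= 0), !is.unsorted(wtp, strictly = TRUE)
  )
  structure(
    list(
      bootstrap_replications = as.integer(bootstrap_replications),
      percentiles = percentiles,
      wtp = wtp,
      exclude = exclude,
      seed = seed
    ),
    class = "analysis_config"
  )
}
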