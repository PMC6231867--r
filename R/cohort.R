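# Synthetic two-arm cohort generator. The generator emulates the
# statistical structure the economic analysis assumes -- EQ-5D-3L profiles
# per wave, heavy-tailed resource use, medication, productivity records,
# monotone dropout -- calibrated so that configured means (utilities,
# category costs, employment, completer fractions) are recovered in
# expectation when the generated data are pushed through the pipeline.

#' Generate a synthetic two-arm trial cohort
#'
#' Patients are measured at the configured waves (default months 0, 6, 9,
#' 12, 15, 18). Utilities are drawn on a latent truncated-normal scale with
#' a patient-level random effect, then snapped to the nearest achievable
#' EQ-5D-3L state under the active value set; the latent means are
#' recalibrated (closed form + root finding) so the *scored* profiles
#' reproduce the configured means exactly in expectation. Resource-use
#' counts are zero-inflated Poisson-lognormal with per-category annual euro
#' means; medication is Bernoulli class use at a calibrated dose;
#' productivity has Bernoulli absence episodes (geometric durations) and
#' lognormal presenteeism hours. Dropout is a per-wave Bernoulli hazard,
#' independent of outcomes, giving monotone missingness.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (deterministic output for a given config+seed).
#' @param costing A [cua_config()] supplying the unit prices used to
#'   translate euro calibrations into counts and doses.
#' @return A list of class `cua_cohort` with tibbles `patients`, `eq5d`,
#'   `resource_use`, `medications`, `productivity`.
#' @examples
#' coh <- generate_cohort(cohort_config(), seed = 1)
#' table(coh$patients$arm)
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL,
                            costing = cua_config()) {
  validate_cohort_config(config)
  if (!is.null(seed)) set.seed(seed)

  vs <- eq5d3l_value_set(config$value_set)
  grid <- utility_grid(vs)
  waves <- config$wave_months
  W <- length(waves)
  n_c <- config$n_control
  n_i <- config$n_intervention
  n <- n_c + n_i
  arm <- rep(c("control", "intervention"), c(n_c, n_i))
  ids <- sprintf("P%03d", seq_len(n))

  # --- patients ----------------------------------------------------------
  age <- round(rtnorm(n, config$age$mean, config$age$sd,
                      config$age$min, config$age$max))
  sex <- ifelse(runif(n) < config$female_fraction, "f", "m")
  employed <- runif(n) < config$employment$fraction
  hours <- sample(config$employment$contracted_hours, n, replace = TRUE)
  hours[!employed] <- NA_real_

  tw <- config$treatment_weeks
  treat_weeks <- rep(NA_real_, n)
  treat_weeks[arm == "intervention"] <-
    round(rtnorm(n_i, tw$mean, tw$sd, tw$min, tw$max))
  contacts_per_week <- ifelse(
    runif(n) < config$weekly_contact_fraction, 1, 0.5)
  therapist_minutes <- treat_weeks * contacts_per_week *
    config$minutes_per_contact
  tier <- ifelse(runif(n) < config$postacademic_fraction,
                 "postacademic", "basic")
  tier[arm == "control"] <- NA_character_
  intakes <- 1 + (runif(n) < config$two_intake_fraction)
  intake_km <- ifelse(arm == "intervention",
                      intakes * config$intake_round_trip_km, NA_real_)

  patients <- tibble::tibble(
    patient_id = ids, arm = arm, age = age, sex = sex,
    employed = employed, contracted_hours = hours,
    treatment_weeks = treat_weeks,
    therapist_minutes = therapist_minutes,
    therapist_tier = tier,
    intake_travel_km = intake_km
  )

  # --- monotone dropout --------------------------------------------------
  hazard <- ifelse(arm == "control",
                   config$dropout_hazard$control,
                   config$dropout_hazard$intervention)
  observed <- matrix(TRUE, n, W)
  for (w in 2:W) {
    observed[, w] <- observed[, w - 1] & (runif(n) >= hazard)
  }

  # --- EQ-5D-3L profiles -------------------------------------------------
  sd_wave <- function(a, w) {
    if (w == 1) config$utility$sd_baseline[[a]] else config$utility$sd_followup
  }
  latent_mu <- matrix(NA_real_, 2, W, dimnames = list(arm_levels, NULL))
  for (a in arm_levels) {
    for (w in seq_len(W)) {
      latent_mu[a, w] <- solve_latent_mean(
        config$utility$mean[[a]][w], sd_wave(a, w),
        grid$utilities, vs$minimum, 1
      )
    }
  }
  rho <- config$utility$within_patient_correlation
  z_pat <- rnorm(n)
  eq5d_rows <- vector("list", W)
  for (w in seq_len(W)) {
    z <- sqrt(rho) * z_pat + sqrt(1 - rho) * rnorm(n)
    u <- pnorm(z)
    lev <- matrix(NA_real_, n, 5, dimnames = list(NULL, eq5d_dimensions))
    for (a in arm_levels) {
      sel <- arm == a & observed[, w]
      if (!any(sel)) next
      latent <- qtnorm(u[sel], latent_mu[a, w], sd_wave(a, w), vs$minimum, 1)
      snapped <- snap_to_grid(latent, grid$utilities)
      lev[sel, ] <- grid$profiles[match(snapped, grid$utilities), , drop = FALSE]
    }
    eq5d_rows[[w]] <- tibble::tibble(
      patient_id = ids, wave_month = waves[w],
      mobility = lev[, 1], self_care = lev[, 2],
      usual_activities = lev[, 3], pain_discomfort = lev[, 4],
      anxiety_depression = lev[, 5]
    )
  }
  eq5d <- dplyr::arrange(dplyr::bind_rows(eq5d_rows),
                         .data$patient_id, .data$wave_month)

  # --- resource use ------------------------------------------------------
  categories <- names(costing$prices)
  p0 <- config$healthcare_zero_fraction
  sdlog <- config$healthcare_sdlog
  ru_list <- list()
  for (cat in categories) {
    price <- costing$prices[[cat]]
    annual_euro <- vapply(arm_levels, function(a) {
      config$healthcare_annual_euro[[a]][[cat]] %||% 0
    }, numeric(1))
    lambda_annual <- annual_euro[match(arm, arm_levels)] / price
    user <- runif(n) >= p0
    lam_user <- lambda_annual / (1 - p0)
    lam_i <- rlnorm(n, log(lam_user) - sdlog^2 / 2, sdlog) * user
    counts <- matrix(rpois(n * W, rep(lam_i / 4, W)), n, W) * observed
    nz <- which(counts > 0, arr.ind = TRUE)
    if (nrow(nz)) {
      ru_list[[cat]] <- tibble::tibble(
        patient_id = ids[nz[, 1]],
        wave_month = waves[nz[, 2]],
        category = cat,
        count = counts[nz]
      )
    }
  }
  resource_use <- dplyr::arrange(dplyr::bind_rows(ru_list),
                                 .data$patient_id, .data$wave_month,
                                 .data$category)

  # --- medication --------------------------------------------------------
  med_classes <- names(costing$medication_prices)
  med_list <- list()
  for (cl in med_classes) {
    price <- costing$medication_prices[[cl]]
    frac <- vapply(arm_levels, function(a) {
      config$medication$user_fraction[[a]][[cl]] %||% 0
    }, numeric(1))
    euro <- vapply(arm_levels, function(a) {
      config$medication$annual_euro[[a]][[cl]] %||% 0
    }, numeric(1))
    dose <- ifelse(frac > 0, euro / (frac * 365 * price), 0)
    ai <- match(arm, arm_levels)
    user <- runif(n) < frac[ai]
    if (any(user)) {
      med_list[[cl]] <- tibble::tibble(
        patient_id = ids[user], class = cl, product = cl,
        dose_per_day = dose[ai][user], days = 365
      )
    }
  }
  medications <- dplyr::arrange(dplyr::bind_rows(med_list),
                                .data$patient_id, .data$class)

  # --- productivity ------------------------------------------------------
  prod_cfg <- config$productivity
  kmax <- prod_cfg$absence_duration_max_weeks
  dur_probs <- lapply(arm_levels, function(a) {
    truncated_geometric(prod_cfg$absence_duration_mean_weeks[[a]], kmax)
  })
  names(dur_probs) <- arm_levels
  wave_end_week <- waves * 52 / 12
  prod_list <- list()
  for (w in seq_len(W)) {
    sel <- which(employed & observed[, w])
    if (!length(sel)) next
    m <- length(sel)
    a_sel <- arm[sel]
    p_abs <- vapply(a_sel, function(a) prod_cfg$absence_prob_quarter[[a]],
                    numeric(1))
    has_abs <- runif(m) < p_abs
    dur <- rep(NA_real_, m)
    for (a in arm_levels) {
      k <- which(has_abs & a_sel == a)
      if (length(k)) {
        dur[k] <- sample.int(kmax, length(k), replace = TRUE,
                             prob = dur_probs[[a]])
      }
    }
    start <- ifelse(has_abs,
                    wave_end_week[w] - 13 + runif(m, 0, 13), NA_real_)
    mh <- vapply(a_sel, function(a) prod_cfg$presenteeism_hours_mean[[a]],
                 numeric(1))
    sl <- prod_cfg$presenteeism_sdlog
    pres <- (runif(m) < prod_cfg$presenteeism_prob) *
      rlnorm(m, log(mh) - sl^2 / 2, sl)
    prod_list[[w]] <- tibble::tibble(
      patient_id = ids[sel], wave_month = waves[w],
      absence_start_week = start, absence_weeks = dur,
      presenteeism_hours = pres
    )
  }
  productivity <- dplyr::arrange(dplyr::bind_rows(prod_list),
                                 .data$patient_id, .data$wave_month)

  structure(
    list(patients = patients, eq5d = eq5d, resource_use = resource_use,
         medications = medications, productivity = productivity),
    class = "cua_cohort"
  )
}

#' @export
print.cua_cohort <- function(x, ...) {
  cat("Two-arm trial cohort:", nrow(x$patients), "patients (",
      sum(x$patients$arm == "intervention"), "intervention /",
      sum(x$patients$arm == "control"), "control ),",
      length(unique(x$eq5d$wave_month)), "waves\n")
  invisible(x)
}

#' Completer counts and fractions per arm
#'
#' A completer provided a (non-missing) EQ-5D-3L profile at every declared
#' measurement wave.
#'
#' @param cohort A `cua_cohort`.
#' @return Tibble with `arm`, `n`, `completers`, `fraction`.
#' @export
completer_summary <- function(cohort) {
  if (is.null(cohort$patients) || nrow(cohort$patients) == 0) {
    stop("empty cohort", call. = FALSE)
  }
  waves <- sort(unique(cohort$eq5d$wave_month))
  per_patient <- cohort$eq5d |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      complete = sum(!is.na(.data$mobility)) == length(waves),
      .groups = "drop"
    )
  cohort$patients |>
    dplyr::left_join(per_patient, by = "patient_id") |>
    dplyr::mutate(complete = dplyr::coalesce(.data$complete, FALSE)) |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      n = dplyr::n(),
      completers = sum(.data$complete),
      fraction = mean(.data$complete),
      .groups = "drop"
    )
}

#' Analytic expectations implied by a generator configuration
#'
#' Returns the means the generator is calibrated to reproduce: baseline
#' and per-wave utilities, employment fraction, completer fractions, and
#' annual euro means per cost category per arm (computed from the
#' configuration and the unit-price table, not from simulation). Used by
#' the calibration-recovery checks.
#'
#' @param config A [cohort_config()].
#' @param costing A [cua_config()].
#' @return Nested list of expected values per arm.
#' @export
expected_generator_means <- function(config = cohort_config(),
                                     costing = cua_config()) {
  W <- length(config$wave_months)
  fr_rate <- costing$friction$cost_per_hour
  hours_mean <- mean(config$employment$contracted_hours)
  emp <- config$employment$fraction
  out <- list(employment_fraction = emp)
  for (a in arm_levels) {
    hc <- sum(unlist(config$healthcare_annual_euro[[a]]))
    med <- sum(unlist(config$medication$annual_euro[[a]]))
    cats <- names(costing$prices)
    counts <- vapply(cats, function(cat) {
      (config$healthcare_annual_euro[[a]][[cat]] %||% 0) / costing$prices[[cat]]
    }, numeric(1))
    travel <- sum(counts * costing$travel$distances[cats]) *
      costing$travel$km_rate
    pres <- emp * 4 * config$productivity$presenteeism_prob *
      config$productivity$presenteeism_hours_mean[[a]] * fr_rate
    absent <- emp * 4 * config$productivity$absence_prob_quarter[[a]] *
      config$productivity$absence_duration_mean_weeks[[a]] *
      hours_mean * fr_rate
    out[[a]] <- list(
      baseline_utility = config$utility$mean[[a]][1],
      wave_utility = config$utility$mean[[a]],
      completer_fraction = (1 - config$dropout_hazard[[a]])^(W - 1),
      healthcare = hc, medication = med, travel = travel,
      presenteeism = pres, absenteeism = absent
    )
  }
  out
}
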