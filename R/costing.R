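# Societal costing: health-care resource use, medication, travel,
# friction-method productivity loss, and the amortized intervention cost
# model. All amounts are euros in the configuration's price year.

cost_categories <- c("healthcare", "medication", "travel",
                     "absenteeism", "presenteeism", "intervention")

#' Health-care use cost
#'
#' Multiplies resource-use counts by unit prices.
#'
#' @param use Data frame with columns `category` and `count` (one row per
#'   contact type, counts within the recall window).
#' @param prices Named numeric vector, euro per unit per category.
#' @return Euro total.
#' @examples
#' healthcare_cost(
#'   data.frame(category = c("general_practitioner", "physical_therapist"),
#'              count = c(3, 1)),
#'   c(general_practitioner = 33, physical_therapist = 40))  # 139
#' @export
healthcare_cost <- function(use, prices) {
  if (nrow(use) == 0) return(0)
  unpriced <- setdiff(unique(use$category), names(prices))
  if (length(unpriced)) {
    stop("no unit price for category: ", paste(unpriced, collapse = ", "),
         call. = FALSE)
  }
  if (any(use$count < 0)) stop("resource-use counts must be >= 0", call. = FALSE)
  sum(use$count * prices[use$category])
}

#' Medication cost
#'
#' Self-reported medication use costed as dose units/day x days covered x
#' tariff price per dose unit.
#'
#' @param meds Data frame with columns `product`, `dose_per_day`, `days`.
#' @param prices Named numeric vector, euro per dose unit per product.
#' @return Euro total.
#' @examples
#' medication_cost(
#'   data.frame(product = "paracetamol", dose_per_day = 1, days = 365),
#'   c(paracetamol = 0.10))  # 36.5
#' @export
medication_cost <- function(meds, prices) {
  if (nrow(meds) == 0) return(0)
  unpriced <- setdiff(unique(meds$product), names(prices))
  if (length(unpriced)) {
    stop("no tariff price for product: ", paste(unpriced, collapse = ", "),
         call. = FALSE)
  }
  if (any(meds$dose_per_day < 0) || any(meds$days < 0)) {
    stop("medication doses and days must be >= 0", call. = FALSE)
  }
  sum(meds$dose_per_day * meds$days * prices[meds$product])
}

#' Patient travel cost
#'
#' Standard round-trip distances per contact times the per-kilometre rate.
#'
#' @param use Data frame with columns `category` and `count`.
#' @param distances Named numeric vector, round-trip km per contact.
#' @param km_rate Euro per kilometre (default 0.19).
#' @return Euro total.
#' @export
travel_cost <- function(use, distances, km_rate = 0.19) {
  if (nrow(use) == 0) return(0)
  missing_d <- setdiff(unique(use$category), names(distances))
  if (length(missing_d)) {
    stop("no travel distance for category: ", paste(missing_d, collapse = ", "),
         call. = FALSE)
  }
  sum(use$count * distances[use$category] * km_rate)
}

#' Friction parameters
#'
#' The friction-cost method prices productivity loss only until a worker
#' could be replaced. Costed absence per episode is capped at the friction
#' period plus a vacancy-filling allowance (default 12 + 4 = 16 weeks).
#'
#' @param friction_period_weeks Friction period (default 12).
#' @param vacancy_extension_weeks Vacancy-filling allowance (default 4).
#' @param cost_per_hour Euro per lost hour (default 34.90).
#' @return A list of class `friction_params`.
#' @export
friction_params <- function(friction_period_weeks = 12,
                            vacancy_extension_weeks = 4,
                            cost_per_hour = 34.90) {
  stopifnot(friction_period_weeks >= 0, vacancy_extension_weeks >= 0,
            cost_per_hour >= 0)
  structure(
    list(friction_period_weeks = friction_period_weeks,
         vacancy_extension_weeks = vacancy_extension_weeks,
         cost_per_hour = cost_per_hour),
    class = "friction_params"
  )
}

# Merge overlapping/contiguous [start, end) absence intervals.
merge_episodes <- function(start, duration) {
  ord <- order(start)
  start <- start[ord]
  end <- start + duration[ord]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_d <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_d <- c(out_d, me - ms)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), duration = c(out_d, me - ms))
}

#' Friction-method productivity cost
#'
#' Absenteeism: per merged absence episode, costed weeks are capped at the
#' friction period plus the vacancy allowance, then multiplied by contracted
#' hours/week and the hourly rate. Presenteeism: reported hours of lost
#' on-the-job productivity times the hourly rate. Non-employed patients cost
#' (0, 0). Episodes overlapping or touching each other are merged before
#' the cap is applied.
#'
#' @param productivity Data frame with columns `absence_start_week`,
#'   `absence_weeks` (NA when no episode) and `presenteeism_hours`.
#' @param employed Logical flag.
#' @param contracted_hours Contracted working hours per week.
#' @param params A [friction_params()].
#' @return Named numeric: `absenteeism` and `presenteeism` euros.
#' @examples
#' friction_productivity_cost(
#'   data.frame(absence_start_week = 0, absence_weeks = 2,
#'              presenteeism_hours = 0),
#'   employed = TRUE, contracted_hours = 40, friction_params())
#' # absenteeism 2 * 40 * 34.90 = 2792
#' @export
friction_productivity_cost <- function(productivity, employed,
                                       contracted_hours,
                                       params = friction_params()) {
  if (!isTRUE(employed) || nrow(productivity) == 0) {
    return(c(absenteeism = 0, presenteeism = 0))
  }
  pres_h <- productivity$presenteeism_hours
  if (any(pres_h < 0, na.rm = TRUE)) {
    stop("presenteeism hours must be >= 0", call. = FALSE)
  }
  presenteeism <- sum(pres_h, na.rm = TRUE) * params$cost_per_hour

  eps <- productivity[!is.na(productivity$absence_weeks), , drop = FALSE]
  absenteeism <- 0
  if (nrow(eps) > 0) {
    if (any(eps$absence_weeks < 0)) {
      stop("absence durations must be >= 0", call. = FALSE)
    }
    merged <- merge_episodes(eps$absence_start_week, eps$absence_weeks)
    cap <- params$friction_period_weeks + params$vacancy_extension_weeks
    absenteeism <- sum(pmin(merged$duration, cap)) *
      contracted_hours * params$cost_per_hour
  }
  c(absenteeism = absenteeism, presenteeism = presenteeism)
}

#' Per-patient intervention cost
#'
#' The amortized development share is `development_cost / amortization_years`
#' spread over the annual treated population (`prevalence x eligible_fraction
#' x reach_fraction`); to that are added therapist time at the tier rate,
#' the assistant's website-introduction session, and intake travel.
#' Control-arm patients cost 0.
#'
#' @param model The `intervention_model` section of [cua_config()].
#' @param therapist_minutes Therapist time spent on the patient, minutes.
#' @param tier `"basic"` or `"postacademic"` therapist salary tier.
#' @param intake_travel_km Patient round-trip km for face-to-face intakes.
#' @param is_intervention Logical; `FALSE` returns 0.
#' @return Euro total.
#' @export
intervention_cost_per_patient <- function(model, therapist_minutes,
                                          tier = "basic",
                                          intake_travel_km = 0,
                                          is_intervention = TRUE) {
  if (!any(is_intervention)) {
    return(rep(0, length(therapist_minutes)))
  }
  pop <- model$prevalence_count * model$eligible_fraction * model$reach_fraction
  if (pop <= 0) stop("intervention reach population is zero", call. = FALSE)
  dev_share <- model$development_cost / model$amortization_years / pop
  rate <- ifelse(tier == "postacademic",
                 model$therapist_rate_postacademic,
                 model$therapist_rate_basic)
  total <- dev_share +
    therapist_minutes / 60 * rate +
    model$assistant_session_minutes / 60 * model$assistant_rate +
    intake_travel_km * model$km_rate
  total * as.numeric(is_intervention)
}

#' Per-patient societal cost breakdown
#'
#' Computes annual euro totals per patient for the six cost components:
#' health-care use, medication, travel, absenteeism, presenteeism and the
#' intervention. Resource use and productivity are reported per measurement
#' wave, each wave covering the preceding quarter; the annual total sums
#' the four recall windows spanning the follow-up year
#' (`cost_wave_months`). Waves missed through dropout are imputed by
#' carrying the patient's previous quarterly amounts forward (the same
#' last-observation-carried-forward rule used for utilities); a wave counts
#' as observed when the patient's EQ-5D-3L profile at that wave is present.
#'
#' @param cohort A `cua_cohort` (tables `patients`, `eq5d`, `resource_use`,
#'   `medications`, `productivity`).
#' @param config A [cua_config()].
#' @return Tibble, one row per patient: `patient_id`, `arm`, the six
#'   component columns, and `total`.
#' @export
cost_breakdown <- function(cohort, config = cua_config()) {
  prices <- config$prices
  distances <- config$travel$distances
  km_rate <- config$travel$km_rate
  fr <- friction_params(config$friction$friction_period_weeks,
                        config$friction$vacancy_extension_weeks,
                        config$friction$cost_per_hour)
  waves <- config$wave_months
  cost_waves <- config$cost_wave_months
  wave_end_week <- waves * 52 / 12   # recall window (end-13, end]

  pts <- cohort$patients
  ids <- pts$patient_id
  fid <- function(x) factor(x, levels = ids)

  observed <- matrix(FALSE, nrow = length(ids), ncol = length(waves))
  ei <- match(cohort$eq5d$patient_id, ids)
  ew <- match(cohort$eq5d$wave_month, waves)
  ok <- !is.na(ei) & !is.na(ew) & !is.na(cohort$eq5d$mobility)
  observed[cbind(ei[ok], ew[ok])] <- TRUE

  ru_split <- split(cohort$resource_use, fid(cohort$resource_use$patient_id))
  med_split <- split(cohort$medications, fid(cohort$medications$patient_id))
  prod_split <- split(cohort$productivity, fid(cohort$productivity$patient_id))

  per_patient <- function(i) {
    obs <- observed[i, ]
    ru <- ru_split[[i]]
    pr <- prod_split[[i]]
    hc <- tr <- ab <- ps <- ifelse(obs, 0, NA_real_)

    if (nrow(ru) > 0) {
      euro_hc <- ru$count * prices[ru$category]
      euro_tr <- ru$count * distances[ru$category] * km_rate
      for (k in seq_along(waves)) {
        if (!obs[k]) next
        sel <- ru$wave_month == waves[k]
        hc[k] <- sum(euro_hc[sel])
        tr[k] <- sum(euro_tr[sel])
      }
    }

    if (isTRUE(pts$employed[i]) && nrow(pr) > 0) {
      merged_by_wave <- rep(0, length(waves))
      eps <- pr[!is.na(pr$absence_weeks), , drop = FALSE]
      if (nrow(eps) > 0) {
        m <- merge_episodes(eps$absence_start_week, eps$absence_weeks)
        cap <- fr$friction_period_weeks + fr$vacancy_extension_weeks
        # attribute each merged episode to the recall window containing
        # its start; windows are (wave_end - 13, wave_end] in weeks
        wk <- findInterval(m$start, wave_end_week - 13 + 1e-9)
        wk <- pmin(pmax(wk, 1L), length(waves))
        euro <- pmin(m$duration, cap) * pts$contracted_hours[i] * fr$cost_per_hour
        for (j in seq_along(euro)) {
          merged_by_wave[wk[j]] <- merged_by_wave[wk[j]] + euro[j]
        }
      }
      for (k in seq_along(waves)) {
        if (!obs[k]) next
        sel <- pr$wave_month == waves[k]
        ps[k] <- sum(pr$presenteeism_hours[sel], na.rm = TRUE) * fr$cost_per_hour
        ab[k] <- merged_by_wave[k]
      }
    }

    carry <- function(x) {
      if (all(is.na(x))) return(rep(0, length(x)))
      f <- locf_fill(x)$utility
      f[is.na(f)] <- 0
      f
    }
    hc <- carry(hc); tr <- carry(tr); ab <- carry(ab); ps <- carry(ps)
    in_year <- waves %in% cost_waves
    c(healthcare = sum(hc[in_year]), travel = sum(tr[in_year]),
      absenteeism = sum(ab[in_year]), presenteeism = sum(ps[in_year]))
  }

  quarterly <- t(vapply(seq_along(ids), per_patient, numeric(4)))

  medication <- vapply(seq_along(ids), function(i) {
    medication_cost(med_split[[i]], config$medication_prices)
  }, numeric(1))

  intervention <- intervention_cost_per_patient(
    config$intervention_model,
    therapist_minutes = tidyr::replace_na(pts$therapist_minutes, 0),
    tier = tidyr::replace_na(pts$therapist_tier, "basic"),
    intake_travel_km = tidyr::replace_na(pts$intake_travel_km, 0),
    is_intervention = pts$arm == "intervention"
  )

  out <- tibble::tibble(
    patient_id = ids,
    arm = pts$arm,
    healthcare = quarterly[, "healthcare"],
    medication = medication,
    travel = quarterly[, "travel"],
    absenteeism = quarterly[, "absenteeism"],
    presenteeism = quarterly[, "presenteeism"],
    intervention = intervention
  )
  out$total <- rowSums(out[, cost_categories])
  out
}

#' Patient totals excluding cost categories
#'
#' @param breakdown Tibble from [cost_breakdown()].
#' @param exclude Character vector of category names from
#'   `c("healthcare", "medication", "travel", "absenteeism",
#'   "presenteeism", "intervention")`.
#' @return Numeric vector: `total` minus the excluded components.
#' @export
total_excluding <- function(breakdown, exclude = character()) {
  bad <- setdiff(exclude, cost_categories)
  if (length(bad)) {
    stop("unknown cost categor(ies): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(exclude) == 0) return(breakdown$total)
  breakdown$total - rowSums(breakdown[, exclude, drop = FALSE])
}
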