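#' Last observation carried forward
#'
#' Fills missing waves of a utility trajectory by carrying the most recent
#' observed value forward. Leading missing waves (before the first
#' observation) are left missing; there is no backward fill. The operation
#' is idempotent and never changes an observed value.
#'
#' @param trajectory Either a numeric vector (in wave order, `NA` =
#'   missing) or a data frame with columns `wave_month` and `utility`
#'   (optionally `patient_id`, in which case filling is per patient).
#' @return For a vector input, a list with `utility` and logical `imputed`;
#'   for a data frame, the same frame ordered by wave with an added
#'   `imputed` column.
#' @examples
#' apply_locf(c(0.8, NA, 0.6))$utility   # 0.8 0.8 0.6
#' @export
apply_locf <- function(trajectory) {
  if (is.numeric(trajectory)) {
    filled <- locf_fill(trajectory)
    return(filled)
  }
  stopifnot(is.data.frame(trajectory),
            all(c("wave_month", "utility") %in% names(trajectory)))
  grouped <- "patient_id" %in% names(trajectory)
  if (grouped) {
    trajectory |>
      dplyr::arrange(.data$patient_id, .data$wave_month) |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::group_modify(function(d, key) {
        f <- locf_fill(d$utility)
        d$utility <- f$utility
        d$imputed <- f$imputed
        d
      }) |>
      dplyr::ungroup()
  } else {
    d <- dplyr::arrange(trajectory, .data$wave_month)
    f <- locf_fill(d$utility)
    d$utility <- f$utility
    d$imputed <- f$imputed
    d
  }
}

locf_fill <- function(x) {
  if (all(is.na(x))) {
    stop("cannot carry forward: all waves are missing", call. = FALSE)
  }
  obs <- !is.na(x)
  idx <- cummax(ifelse(obs, seq_along(x), 0L))
  filled <- rep(NA_real_, length(x))
  filled[idx > 0] <- x[idx[idx > 0]]
  list(utility = filled, imputed = idx > 0 & !obs)
}

#' QALYs by the trapezium rule
#'
#' Integrates a utility trajectory over a time horizon (trapezium rule,
#' i.e. the exact integral of the piecewise-linear interpolant) and
#' converts months to years, so a constant utility of 1 over 12 months
#' yields 1 QALY.
#'
#' @param wave_months Strictly increasing measurement times in months.
#' @param utilities Utilities at those waves; must be non-missing at every
#'   wave inside the horizon (run [apply_locf()] first).
#' @param horizon Length-2 numeric, start and end of the integration window
#'   in months; both must coincide with measurement waves.
#' @return QALYs (years) accrued over the horizon.
#' @examples
#' qaly_trapezoid(c(0, 12), c(1, 0.5), horizon = c(0, 12))  # 0.75
#' @export
qaly_trapezoid <- function(wave_months, utilities, horizon = range(wave_months)) {
  stopifnot(length(wave_months) == length(utilities), length(horizon) == 2)
  if (is.unsorted(wave_months, strictly = TRUE)) {
    stop("wave_months must be strictly increasing", call. = FALSE)
  }
  inside <- wave_months >= horizon[1] & wave_months <= horizon[2]
  t <- wave_months[inside]
  u <- utilities[inside]
  if (length(t) < 2) {
    stop("horizon must span at least two measurement waves", call. = FALSE)
  }
  if (t[1] != horizon[1] || t[length(t)] != horizon[2]) {
    stop("horizon endpoints must coincide with measurement waves", call. = FALSE)
  }
  if (anyNA(u)) {
    stop("missing utility inside the horizon; apply_locf() first", call. = FALSE)
  }
  sum(diff(t) * (head(u, -1) + tail(u, -1)) / 2) / 12
}

#' Per-patient QALYs for a cohort
#'
#' Scores the long-format EQ-5D-3L table, applies last-observation-carried-
#' forward imputation, and integrates each patient's trajectory over the
#' QALY horizon. Patients with no observed wave at or before the horizon
#' (so that LOCF leaves the horizon incomplete) are excluded with a warning.
#'
#' @param cohort A `cua_cohort` (see [generate_cohort()] / [read_cohort()])
#'   or a list with elements `patients` and `eq5d`.
#' @param value_set An [eq5d3l_value_set()]; defaults to the set named in
#'   the default configuration.
#' @param horizon Length-2 numeric months; default from the configuration
#'   is the 1-year window from the post-intervention wave (months 6 to 18).
#' @return Tibble with `patient_id`, `arm`, `qaly`, and `n_imputed` (number
#'   of carried-forward waves inside the horizon).
#' @export
cohort_qalys <- function(cohort,
                         value_set = NULL,
                         horizon = NULL) {
  cfg <- cua_config()
  if (is.null(value_set)) value_set <- eq5d3l_value_set(cfg$value_set)
  if (is.null(horizon)) horizon <- cfg$qaly_horizon_months
  eq5d <- cohort$eq5d
  traj <- eq5d |>
    dplyr::mutate(utility = score_eq5d3l(
      eq5d[, eq5d_dimensions], value_set
    )) |>
    dplyr::select("patient_id", "wave_month", "utility")

  res <- traj |>
    dplyr::arrange(.data$patient_id, .data$wave_month) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(d, key) {
      observed <- !is.na(d$utility)
      # LOCF from baseline alone would extrapolate a single pre-treatment
      # measurement across the whole follow-up year; require at least one
      # post-baseline observation.
      if (!any(observed & d$wave_month > 0)) {
        return(tibble::tibble(qaly = NA_real_, n_imputed = NA_integer_))
      }
      f <- locf_fill(d$utility)
      inside <- d$wave_month >= horizon[1] & d$wave_month <= horizon[2]
      if (anyNA(f$utility[inside])) {
        return(tibble::tibble(qaly = NA_real_, n_imputed = NA_integer_))
      }
      tibble::tibble(
        qaly = qaly_trapezoid(d$wave_month, f$utility, horizon),
        n_imputed = sum(f$imputed[inside])
      )
    }) |>
    dplyr::ungroup()

  res <- dplyr::left_join(res, cohort$patients[, c("patient_id", "arm")],
                          by = "patient_id")
  n_drop <- sum(is.na(res$qaly))
  if (n_drop > 0) {
    warning(n_drop, " patient(s) excluded from the QALY analysis: ",
            "no observed utility covering the horizon", call. = FALSE)
    res <- res[!is.na(res$qaly), ]
  }
  res[, c("patient_id", "arm", "qaly", "n_imputed")]
}

#' Arm-level QALY summary
#'
#' @param qalys Tibble from [cohort_qalys()] (columns `arm`, `qaly`).
#' @return Tibble with one row per arm: `n`, `mean_qaly`, `sd_qaly`.
#' @export
arm_mean_qaly <- function(qalys) {
  stopifnot(nrow(qalys) > 0)
  out <- qalys |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_qaly = mean(.data$qaly),
      sd_qaly = sd(.data$qaly),
      .groups = "drop"
    )
  missing_arm <- setdiff(arm_levels, out$arm)
  if (length(missing_arm)) {
    stop("empty arm(s): ", paste(missing_arm, collapse = ", "), call. = FALSE)
  }
  out
}
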