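# Incremental cost-utility analysis: point estimates, stratified patient
# bootstrap, percentile intervals, CE-plane quadrants and the CEAC.

#' Incremental point estimates and the ICUR
#'
#' Differences are intervention minus control of the arm means; the
#' incremental cost-utility ratio (ICUR) divides the cost difference by the
#' QALY difference and is flagged undefined when the QALY difference is 0.
#'
#' @param qaly_control,qaly_intervention Per-patient QALYs by arm (any
#'   nonempty numeric vectors; arm means are used).
#' @param cost_control,cost_intervention Per-patient euro totals by arm.
#' @return List: `d_qaly`, `d_cost`, `icur`, `icur_defined`.
#' @examples
#' incremental_point_estimates(0.5, 0.6, 100, 150)  # ICUR 500
#' @export
incremental_point_estimates <- function(qaly_control, qaly_intervention,
                                        cost_control, cost_intervention) {
  if (!length(qaly_control) || !length(qaly_intervention)) {
    stop("both arms must be nonempty", call. = FALSE)
  }
  d_qaly <- mean(qaly_intervention) - mean(qaly_control)
  d_cost <- mean(cost_intervention) - mean(cost_control)
  list(
    d_qaly = d_qaly,
    d_cost = d_cost,
    icur = if (d_qaly != 0) d_cost / d_qaly else NA_real_,
    icur_defined = d_qaly != 0
  )
}

#' Stratified patient-level bootstrap of incremental pairs
#'
#' Resamples patients with replacement independently within each arm,
#' keeping each patient's (QALY, cost) pair intact so the within-patient
#' cost-effect correlation is preserved, and records the replicate's
#' incremental QALYs and costs (and the arm means, used for arm-level
#' percentile intervals).
#'
#' @param data Tibble with columns `arm`, `qaly`, `cost` (one row per
#'   patient; arm labels `"control"` / `"intervention"`, each with >= 2
#'   patients).
#' @param replications Number of bootstrap replicates.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Tibble of class `bootstrap_draws` with columns `replicate`,
#'   `qaly_control`, `qaly_intervention`, `cost_control`,
#'   `cost_intervention`, `d_qaly`, `d_cost`.
#' @export
bootstrap_incrementals <- function(data, replications = 1000, seed = NULL) {
  stopifnot(all(c("arm", "qaly", "cost") %in% names(data)))
  ctl <- data[data$arm == "control", ]
  trt <- data[data$arm == "intervention", ]
  if (nrow(ctl) < 2 || nrow(trt) < 2) {
    stop("each arm needs at least 2 patients to bootstrap", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  R <- as.integer(replications)

  arm_means <- function(d) {
    n <- nrow(d)
    idx <- matrix(sample.int(n, n * R, replace = TRUE), nrow = n)
    list(qaly = colMeans(matrix(d$qaly[idx], nrow = n)),
         cost = colMeans(matrix(d$cost[idx], nrow = n)))
  }
  mc <- arm_means(ctl)
  mt <- arm_means(trt)

  out <- tibble::tibble(
    replicate = seq_len(R),
    qaly_control = mc$qaly,
    qaly_intervention = mt$qaly,
    cost_control = mc$cost,
    cost_intervention = mt$cost,
    d_qaly = mt$qaly - mc$qaly,
    d_cost = mt$cost - mc$cost
  )
  class(out) <- c("bootstrap_draws", class(out))
  attr(out, "seed") <- seed
  out
}

#' Percentile interval of bootstrap draws
#'
#' Empirical percentiles using linear interpolation between order
#' statistics (R's default quantile definition, type 7): for probability
#' `p` and `n` draws the quantile sits at rank `1 + p (n - 1)`.
#'
#' @param draws Numeric vector of bootstrap replicates.
#' @param bounds Length-2 percent bounds (default `c(2.5, 97.5)`).
#' @return Named numeric `c(lower, upper)`.
#' @export
percentile_interval <- function(draws, bounds = c(2.5, 97.5)) {
  stopifnot(length(draws) > 0, length(bounds) == 2,
            bounds[1] >= 0, bounds[1] < bounds[2], bounds[2] <= 100)
  q <- quantile(draws, probs = bounds / 100, names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Cost-effectiveness plane quadrant proportions
#'
#' Classifies bootstrap (dQALY, dCost) pairs: NE = more effective & more
#' costly, SE = more effective & cheaper (dominant), NW = less effective &
#' costlier (dominated), SW = less effective & cheaper. Boundary draws with
#' an exact zero are assigned to the adjacent quadrant that is worse for
#' the intervention: dCost = 0 goes to NE rather than SE, dQALY = 0 goes
#' to NE rather than NW (and to SW when dCost < 0).
#'
#' @param draws A [bootstrap_incrementals()] tibble, or any data frame with
#'   `d_qaly` and `d_cost`.
#' @return Named numeric proportions `c(NE, SE, NW, SW)` summing to 1.
#' @export
quadrant_proportions <- function(draws) {
  q <- draws$d_qaly
  c <- draws$d_cost
  stopifnot(length(q) > 0)
  ne <- q >= 0 & c >= 0
  se <- q > 0 & c < 0
  nw <- q < 0 & c >= 0
  sw <- q <= 0 & c < 0 & !se
  n <- length(q)
  c(NE = sum(ne), SE = sum(se), NW = sum(nw), SW = sum(sw)) / n
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value lambda, the probability of the
#' intervention being cost-effective is the fraction of bootstrap draws
#' with strictly positive net monetary benefit
#' `lambda * dQALY - dCost > 0`.
#'
#' @param draws A [bootstrap_incrementals()] tibble (columns `d_qaly`,
#'   `d_cost`).
#' @param wtp Nonnegative, increasing willingness-to-pay grid (euro/QALY).
#' @return Tibble with columns `wtp` and `probability`.
#' @export
ceac <- function(draws, wtp = seq(0, 100000, by = 1000)) {
  stopifnot(nrow(draws) > 0, length(wtp) > 0)
  prob <- vapply(
    wtp,
    function(l) mean(l * draws$d_qaly - draws$d_cost > 0),
    numeric(1)
  )
  tibble::tibble(wtp = wtp, probability = prob)
}

#' Run the full incremental cost-utility analysis
#'
#' Joins per-patient QALYs and cost breakdowns, applies any cost-category
#' exclusion (e.g. medication for the secondary analysis), computes
#' full-sample point estimates, the stratified patient bootstrap,
#' percentile intervals, CE-plane quadrant proportions and the CEAC.
#' QALYs are unaffected by cost exclusions by construction.
#'
#' @param qalys Tibble from [cohort_qalys()] (`patient_id`, `arm`, `qaly`).
#' @param breakdown Tibble from [cost_breakdown()].
#' @param config An [analysis_config()].
#' @return Object of class `cua_result`: point estimates, intervals,
#'   quadrants, `ceac` tibble, the bootstrap `draws`, arm summaries and
#'   the excluded-category set.
#' @export
run_cua <- function(qalys, breakdown, config = analysis_config()) {
  cost <- tibble::tibble(
    patient_id = breakdown$patient_id,
    cost = total_excluding(breakdown, config$exclude)
  )
  data <- dplyr::inner_join(qalys, cost, by = "patient_id")
  if (nrow(data) < nrow(qalys)) {
    warning(nrow(qalys) - nrow(data),
            " patient(s) dropped: no matching cost record", call. = FALSE)
  }

  point <- incremental_point_estimates(
    data$qaly[data$arm == "control"], data$qaly[data$arm == "intervention"],
    data$cost[data$arm == "control"], data$cost[data$arm == "intervention"]
  )
  draws <- bootstrap_incrementals(
    data, replications = config$bootstrap_replications, seed = config$seed
  )

  arm_summary <- data |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_qaly = mean(.data$qaly), sd_qaly = sd(.data$qaly),
      mean_cost = mean(.data$cost), sd_cost = sd(.data$cost),
      .groups = "drop"
    )

  structure(
    list(
      d_qaly = point$d_qaly,
      d_cost = point$d_cost,
      icur = point$icur,
      icur_defined = point$icur_defined,
      ci_d_qaly = percentile_interval(draws$d_qaly, config$percentiles),
      ci_d_cost = percentile_interval(draws$d_cost, config$percentiles),
      quadrants = quadrant_proportions(draws),
      ceac = ceac(draws, config$wtp),
      draws = draws,
      arm_summary = arm_summary,
      excluded = config$exclude,
      percentiles = config$percentiles,
      seed = config$seed
    ),
    class = "cua_result"
  )
}

#' @export
print.cua_result <- function(x, ...) {
  lbl <- if (length(x$excluded)) {
    paste0(" (excluding ", paste(x$excluded, collapse = ", "), ")")
  } else ""
  cat("Incremental cost-utility analysis", lbl, "\n", sep = "")
  cat(sprintf("  delta QALY: %.4f (%g%%-%g%% CI %.4f to %.4f)\n",
              x$d_qaly, x$percentiles[1], x$percentiles[2],
              x$ci_d_qaly["lower"], x$ci_d_qaly["upper"]))
  cat(sprintf("  delta cost: %.2f (CI %.2f to %.2f)\n",
              x$d_cost, x$ci_d_cost["lower"], x$ci_d_cost["upper"]))
  if (x$icur_defined) {
    cat(sprintf("  ICUR: %.2f euro/QALY\n", x$icur))
  } else {
    cat("  ICUR: undefined (delta QALY is 0)\n")
  }
  cat("  CE-plane quadrants:",
      paste(names(x$quadrants), sprintf("%.1f%%", 100 * x$quadrants),
            collapse = ", "), "\n")
  p80 <- x$ceac$probability[x$ceac$wtp == 80000]
  if (length(p80)) {
    cat(sprintf("  P(cost-effective at 80,000 euro/QALY): %.0f%%\n", 100 * p80))
  }
  invisible(x)
}
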