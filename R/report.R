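# Report assembly: machine-readable tables of arm-level QALYs and costs
# with bootstrap percentiles (primary and medication-excluded secondary
# analyses), per-category cost means, and the CE-plane / CEAC data files.

#' Assemble the analysis report bundle
#'
#' @param qalys Tibble from [cohort_qalys()].
#' @param breakdown Tibble from [cost_breakdown()].
#' @param primary `cua_result` of the primary analysis ([run_cua()]).
#' @param secondary Optional `cua_result` of the secondary analysis
#'   (medication costs excluded).
#' @return A list of class `cua_report`: `qaly_cost_table` (per analysis
#'   and arm: mean QALY/cost with bootstrap percentiles and the
#'   incremental columns), `cost_category_table` (per-category mean (SD)
#'   per arm with a between-arm t-test p value), `ce_plane` (bootstrap
#'   draws) and `ceac` tibbles.
#' @export
build_report <- function(qalys, breakdown, primary, secondary = NULL) {
  stopifnot(inherits(primary, "cua_result"))
  analyses <- list(primary = primary)
  if (!is.null(secondary)) {
    stopifnot(inherits(secondary, "cua_result"))
    analyses$secondary <- secondary
  }

  qc_rows <- purrr::imap(analyses, function(res, nm) {
    pb <- res$percentiles
    per_arm <- purrr::map(arm_levels, function(a) {
      qi <- percentile_interval(res$draws[[paste0("qaly_", a)]], pb)
      ci <- percentile_interval(res$draws[[paste0("cost_", a)]], pb)
      s <- res$arm_summary[res$arm_summary$arm == a, ]
      tibble::tibble(
        analysis = nm, arm = a,
        mean_qaly = s$mean_qaly, qaly_lower = qi["lower"],
        qaly_upper = qi["upper"],
        mean_cost = s$mean_cost, cost_lower = ci["lower"],
        cost_upper = ci["upper"]
      )
    })
    inc <- tibble::tibble(
      analysis = nm, arm = "difference",
      mean_qaly = res$d_qaly,
      qaly_lower = res$ci_d_qaly["lower"], qaly_upper = res$ci_d_qaly["upper"],
      mean_cost = res$d_cost,
      cost_lower = res$ci_d_cost["lower"], cost_upper = res$ci_d_cost["upper"]
    )
    dplyr::bind_rows(per_arm, inc)
  })
  qaly_cost_table <- dplyr::bind_rows(qc_rows)

  cost_category_table <- breakdown |>
    tidyr::pivot_longer(dplyr::all_of(c(cost_categories, "total")),
                        names_to = "category", values_to = "euro") |>
    dplyr::group_by(.data$category) |>
    dplyr::group_modify(function(d, key) {
      ctl <- d$euro[d$arm == "control"]
      trt <- d$euro[d$arm == "intervention"]
      p <- if (sd(d$euro) == 0) NA_real_ else {
        t.test(ctl, trt, var.equal = TRUE)$p.value
      }
      tibble::tibble(
        mean_control = mean(ctl), sd_control = sd(ctl),
        mean_intervention = mean(trt), sd_intervention = sd(trt),
        p_value = p
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$category, c(cost_categories, "total")))

  structure(
    list(
      qaly_cost_table = qaly_cost_table,
      cost_category_table = cost_category_table,
      ce_plane = primary$draws[, c("replicate", "d_qaly", "d_cost")],
      ce_plane_secondary = if (!is.null(secondary)) {
        secondary$draws[, c("replicate", "d_qaly", "d_cost")]
      },
      ceac = primary$ceac,
      ceac_secondary = if (!is.null(secondary)) secondary$ceac
    ),
    class = "cua_report"
  )
}

#' Write a report bundle to CSV files
#'
#' Serialization is deterministic: stable row order and fixed 6-decimal
#' formatting for floats; euro means in the category table are additionally
#' rounded to whole euros (money is never rounded internally, only here at
#' the report layer). Re-writing the same bundle is byte-identical.
#'
#' @param report A `cua_report` from [build_report()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cua_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(d, euro_cols = character()) {
    for (nm in names(d)) {
      if (nm %in% euro_cols) {
        d[[nm]] <- sprintf("%d", as.integer(round(d[[nm]])))
      } else if (is.double(d[[nm]])) {
        d[[nm]] <- sprintf("%.6f", d[[nm]])
      }
    }
    d
  }
  files <- list(
    qaly_cost = fmt(report$qaly_cost_table),
    cost_categories = fmt(report$cost_category_table,
                          euro_cols = c("mean_control", "sd_control",
                                        "mean_intervention",
                                        "sd_intervention")),
    ce_plane = fmt(report$ce_plane),
    ceac = fmt(report$ceac)
  )
  if (!is.null(report$ce_plane_secondary)) {
    files$ce_plane_secondary <- fmt(report$ce_plane_secondary)
  }
  if (!is.null(report$ceac_secondary)) {
    files$ceac_secondary <- fmt(report$ceac_secondary)
  }
  for (nm in names(files)) {
    readr::write_csv(files[[nm]], file.path(dir, paste0(nm, ".csv")), na = "")
  }
  invisible(dir)
}
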