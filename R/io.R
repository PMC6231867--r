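# CSV schemas and readers/writers for the five cohort tables, with
# referential-integrity validation, plus baseline-comparison statistics.

cohort_table_names <- c("patients", "eq5d", "resource_use",
                        "medications", "productivity")

cohort_schemas <- list(
  patients = c("patient_id", "arm", "age", "sex", "employed",
               "contracted_hours", "treatment_weeks", "therapist_minutes",
               "therapist_tier", "intake_travel_km"),
  eq5d = c("patient_id", "wave_month", eq5d_dimensions),
  resource_use = c("patient_id", "wave_month", "category", "count"),
  medications = c("patient_id", "class", "product", "dose_per_day", "days"),
  productivity = c("patient_id", "wave_month", "absence_start_week",
                   "absence_weeks", "presenteeism_hours")
)

cohort_col_types <- list(
  patients = readr::cols(
    patient_id = "c", arm = "c", age = "d", sex = "c", employed = "l",
    contracted_hours = "d", treatment_weeks = "d", therapist_minutes = "d",
    therapist_tier = "c", intake_travel_km = "d"
  ),
  eq5d = readr::cols(
    patient_id = "c", wave_month = "d", mobility = "d", self_care = "d",
    usual_activities = "d", pain_discomfort = "d", anxiety_depression = "d"
  ),
  resource_use = readr::cols(
    patient_id = "c", wave_month = "d", category = "c", count = "d"
  ),
  medications = readr::cols(
    patient_id = "c", class = "c", product = "c", dose_per_day = "d",
    days = "d"
  ),
  productivity = readr::cols(
    patient_id = "c", wave_month = "d", absence_start_week = "d",
    absence_weeks = "d", presenteeism_hours = "d"
  )
)

#' Write a cohort to a directory of CSV files
#'
#' One UTF-8 CSV per table (`patients.csv`, `eq5d.csv`, `resource_use.csv`,
#' `medications.csv`, `productivity.csv`), "." as decimal mark, empty
#' fields for missing values. `write_cohort()` then [read_cohort()] is the
#' identity.
#'
#' @param cohort A `cua_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  validate_cohort(cohort)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in cohort_table_names) {
    readr::write_csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")),
                     na = "")
  }
  invisible(dir)
}

#' Read a cohort from a directory of CSV files
#'
#' @param dir Directory written by [write_cohort()].
#' @return A validated `cua_cohort`.
#' @export
read_cohort <- function(dir) {
  tables <- lapply(cohort_table_names, function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      stop("missing cohort table file: ", path, call. = FALSE)
    }
    readr::read_csv(path, col_types = cohort_col_types[[nm]], na = "",
                    progress = FALSE)
  })
  names(tables) <- cohort_table_names
  cohort <- structure(tables, class = "cua_cohort")
  validate_cohort(cohort)
  cohort
}

#' Validate cohort tables against the schemas
#'
#' Checks headers, arm labels, EQ-5D-3L levels (with row/column
#' diagnostics), nonnegative integer counts, and referential integrity
#' (every `patient_id` in a satellite table occurs in `patients`).
#'
#' @param cohort A `cua_cohort` or plain list of the five tables.
#' @return The cohort, invisibly; errors describe the first violation.
#' @export
validate_cohort <- function(cohort) {
  for (nm in cohort_table_names) {
    tbl <- cohort[[nm]]
    if (is.null(tbl)) stop("missing cohort table: ", nm, call. = FALSE)
    missing_cols <- setdiff(cohort_schemas[[nm]], names(tbl))
    if (length(missing_cols)) {
      stop("table '", nm, "' lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
  }
  pts <- cohort$patients
  bad_arm <- setdiff(unique(pts$arm), arm_levels)
  if (length(bad_arm)) {
    stop("table 'patients': invalid arm label(s): ",
         paste(bad_arm, collapse = ", "),
         " (must be 'control' or 'intervention')", call. = FALSE)
  }
  if (anyDuplicated(pts$patient_id)) {
    stop("table 'patients': duplicated patient_id", call. = FALSE)
  }
  for (d in eq5d_dimensions) {
    v <- cohort$eq5d[[d]]
    bad <- which(!is.na(v) & !(v %in% c(1, 2, 3)))
    if (length(bad)) {
      stop("table 'eq5d', row ", bad[1], ", column '", d, "': level ",
           v[bad[1]], " is not in {1, 2, 3}", call. = FALSE)
    }
  }
  cnt <- cohort$resource_use$count
  bad <- which(!is.na(cnt) & (cnt < 0 | cnt != round(cnt)))
  if (length(bad)) {
    stop("table 'resource_use', row ", bad[1],
         ", column 'count': must be a nonnegative integer", call. = FALSE)
  }
  for (nm in setdiff(cohort_table_names, "patients")) {
    orphan <- setdiff(unique(cohort[[nm]]$patient_id), pts$patient_id)
    if (length(orphan)) {
      stop("table '", nm, "': patient_id not present in 'patients': ",
           paste(head(orphan, 3), collapse = ", "), call. = FALSE)
    }
  }
  invisible(cohort)
}

#' Baseline between-arm comparisons
#'
#' Builds a baseline characteristics table: continuous variables (age,
#' baseline utility) are compared with an independent-samples t test
#' (pooled variance by default, Welch by flag); dichotomous variables
#' (sex, employment, medication-class use) with a chi-square test on the
#' 2x2 table without continuity correction by default. Missing values are
#' excluded listwise per variable. A variable that is constant across both
#' arms, or a 2x2 table with a zero margin, is skipped with a note.
#'
#' @param cohort A `cua_cohort`.
#' @param value_set Value set for scoring baseline utilities.
#' @param welch Use Welch's t test instead of the pooled-variance test.
#' @param correct Apply Yates' continuity correction to chi-square tests.
#' @return Tibble: `variable`, `type`, per-arm summaries (mean (SD) or
#'   yes/no/missing counts), `statistic`, `p_value`, `test`, `note`.
#' @export
baseline_table <- function(cohort, value_set = NULL, welch = FALSE,
                           correct = FALSE) {
  if (is.null(value_set)) value_set <- eq5d3l_value_set(cua_config()$value_set)
  pts <- cohort$patients
  if (length(unique(pts$arm)) < 2) {
    stop("both arms must be present", call. = FALSE)
  }
  is_ctl <- pts$arm == "control"

  base_eq <- cohort$eq5d[cohort$eq5d$wave_month == 0, ]
  base_u <- score_eq5d3l(base_eq[, eq5d_dimensions], value_set)
  base_u <- base_u[match(pts$patient_id, base_eq$patient_id)]

  rows <- list()
  add_cont <- function(name, x) {
    xc <- x[is_ctl]; xi <- x[!is_ctl]
    smry <- function(v) sprintf("%.2f (%.2f)", mean(v, na.rm = TRUE),
                                sd(v, na.rm = TRUE))
    if (sd(x, na.rm = TRUE) == 0 || all(is.na(xc)) || all(is.na(xi))) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        variable = name, type = "continuous",
        control = smry(xc), intervention = smry(xi),
        statistic = NA_real_, p_value = NA_real_, test = NA_character_,
        note = "constant or empty; test skipped"
      )
      return(invisible())
    }
    tt <- t.test(xc, xi, var.equal = !welch)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      variable = name, type = "continuous",
      control = smry(xc), intervention = smry(xi),
      statistic = unname(tt$statistic), p_value = tt$p.value,
      test = if (welch) "Welch t" else "Student t", note = NA_character_
    )
  }
  add_dich <- function(name, yes) {
    tab <- table(
      arm = factor(pts$arm, levels = arm_levels),
      yes = factor(yes, levels = c(TRUE, FALSE))
    )
    smry <- function(a) sprintf(
      "%d yes / %d no / %d missing", tab[a, "TRUE"], tab[a, "FALSE"],
      sum(pts$arm == a & is.na(yes)))
    margins_ok <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
    if (!margins_ok) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        variable = name, type = "dichotomous",
        control = smry("control"), intervention = smry("intervention"),
        statistic = NA_real_, p_value = NA_real_, test = NA_character_,
        note = "degenerate 2x2 margin; test skipped"
      )
      return(invisible())
    }
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    rows[[length(rows) + 1]] <<- tibble::tibble(
      variable = name, type = "dichotomous",
      control = smry("control"), intervention = smry("intervention"),
      statistic = unname(ct$statistic), p_value = ct$p.value,
      test = if (correct) "chi-square (Yates)" else "chi-square",
      note = NA_character_
    )
  }

  add_cont("age", pts$age)
  add_cont("baseline_utility", base_u)
  add_dich("female", ifelse(is.na(pts$sex), NA, pts$sex == "f"))
  add_dich("employed", pts$employed)
  for (cl in sort(unique(cohort$medications$class))) {
    users <- unique(cohort$medications$patient_id[
      cohort$medications$class == cl])
    add_dich(paste0("medication_", cl), pts$patient_id %in% users)
  }
  dplyr::bind_rows(rows)
}
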