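# Societal costing components and the per-patient breakdown.

test_that("health-care costs are counts times unit prices", {
  prices <- c(general_practitioner = 33, physical_therapist = 40)
  use <- data.frame(category = c("general_practitioner", "physical_therapist"),
                    count = c(3, 1))
  expect_equal(healthcare_cost(use, prices), 139)
  expect_equal(healthcare_cost(use[0, ], prices), 0)
  use$category[1] <- "chiropractor"
  expect_error(healthcare_cost(use, prices), "chiropractor")
})

test_that("medication costs are dose x days x tariff price", {
  prices <- c(painkiller = 0.10, biologic = 50, nsaid = 0.20)
  expect_equal(
    medication_cost(data.frame(product = "painkiller", dose_per_day = 1,
                               days = 365), prices),
    36.50)
  expect_equal(medication_cost(empty_medications(), prices), 0)
  meds <- data.frame(product = c("biologic", "nsaid"),
                     dose_per_day = c(1, 1), days = c(300, 365))
  expect_equal(medication_cost(meds, prices), 15073)
  expect_error(
    medication_cost(data.frame(product = "unknown", dose_per_day = 1,
                               days = 1), prices),
    "unknown")
})

test_that("travel costs use round-trip distances at the per-km rate", {
  expect_equal(
    travel_cost(data.frame(category = "hospital", count = 1),
                c(hospital = 14), km_rate = 0.19),
    2.66)
  expect_equal(
    travel_cost(data.frame(category = "general_practitioner", count = 10),
                c(general_practitioner = 1.0), km_rate = 0.19),
    1.90)
  expect_equal(travel_cost(empty_resource_use(), c(hospital = 14)), 0)
  expect_error(
    travel_cost(data.frame(category = "hospital", count = 1), c(gp = 1)),
    "hospital")
})

test_that("friction method caps absence episodes at 16 weeks", {
  params <- friction_params()   # 12 + 4 weeks, 34.90/h
  prod2 <- data.frame(absence_start_week = 0, absence_weeks = 2,
                      presenteeism_hours = 0)
  out <- friction_productivity_cost(prod2, TRUE, 40, params)
  expect_equal(out[["absenteeism"]], 2 * 40 * 34.90)

  prod52 <- data.frame(absence_start_week = 0, absence_weeks = 52,
                       presenteeism_hours = 0)
  out <- friction_productivity_cost(prod52, TRUE, 40, params)
  expect_equal(out[["absenteeism"]], 16 * 40 * 34.90)  # 22336

  pres <- data.frame(absence_start_week = NA, absence_weeks = NA,
                     presenteeism_hours = 10)
  out <- friction_productivity_cost(pres, TRUE, 40, params)
  expect_equal(unname(out), c(0, 349))

  expect_equal(
    unname(friction_productivity_cost(prod52, FALSE, NA, params)), c(0, 0))
  expect_error(
    friction_productivity_cost(
      data.frame(absence_start_week = 0, absence_weeks = -1,
                 presenteeism_hours = 0), TRUE, 40, params),
    ">= 0")
})

test_that("absenteeism is nondecreasing in duration, constant past the cap", {
  params <- friction_params()
  cost_of <- function(d) {
    friction_productivity_cost(
      data.frame(absence_start_week = 0, absence_weeks = d,
                 presenteeism_hours = 0), TRUE, 32, params)[["absenteeism"]]
  }
  costs <- vapply(1:30, cost_of, numeric(1))
  expect_true(all(diff(costs) >= 0))
  expect_equal(costs[16:30], rep(costs[16], 15))
  expect_lt(costs[15], costs[16])
})

test_that("overlapping absence episodes are merged before capping", {
  params <- friction_params()
  eps <- data.frame(absence_start_week = c(0, 10, 30),
                    absence_weeks = c(12, 12, 2),
                    presenteeism_hours = 0)
  # [0,12) and [10,22) merge to 22 weeks -> capped at 16; plus 2
  out <- friction_productivity_cost(eps, TRUE, 10, params)
  expect_equal(out[["absenteeism"]], (16 + 2) * 10 * 34.90)
})

test_that("intervention cost combines amortized development share and time", {
  model <- list(development_cost = 50000, amortization_years = 5,
                prevalence_count = 100000, eligible_fraction = 0.30,
                reach_fraction = 0.10, therapist_rate_basic = 40,
                therapist_rate_postacademic = 60, assistant_rate = 20,
                assistant_session_minutes = 30, km_rate = 1)
  # development share: 50000 / 5 / 3000 (assistant session switched off)
  no_assist <- model
  no_assist$assistant_session_minutes <- 0
  share <- intervention_cost_per_patient(no_assist, 0, "basic", 0)
  expect_equal(share, 10 / 3, tolerance = 1e-9)
  # 10 h x 40 + 10 assistant + 5 travel + 3.33 share
  expect_equal(
    intervention_cost_per_patient(model, 600, "basic", 5),
    418 + 1 / 3, tolerance = 1e-9)
  expect_equal(
    intervention_cost_per_patient(model, 600, "basic", 5,
                                  is_intervention = FALSE),
    0)
  model$reach_fraction <- 0
  expect_error(intervention_cost_per_patient(model, 0), "zero")
})

test_that("breakdown components are hand-checkable on a tiny cohort", {
  cfg <- cua_config()
  coh <- blank_cohort()
  coh$resource_use <- tibble::tibble(
    patient_id = "T01",
    wave_month = c(9, 12, 15, 18),
    category = "general_practitioner",
    count = c(1, 2, 0, 1)
  )
  coh$medications <- tibble::tibble(
    patient_id = "T02", class = "biologic", product = "biologic",
    dose_per_day = 1, days = 100
  )
  bd <- cost_breakdown(coh, cfg)
  expect_equal(bd$healthcare[bd$patient_id == "T01"], 4 * 33)
  expect_equal(bd$travel[bd$patient_id == "T01"], 4 * 3.4 * 0.19)
  expect_equal(bd$medication[bd$patient_id == "T02"], 100 * 68)
  # intervention patients: dev share + 300 min x 75/h + 0.5 h x 36 + 28 km
  dev_share <- 150000 / 5 / (260000 * 0.3 * 0.1)
  expect_equal(bd$intervention[bd$patient_id == "T03"],
               dev_share + 5 * 75 + 18 + 28 * 0.19)
  expect_equal(bd$intervention[bd$arm == "control"], c(0, 0))
  expect_equal(bd$total, rowSums(bd[, c("healthcare", "medication", "travel",
                                        "absenteeism", "presenteeism",
                                        "intervention")]))
})

test_that("missed waves carry the previous quarter's costs forward", {
  cfg <- cua_config()
  coh <- blank_cohort()
  coh$resource_use <- tibble::tibble(
    patient_id = "T01", wave_month = c(6, 9),
    category = "physical_therapist", count = c(5, 2)
  )
  coh <- drop_waves(coh, "T01", c(12, 15, 18))
  bd <- cost_breakdown(coh, cfg)
  # observed wave 9 contributes 2 x 40; waves 12/15/18 carry that quarter
  expect_equal(bd$healthcare[bd$patient_id == "T01"], 4 * 2 * 40)
  # patient observed at baseline only: annual costs carry the baseline quarter
  coh2 <- blank_cohort()
  coh2$resource_use <- tibble::tibble(
    patient_id = "T01", wave_month = 0,
    category = "rheumatologist", count = 1
  )
  coh2 <- drop_waves(coh2, "T01", c(6, 9, 12, 15, 18))
  bd2 <- cost_breakdown(coh2, cfg)
  expect_equal(bd2$healthcare[bd2$patient_id == "T01"], 4 * 91)
})

test_that("all-zero inputs give an all-zero breakdown", {
  bd <- cost_breakdown(blank_cohort(arms = c("control", "control")),
                       cua_config())
  expect_equal(bd$total, c(0, 0))
  expect_true(all(bd[, c("healthcare", "medication", "travel", "absenteeism",
                         "presenteeism", "intervention")] == 0))
})

test_that("totals are additive and exclusions consistent for all subsets", {
  coh <- generate_cohort(small_config(), seed = 5)
  bd <- cost_breakdown(coh, cua_config())
  cats <- c("healthcare", "medication", "travel", "absenteeism",
            "presenteeism", "intervention")
  expect_true(all(as.matrix(bd[, cats]) >= 0))
  expect_equal(bd$total, rowSums(bd[, cats]))
  for (k in 0:length(cats)) {
    for (s in utils::combn(cats, k, simplify = FALSE)) {
      excl <- total_excluding(bd, s)
      expect_equal(excl + rowSums(bd[, s, drop = FALSE]), bd$total,
                   tolerance = 1e-12)
    }
  }
  expect_error(total_excluding(bd, "transport"), "transport")
})

test_that("scaling all unit prices by k scales every cost output by k", {
  k <- 2.5
  cfg <- cua_config()
  cfg2 <- cfg
  cfg2$prices <- cfg$prices * k
  cfg2$medication_prices <- cfg$medication_prices * k
  cfg2$travel$km_rate <- cfg$travel$km_rate * k
  cfg2$friction$cost_per_hour <- cfg$friction$cost_per_hour * k
  im <- cfg$intervention_model
  for (f in c("development_cost", "therapist_rate_basic",
              "therapist_rate_postacademic", "assistant_rate", "km_rate")) {
    cfg2$intervention_model[[f]] <- im[[f]] * k
  }
  coh <- generate_cohort(small_config(), seed = 9)
  bd1 <- cost_breakdown(coh, cfg)
  bd2 <- cost_breakdown(coh, cfg2)
  for (col in c("healthcare", "medication", "travel", "absenteeism",
                "presenteeism", "intervention", "total")) {
    expect_equal(bd2[[col]], k * bd1[[col]], tolerance = 1e-12)
  }
})
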