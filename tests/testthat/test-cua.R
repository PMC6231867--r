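# Incremental analysis: point estimates, bootstrap, CE plane, CEAC.

make_arm_data <- function(qc, qi, cc, ci) {
  tibble::tibble(
    arm = rep(c("control", "intervention"), c(length(qc), length(qi))),
    qaly = c(qc, qi),
    cost = c(rep_len(cc, length(qc)), rep_len(ci, length(qi)))
  )
}

test_that("incremental point estimates and the ICUR", {
  p <- incremental_point_estimates(0.5, 0.6, 100, 150)
  expect_equal(p$d_qaly, 0.1)
  expect_equal(p$d_cost, 50)
  expect_equal(p$icur, 500)
  p <- incremental_point_estimates(c(0.5, 0.5), c(0.5, 0.5), 0, 10)
  expect_false(p$icur_defined)
  expect_true(is.na(p$icur))
  expect_error(incremental_point_estimates(numeric(), 1, 1, 1), "nonempty")
})

test_that("bootstrap keeps pairs intact, stratifies by arm, and is seeded", {
  d <- make_arm_data(c(0.5, 0.5, 0.5), c(0.7, 0.7), 100, c(300, 300))
  dr <- bootstrap_incrementals(d, replications = 50, seed = 1)
  # zero variance within arm: every replicate equals the point estimate
  expect_equal(dr$d_qaly, rep(0.2, 50))
  expect_equal(dr$d_cost, rep(200, 50))

  d2 <- make_arm_data(c(0.2, 0.9), c(0.4, 0.8), c(10, 50), c(20, 80))
  a <- bootstrap_incrementals(d2, replications = 100, seed = 7)
  b <- bootstrap_incrementals(d2, replications = 100, seed = 7)
  expect_identical(a, b)
  c <- bootstrap_incrementals(d2, replications = 100, seed = 8)
  expect_false(identical(a$d_qaly, c$d_qaly))
  expect_error(
    bootstrap_incrementals(make_arm_data(0.5, c(0.6, 0.7), 1, c(1, 2))),
    "at least 2")
})

test_that("bootstrap matches the exhaustive enumeration oracle", {
  qc <- c(0.5, 0.9); cc <- c(100, 300)
  qi <- c(0.6, 1.0); ci <- c(150, 450)
  # enumerate all ordered with-replacement resamples of each arm (2^2 each,
  # jointly 16 equally likely outcomes) for the replicate-level increments
  enum_means <- function(x) {
    idx <- expand.grid(1:2, 1:2)
    (x[idx[, 1]] + x[idx[, 2]]) / 2
  }
  dq <- outer(enum_means(qi), enum_means(qc), "-")
  dc <- outer(enum_means(ci), enum_means(cc), "-")
  e_dq <- mean(dq); v_dq <- mean(dq^2) - e_dq^2
  e_dc <- mean(dc); v_dc <- mean(dc^2) - e_dc^2

  dr <- bootstrap_incrementals(make_arm_data(qc, qi, cc, ci),
                               replications = 10000, seed = 42)
  R <- nrow(dr)
  expect_lt(abs(mean(dr$d_qaly) - e_dq), 3 * sqrt(v_dq / R))
  expect_lt(abs(mean(dr$d_cost) - e_dc), 3 * sqrt(v_dc / R))
  # variance of the empirical variance ~ 2 v^2 / R for near-normal draws;
  # allow a generous 4-SE band
  expect_lt(abs(var(dr$d_qaly) - v_dq), 4 * v_dq * sqrt(2 / R))
  expect_lt(abs(var(dr$d_cost) - v_dc), 4 * v_dc * sqrt(2 / R))
})

test_that("percentile intervals follow the documented rank rule", {
  draws <- sample(1:1000)
  # type-7: rank 1 + p (n - 1), linear interpolation between order stats
  expected <- function(p, x) {
    x <- sort(x); h <- 1 + p * (length(x) - 1)
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  ci <- percentile_interval(draws, c(2.5, 97.5))
  expect_equal(unname(ci), c(expected(0.025, draws), expected(0.975, draws)))
  expect_equal(unname(ci), c(25.975, 975.025))
  expect_equal(unname(percentile_interval(rep(3.3, 50))), c(3.3, 3.3))
  expect_equal(unname(percentile_interval(draws, c(0, 100))), c(1, 1000))
})

test_that("quadrant proportions classify and sum to one", {
  all_ne <- tibble::tibble(d_qaly = rep(0.1, 5), d_cost = rep(100, 5))
  expect_equal(quadrant_proportions(all_ne),
               c(NE = 1, SE = 0, NW = 0, SW = 0))
  # documented tie rules: zeros go to the adjacent worse quadrant
  ties <- tibble::tibble(d_qaly = c(0.1, 0, 0, -0.1),
                         d_cost = c(0, 5, -5, 0))
  expect_equal(quadrant_proportions(ties),
               c(NE = 0.5, SE = 0, NW = 0.25, SW = 0.25))
  set.seed(3)
  sym <- tibble::tibble(d_qaly = rnorm(20000), d_cost = rnorm(20000))
  qp <- quadrant_proportions(sym)
  expect_equal(sum(qp), 1)
  expect_true(all(abs(qp - 0.25) < 0.015))
})

test_that("CEAC endpoints reduce to sign probabilities", {
  set.seed(4)
  dr <- tibble::tibble(d_qaly = rnorm(500, 0.05, 0.1),
                       d_cost = rnorm(500, 200, 500))
  cv <- ceac(dr, wtp = c(0, 1000, 80000, 1e9))
  expect_equal(cv$probability[cv$wtp == 0], mean(dr$d_cost < 0))
  expect_equal(cv$probability[cv$wtp == 1e9], mean(dr$d_qaly > 0))
  expect_true(all(cv$probability >= 0 & cv$probability <= 1))
})

test_that("run_cua orchestrates analyses; exclusions leave effects alone", {
  set.seed(6)
  coh <- generate_cohort(small_config(), seed = 13)
  suppressWarnings(q <- cohort_qalys(coh))
  bd <- cost_breakdown(coh)
  primary <- run_cua(q, bd, analysis_config(bootstrap_replications = 400,
                                            seed = 99))
  secondary <- run_cua(q, bd, analysis_config(bootstrap_replications = 400,
                                              exclude = "medication",
                                              seed = 99))
  expect_identical(primary$d_qaly, secondary$d_qaly)
  expect_identical(primary$ci_d_qaly, secondary$ci_d_qaly)
  med <- bd$medication[match(q$patient_id, bd$patient_id)]
  d_med <- mean(med[q$arm == "intervention"]) - mean(med[q$arm == "control"])
  expect_equal(secondary$d_cost, primary$d_cost - d_med, tolerance = 1e-9)
  expect_equal(sum(primary$quadrants), 1)

  rerun <- run_cua(q, bd, analysis_config(bootstrap_replications = 400,
                                          seed = 99))
  expect_identical(primary$draws, rerun$draws)
  expect_identical(primary$ceac, rerun$ceac)
})

test_that("zero-variance cohorts give degenerate intervals", {
  q <- tibble::tibble(
    patient_id = sprintf("T%02d", 1:4),
    arm = c("control", "control", "intervention", "intervention"),
    qaly = c(0.5, 0.5, 0.6, 0.6)
  )
  bd <- tibble::tibble(
    patient_id = q$patient_id, arm = q$arm,
    healthcare = c(100, 100, 150, 150), medication = 0, travel = 0,
    absenteeism = 0, presenteeism = 0, intervention = 0,
    total = c(100, 100, 150, 150)
  )
  res <- run_cua(q, bd, analysis_config(bootstrap_replications = 100,
                                        seed = 1))
  expect_equal(unname(res$ci_d_qaly), c(0.1, 0.1))
  expect_equal(unname(res$ci_d_cost), c(50, 50))
  expect_equal(res$icur, 500)
  expect_equal(unname(res$quadrants["NE"]), 1)
})
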