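test_that("annual-to-monthly probability compounding is exact", {
  expect_equal(annual_to_monthly_prob(0), 0)
  expect_equal(annual_to_monthly_prob(0.05), 1 - 0.95^(1 / 12))
  expect_equal(annual_to_monthly_prob(0.05), 0.004265, tolerance = 1e-4)
  expect_equal(annual_to_monthly_prob(0.02), 0.001683, tolerance = 1e-3)
  for (q in c(0.001, 0.02, 0.3, 0.9)) {
    expect_equal(1 - (1 - annual_to_monthly_prob(q))^12, q, tolerance = 1e-12)
  }
  expect_error(annual_to_monthly_prob(1), "\\[0, 1\\)")
})

test_that("schedule anchors state mortality to life-table age and risk ratio", {
  lt <- flat_life_table(q = 0.024)
  params <- calibrated_params(1, 5, 0.02)
  sched <- build_schedule(params, lt, horizon_months = 60)
  expect_equal(sched$n_cycles, 57)
  # monthly mRS3-5 death probability = monthly general mortality x 5
  expect_equal(sched$d35[1], annual_to_monthly_prob(0.024) * 5,
               tolerance = 1e-12)
  expect_equal(sched$d35[1], 0.010112, tolerance = 1e-4)
  # recovery only while the destination month is inside the first year
  expect_equal(sum(sched$recover > 0), 9)
  expect_true(all(sched$recover[10:57] == 0))
  # rows stochastic
  rs <- apply(sched$mats, c(1, 3), sum)
  expect_equal(as.numeric(rs), rep(1, 3 * 57), tolerance = 1e-12)
})

test_that("null disease effect reproduces life-table survival exactly", {
  lt <- gen_life_table(0.02, 0.08, 75:90)
  sched <- build_schedule(calibrated_params(1, 1, 0), lt,
                          horizon_months = 60)
  tr <- run_cohort(mrs_distribution(0.376, 0.624, 0), sched)
  # the cohort enters at exactly age 75 in month 3; annual landmarks fall
  # at months 15, 27, 39, 51 and match cumulative life-table survival
  for (k in 1:4) {
    expected <- prod(1 - lt$qx[1:k])
    expect_equal(1 - tr$coarse[tr$months == 3 + 12 * k, "dead"],
                 c(dead = expected), tolerance = 1e-9)
  }
})

test_that("increasing disabled-state mortality lowers 5-year survival", {
  lt <- flat_life_table()
  surv5 <- function(rr35) {
    sched <- build_schedule(calibrated_params(1.5, rr35, 0.02), lt)
    tr <- run_cohort(base_init_control(), sched)
    1 - tr$coarse[58, "dead"]
  }
  s <- vapply(c(2, 4, 6, 8), surv5, numeric(1))
  expect_true(all(diff(s) < 0))
})

test_that("build_schedule names the cycle when mortality exceeds 1", {
  lt <- flat_life_table(q = 0.5)
  expect_error(
    build_schedule(calibrated_params(1, 19, 0), lt, horizon_months = 10),
    "cycle")
  expect_error(build_schedule(calibrated_params(1, 1, 0),
                              flat_life_table(ages = 75:76)),
               "does not cover")
})

test_that("calibration recovers known parameters from synthetic targets", {
  lt <- gen_life_table(0.018, 0.095, 75:81)
  init <- base_init_control()
  truth <- synthetic_truth(rr_mort_mrs02 = 1.5, rr_mort_mrs35 = 4.0,
                           p_recover_monthly = 0.02)
  targets <- gen_calibration_targets(truth, init, life_table = lt)
  fit <- calibrate(targets, lt, init)
  expect_equal(fit$rr_mort_mrs02, 1.5, tolerance = 0.01)
  expect_equal(fit$rr_mort_mrs35, 4.0, tolerance = 0.01)
  expect_equal(fit$p_recover_monthly, 0.02, tolerance = 0.01)
  expect_lt(attr(fit, "objective"), 1e-8)
})

test_that("null targets calibrate to unit risk ratios and no recovery", {
  lt <- gen_life_table(0.018, 0.095, 75:81)
  init <- base_init_control()
  truth <- synthetic_truth(1, 1, 0)
  targets <- gen_calibration_targets(truth, init, life_table = lt)
  fit <- calibrate(targets, lt, init)
  expect_equal(fit$rr_mort_mrs02, 1, tolerance = 0.01)
  expect_equal(fit$rr_mort_mrs35, 1, tolerance = 0.01)
  expect_equal(fit$p_recover_monthly, 0, tolerance = 0.01)
})

test_that("scaling all target weights leaves the fit unchanged", {
  lt <- gen_life_table(0.018, 0.095, 75:81)
  init <- base_init_control()
  targets <- gen_calibration_targets(synthetic_truth(2, 5, 0.015), init,
                                     life_table = lt)
  f1 <- calibrate(targets, lt, init, weights = 1)
  f2 <- calibrate(targets, lt, init, weights = 2)
  expect_equal(f1$rr_mort_mrs35, f2$rr_mort_mrs35, tolerance = 1e-4)
  expect_equal(f1$p_recover_monthly, f2$p_recover_monthly, tolerance = 1e-4)
})

test_that("a hopeless fit raises a calibration error carrying the best fit", {
  lt <- gen_life_table(0.018, 0.095, 75:81)
  init <- base_init_control()
  targets <- as_calibration_targets(data.frame(
    month = c(12, 24, 36), survival = c(0.9, 0.95, 0.99),  # rising survival
    p02_among_alive = c(0.3, 0.5, 0.9)))
  err <- tryCatch(calibrate(targets, lt, init, tol = 1e-10), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "tolerance")
  expect_s3_class(err$best, "calibrated_params")
  expect_s3_class(attr(err$best, "residuals"), "data.frame")
})

test_that("calibration refuses underdetermined target sets", {
  lt <- flat_life_table()
  expect_error(
    calibrate(data.frame(month = 12, survival = 0.9,
                         p02_among_alive = NA),
              lt, base_init_control()),
    "free parameters")
})

test_that("schedule extension tracks age-specific mortality only", {
  params <- calibrated_params(1.5, 4, 0.02)
  lt_flat <- flat_life_table(q = 0.024, ages = 75:95)
  sched <- build_schedule(params, lt_flat, horizon_months = 60)
  ext <- extend_schedule(params, sched, lt_flat, to_month = 120)
  expect_equal(ext$n_cycles, 117)
  expect_equal(ext$month_to[117], 120)
  # flat life table: extended death probabilities equal the fifth-year ones
  expect_equal(unique(ext$d35), unique(sched$d35))
  expect_true(all(ext$recover[58:117] == 0))
  # and the extension equals a direct build over the longer horizon
  direct <- build_schedule(params, lt_flat, horizon_months = 120)
  expect_equal(ext$mats, direct$mats, tolerance = 1e-15)
  expect_error(extend_schedule(params, sched, lt_flat, to_month = 60),
               "exceed")
  expect_error(extend_schedule(params, sched, flat_life_table(ages = 75:79),
                               to_month = 120),
               "too short")
})
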