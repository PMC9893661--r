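test_that("rehabilitation day counts in the surcharge windows", {
  # every day is a rehab day in the 7-day arm, any onset weekday
  for (w in ALL_WEEK) {
    expect_equal(rehab_days(rehab_pattern(ALL_WEEK, w)),
                 c(days_1_14 = 14, days_15_30 = 16))
  }
  # any 14-day window holds exactly 10 weekdays
  first <- vapply(ALL_WEEK, function(w) {
    rehab_days(rehab_pattern(MON_FRI, w))[["days_1_14"]]
  }, numeric(1))
  expect_true(all(first == 10))
  # the 16-day tail windows hold 80 weekdays over the 7 onsets
  tail16 <- vapply(ALL_WEEK, function(w) {
    rehab_days(rehab_pattern(MON_FRI, w))[["days_15_30"]]
  }, numeric(1))
  expect_equal(sum(tail16), 80)
})

test_that("acute cost reproduces the published per-arm values", {
  fees <- fee_schedule()
  cost7 <- acute_cost(rehab_pattern(ALL_WEEK, "Sun"), fees)
  expect_equal(cost7, 4.3 * (14 * 24.63 + 16 * 21.01), tolerance = 1e-12)
  expect_equal(round(cost7), 2928)
  cost5 <- expected_acute_cost(MON_FRI, fees)
  expect_equal(cost5, 4.3 * (10 * 24.63 + (80 / 7) * 21.01),
               tolerance = 1e-12)
  expect_equal(round(cost5), 2092)
  # zero fees cost nothing
  expect_equal(acute_cost(rehab_pattern(ALL_WEEK, "Mon"),
                          fee_schedule(0, 0, 0, 4.3)), 0)
})

test_that("acute cost is linear in units per day and in the fee vector", {
  f1 <- fee_schedule()
  f_unit <- fee_schedule(units_per_day = 1)
  f2 <- fee_schedule(18.6 * 2, 2.41 * 2, 3.62 * 2, 4.3)
  p <- rehab_pattern(ALL_WEEK, "Thu")
  expect_equal(acute_cost(p, f_unit), acute_cost(p, f1) / 4.3,
               tolerance = 1e-12)
  expect_equal(acute_cost(p, f2), 2 * acute_cost(p, f1), tolerance = 1e-12)
  expect_equal(expected_acute_cost(MON_FRI, f2),
               2 * expected_acute_cost(MON_FRI, f1), tolerance = 1e-12)
})

test_that("7-day cost ignores onset weekday; 5-day enumeration matches simulation", {
  fees <- fee_schedule()
  costs7 <- vapply(ALL_WEEK, function(w) {
    acute_cost(rehab_pattern(ALL_WEEK, w), fees)
  }, numeric(1))
  expect_equal(length(unique(costs7)), 1L)
  # seeded uniform-onset cohort agrees with exact enumeration
  onsets <- gen_onset_cohort(1000, seed = 11)
  sim <- mean(vapply(onsets, function(w) {
    acute_cost(rehab_pattern(MON_FRI, w), fees)
  }, numeric(1)))
  exact <- expected_acute_cost(MON_FRI, fees)
  per_day <- vapply(ALL_WEEK, function(w) {
    acute_cost(rehab_pattern(MON_FRI, w), fees)
  }, numeric(1))
  se <- stats::sd(per_day) / sqrt(1000)  # conservative SE of the mean
  expect_lt(abs(sim - exact), 4 * se + 1)
})

test_that("incremental acute cost matches the published delta", {
  fees <- fee_schedule()
  delta <- acute_cost(rehab_pattern(ALL_WEEK, "Sun"), fees) -
    expected_acute_cost(MON_FRI, fees)
  expect_equal(delta, 836.63, tolerance = 1e-4)
})

test_that("per-grade monthly long-term-care cost applies utilization and mix", {
  cfg <- base_case_config()
  map <- care_needs_map(cfg$costs$utilization, cfg$costs$care_level_mix)
  g <- monthly_ltc_cost_per_grade(map)
  expect_equal(g[["mRS0"]], 0)
  expect_equal(g[["mRS6"]], 0)
  expect_equal(g[["mRS1"]], 0.216 * 219, tolerance = 1e-9)
  expect_equal(g[["mRS4"]], 1.0 * (0.608 * 1090 + 0.392 * 1596),
               tolerance = 1e-9)
  expect_equal(g[["mRS4"]], 1288.35, tolerance = 1e-4)
  expect_equal(g[["mRS5"]], 0.610 * 1914 + 0.390 * 2205, tolerance = 1e-9)
})

test_that("care map validation rejects bad shares and nonzero edge grades", {
  cfg <- base_case_config()
  mix <- cfg$costs$care_level_mix
  mix$share[4] <- 0.9  # grade 4 shares no longer sum to 1
  expect_error(care_needs_map(cfg$costs$utilization, mix), "sum to 1")
  util <- cfg$costs$utilization
  util[1] <- 0.5
  expect_error(care_needs_map(util, cfg$costs$care_level_mix),
               "zero utilization")
})

test_that("long-term-care cost of a trace discounts monthly cashflows", {
  cfg <- base_case_config()
  map <- care_needs_map(cfg$costs$utilization, cfg$costs$care_level_mix)
  # static cohort fully at mRS4 for 12 undiscounted months
  sched <- transition_schedule(d02 = rep(0, 14), d35 = rep(0, 14),
                               recover = 0)
  tr <- run_cohort(mrs_distribution(0, 1, 0), sched)
  tr <- split_fine(tr, fine_split(c(1, 0, 0), c(0, 1, 0)))
  grade4 <- monthly_ltc_cost_per_grade(map)[["mRS4"]]
  cost <- ltc_cost_of_trace(tr, map, discount = 0, start_month = 4)
  expect_equal(cost, 14 * grade4, tolerance = 1e-9)
  # window restriction
  expect_equal(ltc_cost_of_trace(tr, map, discount = 0, start_month = 15),
               3 * grade4, tolerance = 1e-9)
  # discounting: single month-13 cashflow is scaled by 1.02^-1 vs month-1
  sched1 <- transition_schedule(d02 = 0, d35 = 0, recover = 0,
                                start_month = 12)
  tr1 <- split_fine(run_cohort(mrs_distribution(0, 1, 0), sched1),
                    fine_split(c(1, 0, 0), c(0, 1, 0)))
  c13 <- ltc_cost_of_trace(tr1, map, discount = 0.02, start_month = 13)
  expect_equal(c13, grade4 * 1.02^(-1), tolerance = 1e-9)
  # zero-cost map
  mix0 <- cfg$costs$care_level_mix
  mix0$monthly_cost <- 0
  map0 <- care_needs_map(cfg$costs$utilization, mix0)
  expect_equal(ltc_cost_of_trace(tr, map0), 0)
})

test_that("LTC cost falls as the cohort shifts toward independence", {
  cfg <- base_case_config()
  map <- care_needs_map(cfg$costs$utilization, cfg$costs$care_level_mix)
  sched <- transition_schedule(d02 = rep(0, 20), d35 = rep(0, 20),
                               recover = 0)
  cost_at <- function(p02) {
    tr <- split_fine(run_cohort(mrs_distribution(p02, 0.96 - p02, 0.04),
                                sched), fine_split())
    ltc_cost_of_trace(tr, map)
  }
  costs <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), cost_at, numeric(1))
  expect_true(all(diff(costs) < 0))
})

test_that("per-onset-day breakdown table is exported correctly", {
  tab <- acute_cost_breakdown(MON_FRI, fee_schedule())
  expect_named(tab, c("onset_weekday", "days_1_14", "days_15_30",
                      "cost_usd"))
  expect_equal(nrow(tab), 7)
  expect_equal(mean(tab$cost_usd), expected_acute_cost(MON_FRI,
                                                       fee_schedule()))
})
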