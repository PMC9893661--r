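test_that("fee and units bounds scale the healthcare ICER exactly", {
  cfg <- frozen_base_config()
  dsa <- run_dsa(cfg)
  base <- attr(dsa, "base")$icer_healthcare$value
  pick <- function(param, bound) {
    dsa$icer_healthcare[dsa$parameter == param & dsa$bound == bound]
  }
  expect_equal(pick("rehab_fees", "lower"), 0.5 * base, tolerance = 1e-9)
  expect_equal(pick("rehab_fees", "upper"), 2 * base, tolerance = 1e-9)
  expect_equal(pick("units_per_day", "lower"), base / 4.3,
               tolerance = 1e-9)
  expect_equal(pick("units_per_day", "upper"), base * 9 / 4.3,
               tolerance = 1e-9)
  # parameters that only touch LTC leave the healthcare ICER at base
  expect_equal(pick("ltc_fees", "lower"), base, tolerance = 1e-9)
  expect_equal(pick("ltc_utilization_rates", "upper"), base,
               tolerance = 1e-9)
})

test_that("a bound equal to the base value reproduces the base row", {
  cfg <- frozen_base_config()
  specs <- list(list(
    parameter = "identity",
    lower = function(config) config,
    upper = function(config) {
      config$costs$units_per_day <- 9
      config
    }))
  dsa <- run_dsa(cfg, specs)
  base <- attr(dsa, "base")$icer_healthcare$value
  expect_equal(dsa$icer_healthcare[dsa$bound == "lower"], base,
               tolerance = 1e-12)
})

test_that("an invalid bound yields a row-level error and the run continues", {
  cfg <- frozen_base_config()
  specs <- c(list(list(
    parameter = "broken",
    lower = function(config) {
      config$econ$discount_rate <- -1
      config
    },
    upper = function(config) config)),
    default_dsa_specs()[5])
  dsa <- run_dsa(cfg, specs)
  bad <- dsa[dsa$parameter == "broken" & dsa$bound == "lower", ]
  expect_true(is.na(bad$icer_healthcare))
  expect_match(bad$error, "discount_rate")
  expect_true(all(!is.na(dsa$icer_healthcare[dsa$parameter ==
                                               "rehab_fees"])))
})

test_that("full sensitivity grid keeps the intervention dominant from the combined perspective", {
  dsa <- run_dsa(frozen_base_config())
  expect_true(all(is.na(dsa$error)))
  expect_true(all(dsa$verdict_combined == "Dominant"))
  expect_true(all(dsa$delta_qaly > 0))
  expect_true(all(dsa$delta_total < 0))
})

test_that("PSA is bit-reproducible under a fixed seed", {
  cfg <- frozen_base_config()
  a <- run_psa(cfg, n_iterations = 25, seed = 7)
  b <- run_psa(cfg, n_iterations = 25, seed = 7)
  expect_identical(a$draws, b$draws)
  expect_identical(a$outcomes, b$outcomes)
  c <- run_psa(cfg, n_iterations = 25, seed = 8)
  expect_false(identical(a$draws, c$draws))
})

test_that("degenerate PSA (all variances zero) reproduces the base case", {
  cfg <- frozen_base_config()
  cfg$psa$rr_sd <- 0
  cfg$psa$units_sd <- 0
  cfg$psa$units_mean <- 4.3
  cfg$psa$rr_mean <- odds_ratio_to_risk_ratio(1.62, 0.376)
  cfg$psa$vary_utilities <- FALSE
  cfg$psa$vary_ltc_costs <- FALSE
  psa <- run_psa(cfg, n_iterations = 5, seed = 1)
  base <- run_cea(cfg)
  expect_equal(unique(psa$outcomes$delta_medical), base$delta_medical,
               tolerance = 1e-9)
  expect_equal(unique(psa$outcomes$delta_qaly), base$delta_qaly,
               tolerance = 1e-9)
  expect_equal(unique(psa$outcomes$icer_healthcare),
               base$icer_healthcare$value, tolerance = 1e-9)
})

test_that("utility draws follow their gamma distributions", {
  cfg <- frozen_base_config()
  psa <- run_psa(cfg, n_iterations = 1000, seed = 123)
  ut <- cfg$utilities
  # mRS0 mean = 61.0 / 68.5 within 3 standard errors (cap at 1 is rare)
  for (g in c(1, 2, 4)) {  # grades 0, 1, 3
    shape <- ut$gamma_shape[g]
    rate <- ut$gamma_rate[g]
    se <- sqrt(shape / rate^2) / sqrt(1000)
    expect_lt(abs(mean(psa$draws[[paste0("u_mRS", g - 1)]]) -
                    shape / rate),
              3 * se + 1e-3)
  }
  # the unit cap is applied at use and its frequency reported
  expect_equal(psa$summary$n_utility_capped,
               sum(psa$draws[paste0("u_mRS", 0:5)] > 1))
  expect_true(all(psa$draws$units_per_day > 0))
})

test_that("scenario analysis covers discounting and the 10-year horizon", {
  sc <- run_scenarios(frozen_base_config())
  expect_setequal(sc$scenario,
                  c("base", "discount_0pct", "discount_4pct",
                    "horizon_10yr"))
  base <- sc[sc$scenario == "base", ]
  # undiscounted QALYs dominate discounted ones, 4% discounts hardest
  expect_gte(sc$qaly_7day[sc$scenario == "discount_0pct"], base$qaly_7day)
  expect_lte(sc$qaly_7day[sc$scenario == "discount_4pct"], base$qaly_7day)
  expect_gt(sc$delta_qaly[sc$scenario == "discount_0pct"],
            sc$delta_qaly[sc$scenario == "discount_4pct"])
  # the longer horizon accrues more incremental QALYs, lowering the ICER
  h10 <- sc[sc$scenario == "horizon_10yr", ]
  expect_equal(h10$horizon_months, 120)
  expect_gt(h10$delta_qaly, base$delta_qaly)
  expect_lt(h10$icer_healthcare, base$icer_healthcare)
  # a horizon-60 re-run equals the base exactly
  again <- run_cea(frozen_base_config(), horizon_months = 60)
  expect_equal(again$icer_healthcare$value, base$icer_healthcare,
               tolerance = 1e-12)
})

test_that("plot helpers return ggplot objects", {
  skip_if_not_installed("ggplot2")
  cfg <- frozen_base_config()
  dsa <- run_dsa(cfg)
  psa <- run_psa(cfg, n_iterations = 20, seed = 2)
  expect_s3_class(plot_tornado(dsa), "ggplot")
  expect_s3_class(plot_ce_plane(psa, "combined"), "ggplot")
})
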