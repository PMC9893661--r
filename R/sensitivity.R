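# One-way deterministic sensitivity analysis (tornado), probabilistic
# sensitivity analysis with the published parameter distributions, and
# scenario runs (discount rate, 10-year horizon).

#' Default one-way sensitivity specifications
#'
#' The published ranges: intervention efficacy as explicit month-3
#' distributions (45.0/51.1/3.9 to 53.8/42.2/3.9), fine mRS splits pushed
#' to the best/worst single grade, long-term-care utilization rates +/-10%,
#' rehabilitation fees -50%/+100%, long-term-care fees -50%/+100%, and 1
#' vs 9 rehabilitation units per day.
#'
#' @return A list of DSA specs; each has `parameter`, `lower` and `upper`,
#'   the bounds being functions that modify a config.
#' @export
default_dsa_specs <- function() {
  set_in <- function(...) {
    keys <- list(...)
    function(config) {
      for (k in names(keys)) {
        parts <- strsplit(k, ".", fixed = TRUE)[[1]]
        config[[parts]] <- keys[[k]]
      }
      config
    }
  }
  list(
    list(parameter = "efficacy_initial_mrs02",
         lower = set_in("model.initial_7day" = c(0.450, 0.511, 0.039)),
         upper = set_in("model.initial_7day" = c(0.538, 0.422, 0.039))),
    list(parameter = "split_mrs35",
         lower = set_in("model.split35" = c(1, 0, 0)),
         upper = set_in("model.split35" = c(0, 0, 1))),
    list(parameter = "split_mrs02",
         lower = set_in("model.split02" = c(1, 0, 0)),
         upper = set_in("model.split02" = c(0, 0, 1))),
    list(parameter = "ltc_utilization_rates",
         lower = set_in("costs.utilization_multiplier" = 0.9),
         upper = set_in("costs.utilization_multiplier" = 1.1)),
    list(parameter = "rehab_fees",
         lower = set_in("costs.fee_multiplier" = 0.5),
         upper = set_in("costs.fee_multiplier" = 2)),
    list(parameter = "ltc_fees",
         lower = set_in("costs.ltc_fee_multiplier" = 0.5),
         upper = set_in("costs.ltc_fee_multiplier" = 2)),
    list(parameter = "units_per_day",
         lower = set_in("costs.units_per_day" = 1),
         upper = set_in("costs.units_per_day" = 9))
  )
}

dsa_row <- function(parameter, bound, res) {
  data.frame(
    parameter = parameter, bound = bound,
    icer_healthcare = res$icer_healthcare$value,
    verdict_healthcare = res$icer_healthcare$verdict,
    icer_combined = res$icer_combined$value,
    verdict_combined = res$icer_combined$verdict,
    delta_medical = res$delta_medical,
    delta_total = res$delta_total,
    delta_qaly = res$delta_qaly,
    error = NA_character_
  )
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the cost-utility analysis with one parameter at a time set to
#' its lower and upper bound, on the calibration frozen from the base
#' configuration. Rows are ordered by the healthcare-perspective ICER span
#' (tornado order); a bound producing an invalid configuration yields a
#' row-level error entry and the run continues.
#'
#' @param config A `cua_config`.
#' @param specs DSA specifications; default [default_dsa_specs()].
#' @return A `dsa_result` data frame (one row per spec per bound) with the
#'   base-case `cea_result` attached as attribute `base`.
#' @export
run_dsa <- function(config, specs = default_dsa_specs()) {
  config <- freeze_calibration(config)
  base <- run_cea(config)
  rows <- list()
  for (spec in specs) {
    for (bound in c("lower", "upper")) {
      rows[[length(rows) + 1]] <- tryCatch(
        dsa_row(spec$parameter, bound, run_cea(spec[[bound]](config))),
        error = function(e) {
          data.frame(parameter = spec$parameter, bound = bound,
                     icer_healthcare = NA_real_,
                     verdict_healthcare = NA_character_,
                     icer_combined = NA_real_,
                     verdict_combined = NA_character_,
                     delta_medical = NA_real_, delta_total = NA_real_,
                     delta_qaly = NA_real_, error = conditionMessage(e))
        })
    }
  }
  out <- do.call(rbind, rows)
  span <- vapply(split(out$icer_healthcare, out$parameter),
                 function(v) diff(range(v, na.rm = TRUE)), numeric(1))
  span[!is.finite(span)] <- -Inf
  out <- out[order(-span[out$parameter], out$parameter, out$bound), ]
  rownames(out) <- NULL
  attr(out, "base") <- base
  class(out) <- c("dsa_result", "data.frame")
  out
}

# draw n values from N(mean, sd), redrawing non-positive values
draw_positive_normal <- function(n, mean, sd, max_rounds = 100) {
  x <- stats::rnorm(n, mean, sd)
  redraws <- 0L
  for (i in seq_len(max_rounds)) {
    bad <- which(x <= 0)
    if (!length(bad)) break
    redraws <- redraws + length(bad)
    x[bad] <- stats::rnorm(length(bad), mean, sd)
  }
  if (any(x <= 0)) {
    stop("could not draw positive values from Normal(", mean, ", ", sd, ")",
         call. = FALSE)
  }
  attr(x, "redraws") <- redraws
  x
}

#' Probabilistic sensitivity analysis
#'
#' Draws, per iteration, the intervention risk ratio (Normal(1.31, 0.05),
#' clipped so the derived initial mRS0-2 proportion stays feasible), the
#' number of rehabilitation units per day (Normal(4.3, 1.0), redrawn if
#' non-positive), grade-wise QOL utilities (Gamma(shape, rate), capped at
#' 1) and care-level monthly long-term-care costs (Gamma(shape, rate)); all
#' draws independent. Each iteration rebuilds both arms on the frozen
#' calibrated schedule and records incremental outcomes; the summary
#' reports the percentage of iterations whose ICER falls below the
#' willingness-to-pay (dominant iterations count as below).
#'
#' @param config A `cua_config`.
#' @param n_iterations Number of iterations; default from the config (1000).
#' @param seed Integer seed; default `config$seed`. Identical seed and
#'   config give identical output.
#' @return A `psa_result`: list with `draws` and `outcomes` data frames
#'   (one row per iteration), `summary` (percent below WTP per
#'   perspective, truncation counts) and the base `cea_result`.
#' @export
run_psa <- function(config, n_iterations = NULL, seed = NULL) {
  config <- freeze_calibration(config)
  base <- run_cea(config)
  cp <- config$psa
  n <- if (is.null(n_iterations)) cp$n_iterations else n_iterations
  if (is.null(seed)) seed <- config$seed
  cm <- config$model
  cc <- config$costs

  life_table <- resolve_life_table(config)
  params <- do.call(calibrated_params, as.list(config$calibration$params))
  schedule <- build_schedule(params, life_table, start_age = cm$start_age,
                             horizon_months = cm$horizon_months,
                             recovery_window_months =
                               cm$recovery_window_months,
                             start_month = cm$start_month)
  split <- fine_split(cm$split02, cm$split35)
  init_control <- control_initial(config)
  trace_control <- split_fine(run_cohort(init_control, schedule), split)
  r <- config$econ$discount_rate
  m0 <- config$econ$accrue_from_month
  wtp_usd <- convert_wtp(config$econ$wtp_jpy, config$econ$exchange_rate,
                         round_usd = FALSE)
  rr_max <- (1 - cm$p_dead_initial) / cm$control_p02
  ut <- config$utilities
  mix <- cc$care_level_mix

  set.seed(seed)
  rr_raw <- stats::rnorm(n, cp$rr_mean, cp$rr_sd)
  rr <- pmin(pmax(rr_raw, 1e-9), rr_max)
  units <- draw_positive_normal(n, cp$units_mean, cp$units_sd)
  vary_u <- !isFALSE(cp$vary_utilities)
  vary_c <- !isFALSE(cp$vary_ltc_costs)
  # raw gamma draws are recorded; the unit cap is applied (and counted)
  # where a draw is used as a utility weight
  u_draw <- matrix(rep(ut$utility[1:6], each = n), n, 6)
  if (vary_u) {
    for (g in 1:6) {
      u_draw[, g] <- stats::rgamma(n, shape = ut$gamma_shape[g],
                                   rate = ut$gamma_rate[g])
    }
  }
  colnames(u_draw) <- paste0("u_mRS", 0:5)
  n_utility_capped <- sum(u_draw > 1)
  cost_draw <- matrix(rep(mix$monthly_cost, each = n), n, nrow(mix))
  if (vary_c) {
    for (j in seq_len(nrow(mix))) {
      cost_draw[, j] <- stats::rgamma(n, shape = mix$gamma_shape[j],
                                      rate = mix$gamma_rate[j])
    }
  }
  colnames(cost_draw) <- paste0("cost_", gsub(" ", "", mix$level))

  util_base <- pmin(1, cc$utilization * cc$utilization_multiplier)
  util_base[c(1, 7)] <- 0
  out <- vector("list", n)
  for (i in seq_len(n)) {
    fees <- fee_schedule(cc$base_fee_per_unit * cc$fee_multiplier,
                         cc$surcharge_30d_per_unit * cc$fee_multiplier,
                         cc$surcharge_14d_per_unit * cc$fee_multiplier,
                         units[i])
    init7 <- derive_initial_distribution(cm$control_p02, rr[i],
                                         cm$p_dead_initial)
    tr7 <- split_fine(run_cohort(init7, schedule), split)
    grade_cost <- stats::setNames(numeric(7), paste0("mRS", 0:6))
    mixed <- tapply(mix$share * cost_draw[i, ] * cc$ltc_fee_multiplier,
                    mix$grade, sum)
    grade_cost[paste0("mRS", names(mixed))] <- as.numeric(mixed)
    grade_cost <- grade_cost * util_base
    u_vec <- c(pmin(1, u_draw[i, ]), 0)

    acute7 <- expected_acute_cost(cc$pattern_7day, fees,
                                  cc$rehab_duration_days)
    acute5 <- expected_acute_cost(cc$pattern_control, fees,
                                  cc$rehab_duration_days)
    ltc_of <- function(tr) {
      keep <- tr$months >= m0
      monthly <- as.numeric(tr$fine[keep, , drop = FALSE] %*% grade_cost)
      sum(monthly * discount_factor(tr$months[keep], r))
    }
    q_of <- function(tr) {
      keep <- tr$months >= m0
      u <- as.numeric(tr$fine[keep, , drop = FALSE] %*% u_vec)
      sum(u * discount_factor(tr$months[keep], r)) / 12
    }
    d_med <- acute7 - acute5
    d_ltc <- ltc_of(tr7) - ltc_of(trace_control)
    d_q <- q_of(tr7) - q_of(trace_control)
    ic_h <- icer(d_med, d_q)
    ic_c <- icer(d_med + d_ltc, d_q)
    out[[i]] <- c(delta_medical = d_med, delta_ltc = d_ltc,
                  delta_total = d_med + d_ltc, delta_qaly = d_q,
                  icer_healthcare = ic_h$value, icer_combined = ic_c$value,
                  below_wtp_healthcare = icer_below_wtp(ic_h, wtp_usd),
                  below_wtp_combined = icer_below_wtp(ic_c, wtp_usd))
  }
  outcomes <- as.data.frame(do.call(rbind, out))
  outcomes$iteration <- seq_len(n)
  verdict_of <- function(d_cost, d_q) {
    vapply(seq_along(d_cost),
           function(i) icer(d_cost[i], d_q[i])$verdict, character(1))
  }
  outcomes$verdict_healthcare <- verdict_of(outcomes$delta_medical,
                                            outcomes$delta_qaly)
  outcomes$verdict_combined <- verdict_of(outcomes$delta_total,
                                          outcomes$delta_qaly)
  draws <- data.frame(iteration = seq_len(n), risk_ratio = rr,
                      units_per_day = units, u_draw, cost_draw)
  structure(
    list(draws = draws, outcomes = outcomes,
         summary = list(
           n_iterations = n, seed = seed, wtp_usd = wtp_usd,
           pct_below_wtp_healthcare =
             100 * mean(outcomes$below_wtp_healthcare),
           pct_below_wtp_combined = 100 * mean(outcomes$below_wtp_combined),
           n_rr_clipped = sum(rr_raw != rr),
           n_utility_capped = n_utility_capped,
           n_units_redrawn = attr(units, "redraws")),
         base = base),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  s <- x$summary
  cat("Probabilistic sensitivity analysis:", s$n_iterations,
      "iterations (seed", paste0(s$seed, ")\n"))
  cat(sprintf("  below WTP ($%0.0f/QALY): healthcare %.1f%% | combined %.1f%%\n",
              s$wtp_usd, s$pct_below_wtp_healthcare,
              s$pct_below_wtp_combined))
  cat("  risk-ratio draws clipped:", s$n_rr_clipped,
      "| units/day redraws:", s$n_units_redrawn, "\n")
  invisible(x)
}

#' Scenario analysis: discount rate and time horizon
#'
#' Re-runs the cost-utility analysis at 0% and 4% annual discounting and
#' over a 10-year (120-month) horizon, alongside the base case, on the
#' frozen calibration. Beyond month 60 the transition schedule reuses the
#' fifth-year parameters with death probabilities tracking attained-age
#' life-table mortality.
#'
#' @param config A `cua_config`.
#' @return A `scenario_result` data frame, one row per scenario.
#' @export
run_scenarios <- function(config) {
  config <- freeze_calibration(config)
  scenarios <- list(
    list(name = "base", mod = identity),
    list(name = "discount_0pct",
         mod = function(cfg) { cfg$econ$discount_rate <- 0; cfg }),
    list(name = "discount_4pct",
         mod = function(cfg) { cfg$econ$discount_rate <- 0.04; cfg }),
    list(name = "horizon_10yr",
         mod = function(cfg) { cfg$model$horizon_months <- 120; cfg })
  )
  rows <- lapply(scenarios, function(sc) {
    cfg <- sc$mod(config)
    res <- run_cea(cfg)
    data.frame(
      scenario = sc$name,
      discount_rate = cfg$econ$discount_rate,
      horizon_months = cfg$model$horizon_months,
      qaly_7day = res$arms$seven_day$qalys,
      qaly_control = res$arms$control$qalys,
      delta_qaly = res$delta_qaly,
      delta_medical = res$delta_medical,
      delta_total = res$delta_total,
      icer_healthcare = res$icer_healthcare$value,
      verdict_healthcare = res$icer_healthcare$verdict,
      icer_combined = res$icer_combined$value,
      verdict_combined = res$icer_combined$verdict
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("scenario_result", "data.frame")
  out
}

#' Tornado plot of one-way sensitivity results
#'
#' @param dsa A `dsa_result` from [run_dsa()].
#' @param perspective `"healthcare"` or `"combined"`.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_tornado <- function(dsa, perspective = c("healthcare", "combined")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_tornado requires ggplot2", call. = FALSE)
  }
  perspective <- match.arg(perspective)
  col <- paste0("icer_", perspective)
  base <- attr(dsa, "base")[[paste0("icer_", perspective)]]$value
  d <- dsa[!is.na(dsa[[col]]), ]
  d$parameter <- factor(d$parameter, levels = rev(unique(d$parameter)))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$parameter, x = .data[[col]],
                                  fill = .data$bound)) +
    ggplot2::geom_col(position = "identity", alpha = 0.7) +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(x = "ICER (USD/QALY)", y = NULL,
                  title = paste("One-way sensitivity,", perspective,
                                "perspective"))
}

#' Cost-effectiveness plane from PSA iterations
#'
#' @param psa A `psa_result` from [run_psa()].
#' @param perspective `"healthcare"` or `"combined"`.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_ce_plane <- function(psa, perspective = c("healthcare", "combined")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_ce_plane requires ggplot2", call. = FALSE)
  }
  perspective <- match.arg(perspective)
  ycol <- if (perspective == "healthcare") "delta_medical" else "delta_total"
  wtp <- psa$summary$wtp_usd
  ggplot2::ggplot(psa$outcomes,
                  ggplot2::aes(x = .data$delta_qaly, y = .data[[ycol]])) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)",
                  title = paste("CE plane,", perspective, "perspective"))
}
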