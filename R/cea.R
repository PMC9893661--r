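# Utility weighting, QALY accrual, perspectives and incremental results.

#' QOL utility table by mRS grade
#'
#' @param utility Numeric length 7: QALY weight per grade mRS0-mRS6
#'   (mRS6 = 0; weakly decreasing in grade).
#' @param gamma_shape,gamma_rate Gamma distribution parameters per grade for
#'   probabilistic sensitivity analysis (`NA` for mRS6). The gamma mean
#'   `shape/rate` must sit within 0.01 of the point utility.
#' @return A `utility_table` data frame (grades 0-6).
#' @export
utility_table <- function(utility, gamma_shape = NA_real_,
                          gamma_rate = NA_real_) {
  stopifnot(length(utility) == 7, all(utility >= 0), all(utility <= 1))
  if (utility[7] != 0) stop("utility_table: mRS6 utility must be 0",
                            call. = FALSE)
  if (any(diff(utility) > 1e-12)) {
    stop("utility_table: utilities must be weakly decreasing in grade",
         call. = FALSE)
  }
  gamma_shape <- rep_len(gamma_shape, 7)
  gamma_rate <- rep_len(gamma_rate, 7)
  m <- gamma_shape / gamma_rate
  off <- which(!is.na(m) & abs(m - utility) > 0.01)
  if (length(off)) {
    stop("utility_table: gamma mean differs from point utility by > 0.01 ",
         "at grade(s) ", paste(off - 1, collapse = ", "), call. = FALSE)
  }
  structure(data.frame(grade = 0:6, utility = utility,
                       gamma_shape = gamma_shape, gamma_rate = gamma_rate),
            class = c("utility_table", "data.frame"))
}

#' Discounted QALYs of a cohort trace
#'
#' Each calendar month from `start_month` onward contributes 1/12 of a year
#' weighted by the occupancy-weighted utility and the annual discount rate
#' (`(1 + r)^(-(m - 1)/12)`).
#'
#' @param trace A `cohort_trace` with fine occupancies attached.
#' @param utilities A [utility_table].
#' @param discount Annual discount rate. Default 0.02.
#' @param start_month First accrual month. Default 4.
#' @return QALYs (numeric scalar).
#' @export
qalys_of_trace <- function(trace, utilities, discount = 0.02,
                           start_month = 4) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (is.null(trace$fine)) {
    stop("qalys_of_trace: attach fine occupancies with split_fine() first",
         call. = FALSE)
  }
  keep <- trace$months >= start_month
  if (!any(keep)) return(0)
  u <- as.numeric(trace$fine[keep, , drop = FALSE] %*% utilities$utility)
  sum(u * discount_factor(trace$months[keep], discount)) / 12
}

#' Incremental cost-effectiveness ratio with dominance verdict
#'
#' @param delta_cost Incremental cost (USD; intervention minus comparator).
#' @param delta_qaly Incremental QALYs.
#' @return A list with `value` (USD/QALY, `NA` when not a ratio) and
#'   `verdict`: `"value"` when the ratio is meaningful, `"Dominant"`
#'   (cheaper and more effective), `"Dominated"` (costlier and less
#'   effective) or `"Undefined"` (no QALY difference).
#' @examples
#' icer(-1524, 0.132) # Dominant
#' icer(836, 0.132)
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0) {
    list(value = NA_real_, verdict = "Undefined")
  } else if (delta_cost < 0 && delta_qaly > 0) {
    list(value = delta_cost / delta_qaly, verdict = "Dominant")
  } else if (delta_cost > 0 && delta_qaly < 0) {
    list(value = delta_cost / delta_qaly, verdict = "Dominated")
  } else {
    list(value = delta_cost / delta_qaly, verdict = "value")
  }
}

#' Convert a willingness-to-pay threshold from JPY to USD
#'
#' @param wtp_jpy Threshold in JPY per QALY (default 5,000,000).
#' @param rate Exchange rate in JPY per USD (default 131.88).
#' @param round_usd Round to whole dollars for reporting (default `TRUE`).
#' @return Threshold in USD/QALY.
#' @examples
#' convert_wtp() # 37913
#' @export
convert_wtp <- function(wtp_jpy = 5e6, rate = 131.88, round_usd = TRUE) {
  stopifnot(rate > 0)
  usd <- wtp_jpy / rate
  if (round_usd) round(usd) else usd
}

# is an ICER outcome acceptable at a WTP threshold (Dominant counts as
# below; Dominated / Undefined do not)
icer_below_wtp <- function(ic, wtp_usd) {
  switch(ic$verdict,
         Dominant = TRUE,
         Dominated = FALSE,
         Undefined = FALSE,
         value = ic$value <= wtp_usd)
}

# Shared machinery: resolve the calibrated schedule and both arms' traces
# from a validated config. Returns list(schedule, traces, initials, params).
build_model <- function(config, horizon_months = NULL) {
  cm <- config$model
  life_table <- resolve_life_table(config)
  params <- resolve_calibration(config, life_table)
  horizon <- if (is.null(horizon_months)) cm$horizon_months else
    horizon_months
  schedule <- build_schedule(
    params, life_table, start_age = cm$start_age,
    horizon_months = horizon,
    recovery_window_months = cm$recovery_window_months,
    start_month = cm$start_month
  )
  rr <- effective_risk_ratio(config)
  init_control <- mrs_distribution(cm$control_p02,
                                   1 - cm$control_p02 - cm$p_dead_initial,
                                   cm$p_dead_initial)
  init_7day <- if (!is.null(cm$initial_7day)) {
    # printed triples can sum to 99.9%; renormalise like the fine splits
    v <- cm$initial_7day / sum(cm$initial_7day)
    do.call(mrs_distribution, as.list(unname(v)))
  } else {
    derive_initial_distribution(cm$control_p02, rr, cm$p_dead_initial)
  }
  split <- fine_split(cm$split02, cm$split35)
  traces <- list(
    seven_day = split_fine(run_cohort(init_7day, schedule), split),
    control = split_fine(run_cohort(init_control, schedule), split)
  )
  list(schedule = schedule, traces = traces, params = params,
       initials = list(seven_day = init_7day, control = init_control),
       life_table = life_table)
}

effective_risk_ratio <- function(config) {
  cm <- config$model
  if (!is.null(cm$risk_ratio)) cm$risk_ratio else
    odds_ratio_to_risk_ratio(cm$odds_ratio, cm$control_p02)
}

config_fees <- function(config) {
  cc <- config$costs
  fee_schedule(cc$base_fee_per_unit * cc$fee_multiplier,
               cc$surcharge_30d_per_unit * cc$fee_multiplier,
               cc$surcharge_14d_per_unit * cc$fee_multiplier,
               cc$units_per_day)
}

config_care_map <- function(config) {
  cc <- config$costs
  mix <- cc$care_level_mix
  mix$monthly_cost <- mix$monthly_cost * cc$ltc_fee_multiplier
  util <- pmin(1, cc$utilization * cc$utilization_multiplier)
  util[c(1, 7)] <- 0
  care_needs_map(util, mix)
}

config_utilities <- function(config) {
  u <- config$utilities
  utility_table(u$utility, u$gamma_shape, u$gamma_rate)
}

#' Run the base-case cost-utility analysis
#'
#' Builds both arms on the shared calibrated transition schedule (the arms
#' differ only in initial mRS distribution and acute rehabilitation
#' calendar), computes discounted costs and QALYs, and reports incremental
#' results under the public-healthcare perspective (medical costs only) and
#' the combined healthcare plus long-term-care perspective.
#'
#' @param config A validated configuration, e.g. [base_case_config()] or
#'   [load_config()].
#' @param horizon_months Optional horizon override (calendar months since
#'   onset).
#' @return A `cea_result` list: per-arm `arms` (acute medical cost,
#'   long-term-care cost, total cost, QALYs), deltas, `icer_healthcare`,
#'   `icer_combined`, the WTP threshold in USD, and run metadata.
#' @examples
#' \donttest{
#' res <- run_cea(base_case_config())
#' res
#' }
#' @export
run_cea <- function(config, horizon_months = NULL) {
  config <- validate_config(config)
  model <- build_model(config, horizon_months)
  fees <- config_fees(config)
  map <- config_care_map(config)
  utilities <- config_utilities(config)
  r <- config$econ$discount_rate
  m0 <- config$econ$accrue_from_month

  arm <- function(trace, weekdays) {
    acute <- expected_acute_cost(weekdays, fees,
                                 config$costs$rehab_duration_days)
    ltc <- ltc_cost_of_trace(trace, map, r, m0)
    q <- qalys_of_trace(trace, utilities, r, m0)
    list(acute_medical_cost = acute, ltc_cost = ltc,
         total_cost = acute + ltc, qalys = q)
  }
  arms <- list(
    seven_day = arm(model$traces$seven_day, config$costs$pattern_7day),
    control = arm(model$traces$control, config$costs$pattern_control)
  )
  d_med <- arms$seven_day$acute_medical_cost - arms$control$acute_medical_cost
  d_ltc <- arms$seven_day$ltc_cost - arms$control$ltc_cost
  d_tot <- arms$seven_day$total_cost - arms$control$total_cost
  d_q <- arms$seven_day$qalys - arms$control$qalys
  wtp_usd <- convert_wtp(config$econ$wtp_jpy, config$econ$exchange_rate,
                         round_usd = FALSE)
  structure(
    list(arms = arms,
         delta_medical = d_med, delta_ltc = d_ltc, delta_total = d_tot,
         delta_qaly = d_q,
         icer_healthcare = icer(d_med, d_q),
         icer_combined = icer(d_tot, d_q),
         wtp_usd = wtp_usd,
         calibration = model$params,
         meta = list(config_hash = config_hash(config),
                     seed = config$seed,
                     horizon_months = if (is.null(horizon_months))
                       config$model$horizon_months else horizon_months,
                     discount_rate = r,
                     package_version =
                       as.character(utils::packageVersion("rehabcua")))),
    class = "cea_result"
  )
}

fmt_icer <- function(ic) {
  if (ic$verdict == "value") paste0("$", round(ic$value), "/QALY") else
    ic$verdict
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-utility analysis: 7-days/week vs 5-/6-days/week acute stroke",
      "rehabilitation\n")
  row <- function(label, a) {
    cat(sprintf("  %-18s medical $%8.0f | LTC $%8.0f | total $%8.0f | %.3f QALY\n",
                label, a$acute_medical_cost, a$ltc_cost, a$total_cost,
                a$qalys))
  }
  row("7-day schedule:", x$arms$seven_day)
  row("5-/6-day schedule:", x$arms$control)
  cat(sprintf("  increments:        medical $%8.0f | LTC $%8.0f | total $%8.0f | %.3f QALY\n",
              x$delta_medical, x$delta_ltc, x$delta_total, x$delta_qaly))
  cat("  ICER, healthcare perspective:", fmt_icer(x$icer_healthcare), "\n")
  cat("  ICER, healthcare + long-term-care perspective:",
      fmt_icer(x$icer_combined), "\n")
  cat("  willingness-to-pay:", paste0("$", round(x$wtp_usd), "/QALY"), "\n")
  invisible(x)
}

#' Serialise a CEA result to JSON
#'
#' @param result A `cea_result`.
#' @param path Optional output file.
#' @return The JSON string, invisibly when written to file.
#' @export
cea_result_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "cea_result"))
  obj <- list(
    arms = result$arms,
    delta = list(medical = result$delta_medical, ltc = result$delta_ltc,
                 total = result$delta_total, qaly = result$delta_qaly),
    icer = list(
      healthcare = result$icer_healthcare,
      combined = result$icer_combined
    ),
    wtp_usd = result$wtp_usd,
    calibration = unclass(result$calibration)[
      c("rr_mort_mrs02", "rr_mort_mrs35", "p_recover_monthly",
        "p_worsen_monthly")],
    meta = result$meta
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
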