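# Run configuration: base-case defaults, YAML loading, schema validation.
# Every printed model input is a config key and can be overridden.

#' Base-case model configuration
#'
#' The complete default configuration of the cost-utility analysis: month-3
#' mRS distributions (control arm 37.6/58.5/3.9%; intervention arm derived
#' from the adjusted odds ratio 1.62), fine mRS splits, the national fee
#' schedule (USD 18.6 per unit, +2.41 days 1-30, +3.62 days 1-14, 4.3
#' units/day), the care-needs mapping with utilization rates and monthly
#' costs, QOL utilities with gamma parameters, a 2%/year discount rate,
#' 60-month horizon and the 5,000,000 JPY/QALY willingness-to-pay at
#' 131.88 JPY/USD.
#'
#' @return A `cua_config` list with blocks `model`, `paths`, `calibration`,
#'   `costs`, `utilities`, `econ`, `psa` and a top-level `seed`.
#' @examples
#' cfg <- base_case_config()
#' cfg$costs$units_per_day
#' @export
base_case_config <- function() {
  cfg <- list(
    model = list(
      control_p02 = 0.376,
      odds_ratio = 1.62,
      risk_ratio = NULL,      # derived from odds_ratio unless set
      initial_7day = NULL,    # explicit intervention initial (DSA override)
      p_dead_initial = 0.039,
      split02 = c(0.305, 0.298, 0.396),
      split35 = c(0.375, 0.369, 0.256),
      start_age = 75,
      start_month = 3,
      horizon_months = 60,
      recovery_window_months = 12
    ),
    paths = list(
      life_table = NULL,            # NULL = packaged synthetic life table
      calibration_targets = NULL    # NULL = packaged synthetic targets
    ),
    calibration = list(
      params = NULL,                # set to skip calibration entirely
      rr_bounds = c(1, 20),
      p_bounds = c(0, 0.2),
      grid_points = 10,
      tie_ratios = FALSE,
      tol = 0.01
    ),
    costs = list(
      base_fee_per_unit = 18.6,
      surcharge_30d_per_unit = 2.41,
      surcharge_14d_per_unit = 3.62,
      units_per_day = 4.3,
      rehab_duration_days = 30,
      pattern_7day = c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat"),
      pattern_control = c("Mon", "Tue", "Wed", "Thu", "Fri"),
      fee_multiplier = 1,
      ltc_fee_multiplier = 1,
      utilization_multiplier = 1,
      utilization = c(0, 0.216, 0.915, 0.985, 1, 1, 0),
      care_level_mix = data.frame(
        grade = c(1, 2, 3, 4, 4, 5, 5),
        level = c("Support 1", "Support 2", "Care 1", "Care 2", "Care 3",
                  "Care 4", "Care 5"),
        share = c(1, 1, 1, 0.608, 0.392, 0.610, 0.390),
        monthly_cost = c(219, 376, 806, 1090, 1596, 1914, 2205),
        gamma_shape = c(34.5, 36.4, 167.2, 306.1, 655.6, 517.3, 686.3),
        gamma_rate = c(0.2, 0.1, 0.2, 0.2, 0.4, 0.3, 0.3)
      )
    ),
    utilities = data.frame(
      grade = 0:6,
      utility = c(0.89, 0.797, 0.65, 0.588, 0.363, 0.092, 0),
      gamma_shape = c(61.0, 90.0, 77.1, 77.0, 24.7, 1.32, NA),
      gamma_rate = c(68.5, 113.0, 118.7, 131.0, 68.1, 14.4, NA)
    ),
    econ = list(
      discount_rate = 0.02,
      wtp_jpy = 5e6,
      exchange_rate = 131.88,
      accrue_from_month = 4
    ),
    psa = list(
      n_iterations = 1000,
      rr_mean = 1.31,
      rr_sd = 0.05,
      units_mean = 4.3,
      units_sd = 1.0,
      vary_utilities = TRUE,
      vary_ltc_costs = TRUE
    ),
    seed = 1L
  )
  structure(cfg, class = "cua_config")
}

#' Validate a configuration
#'
#' Checks every block against the schema (types, bounds, share sums);
#' errors name the offending key.
#'
#' @param config A configuration list.
#' @return The config, with class `cua_config`, invisibly usable downstream.
#' @export
validate_config <- function(config) {
  chk <- function(ok, key, what) {
    if (!isTRUE(ok)) {
      stop("config validation: '", key, "' ", what, call. = FALSE)
    }
  }
  cm <- config$model
  chk(is.numeric(cm$control_p02) && cm$control_p02 > 0 && cm$control_p02 < 1,
      "model.control_p02", "must be a probability in (0, 1)")
  chk(is.numeric(cm$p_dead_initial) && cm$p_dead_initial >= 0 &&
        cm$p_dead_initial < 1,
      "model.p_dead_initial", "must be a probability in [0, 1)")
  chk(is.null(cm$odds_ratio) || cm$odds_ratio > 0, "model.odds_ratio",
      "must be > 0")
  chk(is.null(cm$risk_ratio) || cm$risk_ratio > 0, "model.risk_ratio",
      "must be > 0")
  chk(!is.null(cm$odds_ratio) || !is.null(cm$risk_ratio),
      "model.odds_ratio", "or model.risk_ratio must be supplied")
  chk(length(cm$split02) == 3 && all(cm$split02 >= 0) && sum(cm$split02) > 0,
      "model.split02", "must be 3 nonnegative proportions")
  chk(length(cm$split35) == 3 && all(cm$split35 >= 0) && sum(cm$split35) > 0,
      "model.split35", "must be 3 nonnegative proportions")
  chk(cm$horizon_months > cm$start_month, "model.horizon_months",
      "must exceed model.start_month")
  chk(cm$recovery_window_months >= 0, "model.recovery_window_months",
      "must be >= 0")
  chk(cm$start_age >= 0, "model.start_age", "must be >= 0")
  if (!is.null(cm$initial_7day)) {
    chk(length(cm$initial_7day) == 3 && all(cm$initial_7day >= 0) &&
          abs(sum(cm$initial_7day) - 1) < 0.005,
        "model.initial_7day",
        "must be 3 probabilities summing to 1 (rounding slack 0.005)")
  }
  cc <- config$costs
  for (key in c("base_fee_per_unit", "surcharge_30d_per_unit",
                "surcharge_14d_per_unit")) {
    chk(is.numeric(cc[[key]]) && cc[[key]] >= 0, paste0("costs.", key),
        "must be >= 0")
  }
  chk(cc$units_per_day > 0, "costs.units_per_day", "must be > 0")
  chk(cc$rehab_duration_days >= 1, "costs.rehab_duration_days",
      "must be >= 1")
  chk(all(cc$pattern_7day %in% WEEKDAYS) && length(cc$pattern_7day) >= 1,
      "costs.pattern_7day", "must be a subset of Sun..Sat")
  chk(all(cc$pattern_control %in% WEEKDAYS) &&
        length(cc$pattern_control) >= 1,
      "costs.pattern_control", "must be a subset of Sun..Sat")
  for (key in c("fee_multiplier", "ltc_fee_multiplier",
                "utilization_multiplier")) {
    chk(is.numeric(cc[[key]]) && cc[[key]] >= 0, paste0("costs.", key),
        "must be >= 0")
  }
  chk(length(cc$utilization) == 7 && all(cc$utilization >= 0) &&
        all(cc$utilization <= 1),
      "costs.utilization", "must be 7 probabilities")
  ce <- config$econ
  chk(is.numeric(ce$discount_rate) && ce$discount_rate >= 0,
      "econ.discount_rate", "must be >= 0")
  chk(ce$wtp_jpy >= 0, "econ.wtp_jpy", "must be >= 0")
  chk(ce$exchange_rate > 0, "econ.exchange_rate", "must be > 0")
  chk(ce$accrue_from_month >= 1, "econ.accrue_from_month", "must be >= 1")
  cp <- config$psa
  chk(cp$n_iterations >= 1, "psa.n_iterations", "must be >= 1")
  chk(cp$rr_sd >= 0, "psa.rr_sd", "must be >= 0")
  chk(cp$units_sd >= 0, "psa.units_sd", "must be >= 0")
  chk(cp$units_mean > 0, "psa.units_mean", "must be > 0")
  # constructors re-validate utilities / care map in depth
  config_utilities(config)
  config_care_map(config)
  structure(config, class = "cua_config")
}

config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "seed")])
}

resolve_life_table <- function(config) {
  p <- config$paths$life_table
  if (is.null(p) || identical(p, "packaged")) {
    p <- system.file("extdata", "life_table_synthetic.csv",
                     package = "rehabcua", mustWork = TRUE)
  }
  read_life_table(p)
}

resolve_calibration <- function(config, life_table) {
  cal <- config$calibration
  if (!is.null(cal$params)) {
    return(do.call(calibrated_params, as.list(cal$params)))
  }
  p <- config$paths$calibration_targets
  targets <- if (is.null(p) || identical(p, "packaged")) {
    read_calibration_targets(system.file(
      "extdata", "calibration_targets_synthetic.csv",
      package = "rehabcua", mustWork = TRUE))
  } else if (identical(p, "synthetic")) {
    truth <- synthetic_truth()
    gen_calibration_targets(truth, control_initial(config),
                            life_table = life_table)
  } else {
    read_calibration_targets(p)
  }
  calibrate(targets, life_table, control_initial(config),
            start_age = config$model$start_age,
            recovery_window_months = config$model$recovery_window_months,
            start_month = config$model$start_month,
            rr_bounds = cal$rr_bounds, p_bounds = cal$p_bounds,
            grid_points = cal$grid_points, tie_ratios = cal$tie_ratios,
            tol = cal$tol)
}

control_initial <- function(config) {
  cm <- config$model
  mrs_distribution(cm$control_p02, 1 - cm$control_p02 - cm$p_dead_initial,
                   cm$p_dead_initial)
}

#' Freeze the calibration into a configuration
#'
#' Runs the calibration once (if not already fixed) and stores the fitted
#' parameters in `config$calibration$params`, so repeated [run_cea()] calls
#' (sensitivity analysis, scenario runs) reuse them instead of refitting.
#'
#' @param config A `cua_config`.
#' @return The config with `calibration$params` set.
#' @export
freeze_calibration <- function(config) {
  config <- validate_config(config)
  if (is.null(config$calibration$params)) {
    life_table <- resolve_life_table(config)
    p <- resolve_calibration(config, life_table)
    config$calibration$params <- list(
      rr_mort_mrs02 = p$rr_mort_mrs02, rr_mort_mrs35 = p$rr_mort_mrs35,
      p_recover_monthly = p$p_recover_monthly,
      p_worsen_monthly = p$p_worsen_monthly)
  }
  config
}

# deep merge `override` into `defaults`, rejecting unknown keys;
# data-frame-backed blocks accept column lists or row records
merge_config <- function(defaults, override, path = "") {
  if (is.null(override)) return(defaults)
  if (is.list(override) && length(override) == 0) return(defaults)
  if (is.data.frame(defaults)) return(coerce_df(defaults, override, path))
  if (!is.list(defaults) || !is.list(override) || is.null(names(override))) {
    return(override)
  }
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    stop("config validation: unknown key(s) ",
         paste0("'", sub("^\\.", "", paste0(path, ".", unknown)), "'",
                collapse = ", "), call. = FALSE)
  }
  for (nm in names(override)) {
    # `[nm] <- list(...)` keeps keys whose merged value is NULL
    defaults[nm] <- list(merge_config(defaults[[nm]], override[[nm]],
                                      paste0(path, ".", nm)))
  }
  defaults
}

coerce_df <- function(template, value, path) {
  if (is.data.frame(value)) return(value)
  if (!is.list(value)) {
    stop("config validation: '", sub("^\\.", "", path),
         "' must be a table (list of columns or of rows)", call. = FALSE)
  }
  if (!is.null(names(value)) && all(names(value) %in% names(template))) {
    value <- lapply(value, function(col) {
      col[vapply(col, is.null, logical(1))] <- NA
      unlist(col)
    })
    return(as.data.frame(value))
  }
  rows <- lapply(value, function(r) as.data.frame(r, check.names = FALSE))
  do.call(rbind, rows)
}

#' Load a configuration from YAML (or JSON)
#'
#' Reads the file, deep-merges it over [base_case_config()] (so an empty
#' file yields the full base case), rejects unknown keys and validates the
#' result.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A validated `cua_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  cfg <- merge_config(base_case_config(), raw)
  validate_config(cfg)
}

#' Write a configuration to YAML
#'
#' @param config A `cua_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly. `load_config(dump_config(x))` is semantically
#'   identical to `x`.
#' @export
dump_config <- function(config, path) {
  to_plain <- function(x) {
    if (is.data.frame(x)) return(lapply(as.list(x), unname))
    if (is.list(x)) return(lapply(x, to_plain))
    if (is.null(x)) return(NULL)
    unname(x)
  }
  yaml::write_yaml(to_plain(unclass(config)), path)
  invisible(path)
}
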