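# Acute-stage rehabilitation fee arithmetic (Japanese national fee
# schedule, USD-converted) and long-term-care costing from fine mRS
# occupancy via the care-needs-level mapping.

WEEKDAYS <- c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")

#' Rehabilitation fee schedule
#'
#' Per-unit fee for a 20-minute rehabilitation unit, with the additional
#' per-unit surcharge chargeable during the first 30 days after onset and
#' the further surcharge during the first 14 days.
#'
#' @param base_fee_per_unit Base fee per unit (USD). Default 18.6.
#' @param surcharge_30d_per_unit Surcharge for onset-days 1-30. Default 2.41.
#' @param surcharge_14d_per_unit Surcharge for onset-days 1-14. Default 3.62.
#' @param units_per_day Rehabilitation units delivered per rehab day.
#'   Default 4.3.
#' @return A `fee_schedule` list.
#' @export
fee_schedule <- function(base_fee_per_unit = 18.6,
                         surcharge_30d_per_unit = 2.41,
                         surcharge_14d_per_unit = 3.62,
                         units_per_day = 4.3) {
  stopifnot(base_fee_per_unit >= 0, surcharge_30d_per_unit >= 0,
            surcharge_14d_per_unit >= 0, units_per_day > 0)
  structure(list(base_fee_per_unit = base_fee_per_unit,
                 surcharge_30d_per_unit = surcharge_30d_per_unit,
                 surcharge_14d_per_unit = surcharge_14d_per_unit,
                 units_per_day = units_per_day),
            class = "fee_schedule")
}

#' Weekly rehabilitation calendar
#'
#' @param rehab_weekdays Character subset of
#'   `c("Sun","Mon","Tue","Wed","Thu","Fri","Sat")` on which rehabilitation
#'   is delivered (all seven for the 7-day arm, Mon-Fri for the
#'   conventional arm).
#' @param onset_weekday Weekday of stroke onset (day 1 of the chargeable
#'   window).
#' @param duration_days Length of the acute rehabilitation period.
#'   Default 30.
#' @return A `rehab_pattern` list.
#' @export
rehab_pattern <- function(rehab_weekdays, onset_weekday = "Sun",
                          duration_days = 30) {
  rehab_weekdays <- match.arg(rehab_weekdays, WEEKDAYS, several.ok = TRUE)
  onset_weekday <- match.arg(onset_weekday, WEEKDAYS)
  stopifnot(duration_days >= 1)
  structure(list(rehab_weekdays = rehab_weekdays,
                 onset_weekday = onset_weekday,
                 duration_days = as.integer(duration_days)),
            class = "rehab_pattern")
}

#' Count rehabilitation days in the surcharge windows
#'
#' Day 1 is the onset day. Returns the number of delivered rehabilitation
#' days falling in onset-days 1-14 (both surcharges apply) and in
#' onset-days 15 to `duration_days` (30-day surcharge only).
#'
#' @param pattern A [rehab_pattern].
#' @return Named integer vector `c(days_1_14 = , days_15_30 = )`.
#' @examples
#' rehab_days(rehab_pattern(c("Mon", "Tue", "Wed", "Thu", "Fri"), "Wed"))
#' @export
rehab_days <- function(pattern) {
  stopifnot(inherits(pattern, "rehab_pattern"))
  onset_idx <- match(pattern$onset_weekday, WEEKDAYS)
  days <- seq_len(pattern$duration_days)
  wday <- WEEKDAYS[((onset_idx - 1 + days - 1) %% 7) + 1]
  is_rehab <- wday %in% pattern$rehab_weekdays
  c(days_1_14 = sum(is_rehab & days <= 14),
    days_15_30 = sum(is_rehab & days > 14))
}

#' Acute-stage rehabilitation cost for one onset weekday
#'
#' `units_per_day * (n_days_1_14 * (base + s30 + s14) +
#'  n_days_15_30 * (base + s30))`.
#'
#' @param pattern A [rehab_pattern].
#' @param fees A [fee_schedule].
#' @return Cost in USD (unrounded).
#' @examples
#' acute_cost(rehab_pattern(c("Sun","Mon","Tue","Wed","Thu","Fri","Sat")),
#'            fee_schedule()) # ~2928
#' @export
acute_cost <- function(pattern, fees) {
  stopifnot(inherits(fees, "fee_schedule"))
  n <- rehab_days(pattern)
  full <- fees$base_fee_per_unit + fees$surcharge_30d_per_unit +
    fees$surcharge_14d_per_unit
  late <- fees$base_fee_per_unit + fees$surcharge_30d_per_unit
  fees$units_per_day * (n[["days_1_14"]] * full + n[["days_15_30"]] * late)
}

#' Expected acute cost over a uniform random onset weekday
#'
#' The day of onset is equiprobable over Sunday-Saturday; the expected cost
#' is the arithmetic mean of [acute_cost()] over the seven onset weekdays.
#'
#' @param rehab_weekdays Weekday subset on which rehabilitation is
#'   delivered.
#' @param fees A [fee_schedule].
#' @param duration_days Acute rehabilitation period. Default 30.
#' @return Expected cost in USD (unrounded).
#' @examples
#' expected_acute_cost(c("Mon","Tue","Wed","Thu","Fri"), fee_schedule())
#' @export
expected_acute_cost <- function(rehab_weekdays, fees, duration_days = 30) {
  costs <- vapply(
    WEEKDAYS,
    function(w) acute_cost(rehab_pattern(rehab_weekdays, w, duration_days),
                           fees),
    numeric(1)
  )
  mean(costs)
}

#' Per-onset-weekday acute cost breakdown
#'
#' @inheritParams expected_acute_cost
#' @return Data frame `onset_weekday, days_1_14, days_15_30, cost_usd`.
#' @export
acute_cost_breakdown <- function(rehab_weekdays, fees, duration_days = 30) {
  rows <- lapply(WEEKDAYS, function(w) {
    p <- rehab_pattern(rehab_weekdays, w, duration_days)
    n <- rehab_days(p)
    data.frame(onset_weekday = w, days_1_14 = n[["days_1_14"]],
               days_15_30 = n[["days_15_30"]], cost_usd = acute_cost(p, fees))
  })
  do.call(rbind, rows)
}

#' Care-needs mapping from mRS grade to long-term-care cost
#'
#' Maps each mRS grade 0-6 to a utilization rate of public long-term-care
#' services and a mix of care-needs levels with monthly costs (USD) and
#' gamma distribution parameters for probabilistic sensitivity analysis.
#' mRS0 and mRS6 incur no long-term-care cost.
#'
#' @param utilization Named numeric of length 7 (grades 0-6): probability
#'   of utilising long-term-care services.
#' @param level_mix Data frame with columns `grade`, `level`, `share`,
#'   `monthly_cost`, `gamma_shape`, `gamma_rate`; shares within a grade sum
#'   to 1.
#' @return A `care_needs_map` list.
#' @export
care_needs_map <- function(utilization, level_mix) {
  stopifnot(length(utilization) == 7, all(utilization >= 0),
            all(utilization <= 1))
  req <- c("grade", "level", "share", "monthly_cost")
  if (!all(req %in% names(level_mix))) {
    stop("level_mix needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(level_mix$share >= 0), all(level_mix$monthly_cost >= 0))
  shares <- tapply(level_mix$share, level_mix$grade, sum)
  if (any(abs(shares - 1) > 1e-9)) {
    stop("care_needs_map: care-level shares within a grade must sum to 1",
         call. = FALSE)
  }
  names(utilization) <- paste0("mRS", 0:6)
  if (utilization[["mRS0"]] != 0 || utilization[["mRS6"]] != 0) {
    stop("care_needs_map: mRS0 and mRS6 must have zero utilization",
         call. = FALSE)
  }
  structure(list(utilization = utilization, level_mix = level_mix),
            class = "care_needs_map")
}

#' Expected monthly long-term-care cost per mRS grade
#'
#' Grade cost = utilization rate times the share-weighted mean of the
#' grade's care-level monthly costs.
#'
#' @param map A [care_needs_map].
#' @return Named numeric vector of length 7 (USD/month, grades mRS0-mRS6).
#' @export
monthly_ltc_cost_per_grade <- function(map) {
  stopifnot(inherits(map, "care_needs_map"))
  cost <- stats::setNames(numeric(7), paste0("mRS", 0:6))
  mixed <- tapply(map$level_mix$share * map$level_mix$monthly_cost,
                  map$level_mix$grade, sum)
  cost[paste0("mRS", names(mixed))] <- as.numeric(mixed)
  cost * map$utilization
}

# discount factor for a cashflow in calendar month m (month 1 undiscounted)
discount_factor <- function(month, annual_rate) {
  (1 + annual_rate)^(-(month - 1) / 12)
}

#' Discounted long-term-care cost of a cohort trace
#'
#' Sums, over calendar months from `start_month` to the end of the trace,
#' the fine-grade occupancy times the grade's expected monthly
#' long-term-care cost, discounted at `discount` per year
#' (`(1 + r)^(-(m - 1)/12)` for a month-`m` cashflow).
#'
#' @param trace A `cohort_trace` with fine occupancies attached.
#' @param map A [care_needs_map].
#' @param discount Annual discount rate. Default 0.02.
#' @param start_month First month of long-term-care accrual. Default 4.
#' @return Discounted cost in USD.
#' @export
ltc_cost_of_trace <- function(trace, map, discount = 0.02, start_month = 4) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (is.null(trace$fine)) {
    stop("ltc_cost_of_trace: attach fine occupancies with split_fine() first",
         call. = FALSE)
  }
  keep <- trace$months >= start_month
  if (!any(keep)) return(0)
  grade_cost <- monthly_ltc_cost_per_grade(map)
  monthly <- as.numeric(trace$fine[keep, , drop = FALSE] %*% grade_cost)
  sum(monthly * discount_factor(trace$months[keep], discount))
}
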