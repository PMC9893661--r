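# Life-table-anchored transition probabilities: state-specific mortality
# risk ratios and a first-year recovery probability, fitted by least-squares
# calibration against landmark survival / independence targets.

#' Convert an annual death probability to a monthly one
#'
#' `q_month = 1 - (1 - q_annual)^(1/12)`, so that compounding twelve monthly
#' cycles reproduces the annual probability exactly.
#'
#' @param q_annual Annual death probability in `[0, 1)`.
#' @return Monthly death probability.
#' @examples
#' annual_to_monthly_prob(0.05)
#' @export
annual_to_monthly_prob <- function(q_annual) {
  if (any(!is.finite(q_annual)) || any(q_annual < 0) || any(q_annual >= 1)) {
    stop("annual_to_monthly_prob: q_annual must lie in [0, 1)", call. = FALSE)
  }
  1 - (1 - q_annual)^(1 / 12)
}

#' Read a life table from CSV
#'
#' Expects columns `age` (integer years, strictly increasing and contiguous)
#' and `qx` (annual death probability in `[0, 1)`).
#'
#' @param path CSV file path.
#' @return A `life_table` data frame.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) {
    stop("life table file not found: ", path, call. = FALSE)
  }
  as_life_table(utils::read.csv(path))
}

#' @rdname read_life_table
#' @param x A data frame with `age` and `qx` columns.
#' @export
as_life_table <- function(x) {
  if (!all(c("age", "qx") %in% names(x))) {
    stop("life table needs columns 'age' and 'qx'", call. = FALSE)
  }
  x <- x[order(x$age), c("age", "qx")]
  if (any(diff(x$age) != 1)) {
    stop("life table ages must be contiguous integer years", call. = FALSE)
  }
  if (any(!is.finite(x$qx)) || any(x$qx < 0) || any(x$qx >= 1)) {
    stop("life table qx must lie in [0, 1)", call. = FALSE)
  }
  structure(x, class = c("life_table", "data.frame"))
}

life_table_q <- function(life_table, ages) {
  idx <- match(ages, life_table$age)
  if (anyNA(idx)) {
    stop("life table does not cover age(s) ",
         paste(unique(ages[is.na(idx)]), collapse = ", "),
         " needed by the model horizon", call. = FALSE)
  }
  life_table$qx[idx]
}

#' Calibrated transition parameters
#'
#' Bundle of the free parameters governing transitions: mortality risk
#' ratios multiplying general-population monthly mortality in each living
#' state, the monthly first-year recovery probability (mRS3-5 -> mRS0-2)
#' and an optional monthly worsening probability (default 0).
#'
#' @param rr_mort_mrs02 Mortality risk ratio for the independent state.
#' @param rr_mort_mrs35 Mortality risk ratio for the disabled state.
#' @param p_recover_monthly Monthly recovery probability inside the window.
#' @param p_worsen_monthly Monthly worsening probability (default 0).
#' @return A `calibrated_params` list.
#' @export
calibrated_params <- function(rr_mort_mrs02, rr_mort_mrs35,
                              p_recover_monthly, p_worsen_monthly = 0) {
  stopifnot(rr_mort_mrs02 >= 0, rr_mort_mrs35 >= 0,
            p_recover_monthly >= 0, p_recover_monthly <= 1,
            p_worsen_monthly >= 0, p_worsen_monthly <= 1)
  structure(list(rr_mort_mrs02 = rr_mort_mrs02,
                 rr_mort_mrs35 = rr_mort_mrs35,
                 p_recover_monthly = p_recover_monthly,
                 p_worsen_monthly = p_worsen_monthly),
            class = "calibrated_params")
}

#' Build the monthly transition schedule from calibrated parameters
#'
#' For each monthly cycle, the death probability from each living state is
#' the general-population monthly mortality at the cohort's attained age
#' multiplied by the state's mortality risk ratio. The cohort enters the
#' model aged `start_age` at `start_month` months after onset; attained age
#' advances by one year every 12 cycles. Recovery (mRS3-5 -> mRS0-2) is
#' permitted only for cycles whose destination month does not exceed
#' `recovery_window_months`.
#'
#' @param params A [calibrated_params] object.
#' @param life_table A `life_table` covering the needed ages.
#' @param start_age Age (years) at model entry. Default 75.
#' @param horizon_months Calendar month (since onset) at which the trace
#'   ends. Default 60 (five-year horizon).
#' @param recovery_window_months Last calendar month (since onset) into
#'   which recovery transitions are allowed. Default 12.
#' @param start_month Calendar month of model entry. Default 3.
#' @return A [transition_schedule] with
#'   `horizon_months - start_month` cycles.
#' @export
build_schedule <- function(params, life_table, start_age = 75,
                           horizon_months = 60, recovery_window_months = 12,
                           start_month = 3) {
  stopifnot(inherits(params, "calibrated_params"),
            horizon_months > start_month)
  n <- horizon_months - start_month
  ages <- start_age + (seq_len(n) - 1) %/% 12
  q_month <- annual_to_monthly_prob(life_table_q(life_table, ages))
  d02 <- q_month * params$rr_mort_mrs02
  d35 <- q_month * params$rr_mort_mrs35
  over <- which(d02 > 1 | d35 > 1)
  if (length(over)) {
    stop("build_schedule: risk ratio times monthly mortality exceeds 1 at ",
         "cycle ", over[1], " (transition month ", start_month + over[1] - 1,
         " -> ", start_month + over[1], ", age ", ages[over[1]], ")",
         call. = FALSE)
  }
  dest_month <- start_month + seq_len(n)
  recover <- ifelse(dest_month <= recovery_window_months,
                    params$p_recover_monthly, 0)
  transition_schedule(d02, d35, recover, params$p_worsen_monthly,
                      start_month = start_month)
}

#' Extend a transition schedule beyond its horizon
#'
#' Appends cycles up to `to_month`, reusing the final year's non-mortality
#' parameters (recovery is already zero outside the first-year window) while
#' death probabilities continue to track attained-age life-table mortality
#' times the same state-specific risk ratios.
#'
#' @param params The [calibrated_params] used to build `schedule`.
#' @param schedule The existing [transition_schedule].
#' @param life_table A `life_table` covering the extended ages.
#' @param to_month New horizon (calendar months since onset).
#' @param start_age Age at model entry (must match the original build).
#' @return A [transition_schedule] spanning `start_month` to `to_month`.
#' @export
extend_schedule <- function(params, schedule, life_table, to_month,
                            start_age = 75) {
  stopifnot(inherits(schedule, "transition_schedule"))
  old_horizon <- schedule$month_to[schedule$n_cycles]
  if (to_month <= old_horizon) {
    stop("extend_schedule: to_month (", to_month,
         ") must exceed the current horizon (", old_horizon, ")",
         call. = FALSE)
  }
  start_month <- schedule$start_month
  n <- to_month - start_month
  extra <- (schedule$n_cycles + 1):n
  ages <- start_age + (extra - 1) %/% 12
  if (!all(ages %in% life_table$age)) {
    stop("extend_schedule: life table too short for extension to month ",
         to_month, " (needs age ", max(ages), ")", call. = FALSE)
  }
  q_month <- annual_to_monthly_prob(life_table_q(life_table, ages))
  transition_schedule(
    d02 = c(schedule$d02, q_month * params$rr_mort_mrs02),
    d35 = c(schedule$d35, q_month * params$rr_mort_mrs35),
    recover = c(schedule$recover, rep(0, length(extra))),
    worsen = c(schedule$worsen, rep(params$p_worsen_monthly, length(extra))),
    start_month = start_month
  )
}

#' Read calibration targets from CSV
#'
#' Expects columns `month` (calendar months since onset), `survival`
#' (probability of being alive) and optionally `p02_among_alive` (proportion
#' functionally independent among survivors; blanks allowed).
#'
#' @param path CSV file path.
#' @return A `calibration_targets` data frame.
#' @export
read_calibration_targets <- function(path) {
  if (!file.exists(path)) {
    stop("calibration targets file not found: ", path, call. = FALSE)
  }
  as_calibration_targets(utils::read.csv(path))
}

#' @rdname read_calibration_targets
#' @param x Data frame with the target columns.
#' @export
as_calibration_targets <- function(x) {
  if (!all(c("month", "survival") %in% names(x))) {
    stop("calibration targets need columns 'month' and 'survival'",
         call. = FALSE)
  }
  if (is.null(x$p02_among_alive)) x$p02_among_alive <- NA_real_
  x <- x[order(x$month), c("month", "survival", "p02_among_alive")]
  ok <- function(p) is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok(x$survival)) || !all(ok(x$p02_among_alive))) {
    stop("calibration target probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  structure(x, class = c("calibration_targets", "data.frame"))
}

# Model-predicted (survival, p02-among-alive) at the target months for a
# parameter vector, using the control-arm initial distribution.
predict_targets <- function(par, targets, life_table, initial, start_age,
                            recovery_window_months, start_month) {
  params <- calibrated_params(par[1], par[2], par[3],
                              if (length(par) >= 4) par[4] else 0)
  horizon <- max(targets$month)
  sched <- build_schedule(params, life_table, start_age = start_age,
                          horizon_months = horizon,
                          recovery_window_months = recovery_window_months,
                          start_month = start_month)
  tr <- run_cohort(initial, sched)
  idx <- match(targets$month, tr$months)
  if (anyNA(idx)) {
    stop("calibration target month(s) outside the model trace", call. = FALSE)
  }
  alive <- 1 - tr$coarse[idx, 3]
  data.frame(month = targets$month, survival = alive,
             p02_among_alive = ifelse(alive > 0,
                                      tr$coarse[idx, 1] / alive, 0))
}

calibration_sse <- function(par, targets, life_table, initial, start_age,
                            recovery_window_months, start_month, weights) {
  pred <- predict_targets(par, targets, life_table, initial, start_age,
                          recovery_window_months, start_month)
  res <- c(pred$survival - targets$survival,
           pred$p02_among_alive - targets$p02_among_alive)
  w <- rep(weights, 2)
  sum(w * res^2, na.rm = TRUE)
}

#' Calibrate transition parameters to landmark targets
#'
#' Fits the mortality risk ratios and the monthly recovery probability by
#' unweighted least squares on the target rows (survival at each landmark
#' month, and independence-among-survivors where given). The optimiser is a
#' deterministic coarse grid over the parameter bounds followed by
#' derivative-free Nelder-Mead refinement on box-transformed coordinates.
#'
#' @param targets A `calibration_targets` object.
#' @param life_table A `life_table`.
#' @param initial The [mrs_distribution] at model entry (control arm).
#' @param start_age Age at entry. Default 75.
#' @param recovery_window_months Recovery window. Default 12.
#' @param start_month Model entry month. Default 3.
#' @param rr_bounds Bounds for both mortality risk ratios. Default `c(1, 20)`.
#' @param p_bounds Bounds for the recovery probability. Default `c(0, 0.2)`.
#' @param grid_points Grid resolution per dimension. Default 10.
#' @param tie_ratios If `TRUE`, force the two mortality ratios equal.
#' @param weights Optional per-row weights (scaling all weights leaves the
#'   argmin unchanged). Default 1.
#' @param tol Acceptable residual sum of squares; the fit errors out (with
#'   the best-found parameters and residuals attached to the condition) if
#'   the optimiser cannot reduce the objective below `tol`. Default 0.01,
#'   i.e. a root-mean-square landmark residual of a few percent — loose
#'   enough for hand-transcribed targets that no parameter vector fits
#'   exactly, tight enough to catch a failed fit.
#' @param must_converge Raise an error on poor fit (default `TRUE`).
#' @return A [calibrated_params] object with attributes `objective`
#'   (residual sum of squares) and `residuals`.
#' @export
calibrate <- function(targets, life_table, initial, start_age = 75,
                      recovery_window_months = 12, start_month = 3,
                      rr_bounds = c(1, 20), p_bounds = c(0, 0.2),
                      grid_points = 10, tie_ratios = FALSE, weights = 1,
                      tol = 0.01, must_converge = TRUE) {
  targets <- as_calibration_targets(targets)
  n_info <- sum(!is.na(targets$survival)) +
    sum(!is.na(targets$p02_among_alive))
  n_free <- if (tie_ratios) 2L else 3L
  if (nrow(targets) == 0 || n_info < n_free) {
    stop("calibrate: need at least as many target values (", n_info,
         ") as free parameters (", n_free, ")", call. = FALSE)
  }
  weights <- rep_len(weights, nrow(targets))
  obj3 <- function(par) {
    calibration_sse(par, targets, life_table, initial, start_age,
                    recovery_window_months, start_month, weights)
  }
  obj <- if (tie_ratios) function(p) obj3(c(p[1], p[1], p[2])) else obj3

  rr_grid <- seq(rr_bounds[1], rr_bounds[2], length.out = grid_points)
  p_grid <- seq(p_bounds[1], p_bounds[2], length.out = grid_points)
  grid <- if (tie_ratios) {
    expand.grid(rr = rr_grid, p = p_grid)
  } else {
    expand.grid(rr02 = rr_grid, rr35 = rr_grid, p = p_grid)
  }
  vals <- apply(as.matrix(grid), 1, obj)
  best <- as.numeric(grid[which.min(vals), ])

  # box transform: optimise unconstrained z with par = lo + (hi-lo)*plogis(z)
  lo <- c(rep(rr_bounds[1], if (tie_ratios) 1 else 2), p_bounds[1])
  hi <- c(rep(rr_bounds[2], if (tie_ratios) 1 else 2), p_bounds[2])
  to_z <- function(par) {
    # keep the start strictly interior: a boundary grid point would put the
    # logistic transform in its saturated tail and stall Nelder-Mead
    f <- pmin(pmax((par - lo) / (hi - lo), 0.02), 0.98)
    stats::qlogis(f)
  }
  from_z <- function(z) lo + (hi - lo) * stats::plogis(z)
  fit <- stats::optim(to_z(best), function(z) obj(from_z(z)),
                      method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  # one restart from the refined point guards against premature collapse
  fit2 <- stats::optim(fit$par, function(z) obj(from_z(z)),
                       method = "Nelder-Mead",
                       control = list(maxit = 4000, reltol = 1e-12))
  if (fit2$value < fit$value) fit <- fit2
  par <- from_z(fit$par)
  if (tie_ratios) par <- c(par[1], par[1], par[2])

  pred <- predict_targets(par, targets, life_table, initial, start_age,
                          recovery_window_months, start_month)
  residuals <- data.frame(
    month = targets$month,
    survival = pred$survival - targets$survival,
    p02_among_alive = pred$p02_among_alive - targets$p02_among_alive
  )
  out <- calibrated_params(par[1], par[2], par[3])
  attr(out, "objective") <- fit$value
  attr(out, "residuals") <- residuals
  if (must_converge && fit$value > tol) {
    cond <- simpleError(paste0(
      "calibrate: optimiser left residual sum of squares ",
      format(fit$value, digits = 4), " above tolerance; best parameters (",
      paste(signif(par, 4), collapse = ", "),
      ") attached to the condition as 'best'"))
    cond$best <- out
    stop(cond)
  }
  out
}

#' @export
print.calibrated_params <- function(x, ...) {
  cat("Calibrated transition parameters\n")
  cat("  mortality risk ratio, mRS0-2:", signif(x$rr_mort_mrs02, 5), "\n")
  cat("  mortality risk ratio, mRS3-5:", signif(x$rr_mort_mrs35, 5), "\n")
  cat("  monthly recovery probability:", signif(x$p_recover_monthly, 5), "\n")
  if (x$p_worsen_monthly > 0) {
    cat("  monthly worsening probability:", signif(x$p_worsen_monthly, 5),
        "\n")
  }
  if (!is.null(attr(x, "objective"))) {
    cat("  calibration objective (RSS):",
        format(attr(x, "objective"), digits = 4), "\n")
  }
  invisible(x)
}
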