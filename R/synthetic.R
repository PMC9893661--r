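# Synthetic input generators: Gompertz life tables, forward-model
# calibration targets from known ground-truth parameters, and random onset
# cohorts. Everything the pipeline consumes can be generated here, which
# also makes the calibration testable by parameter recovery.

#' Ground-truth parameters for synthetic target generation
#'
#' @param rr_mort_mrs02,rr_mort_mrs35 Mortality risk ratios.
#' @param p_recover_monthly,p_worsen_monthly Monthly transition
#'   probabilities.
#' @param q75 Annual death probability at age 75 for the generated life
#'   table.
#' @param gompertz_slope Per-year log-increase of mortality with age.
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(rr_mort_mrs02 = 2.0, rr_mort_mrs35 = 5.0,
                            p_recover_monthly = 0.02,
                            p_worsen_monthly = 0,
                            q75 = 0.018, gompertz_slope = 0.095) {
  structure(list(rr_mort_mrs02 = rr_mort_mrs02,
                 rr_mort_mrs35 = rr_mort_mrs35,
                 p_recover_monthly = p_recover_monthly,
                 p_worsen_monthly = p_worsen_monthly,
                 q75 = q75, gompertz_slope = gompertz_slope),
            class = "synthetic_truth")
}

#' Generate a Gompertz-form life table
#'
#' `q(age) = min(1 - eps, q75 * exp(slope * (age - 75)))`; a flat table
#' (slope 0) is useful for closed-form checks. If the Gompertz curve
#' reaches 1 before the end of the range the table is truncated (with a
#' warning) at the last valid age.
#'
#' @param q75 Annual death probability at age 75, in (0, 1).
#' @param slope Per-year log-increase (>= 0 for a monotone table).
#' @param ages Integer age range. Default `75:105`.
#' @return A `life_table` data frame.
#' @examples
#' gen_life_table(0.02, 0.1, 75:85)
#' @export
gen_life_table <- function(q75 = 0.018, slope = 0.095, ages = 75:105) {
  stopifnot(q75 > 0, q75 < 1)
  q <- q75 * exp(slope * (ages - 75))
  valid <- q < 1
  if (!all(valid)) {
    warning("gen_life_table: q reaches 1 at age ", min(ages[!valid]),
            "; table truncated", call. = FALSE)
    ages <- ages[valid]
    q <- q[valid]
  }
  as_life_table(data.frame(age = ages, qx = q))
}

#' Generate calibration targets from known parameters
#'
#' Runs the forward model (schedule construction plus cohort simulation)
#' under the ground-truth parameters and reads off survival and
#' independence-among-survivors at the landmark months. Feeding these
#' targets back into [calibrate()] must recover the truth (the forward
#' model is its own oracle).
#'
#' @param truth A [synthetic_truth].
#' @param initial The [mrs_distribution] at model entry.
#' @param landmark_months Calendar months (since onset) of the landmarks.
#'   Default `c(12, 24, 36, 48, 60)`.
#' @param life_table Optional `life_table`; by default generated from the
#'   truth's Gompertz parameters.
#' @param start_age,recovery_window_months,start_month Model timing as in
#'   [build_schedule()].
#' @return A `calibration_targets` data frame.
#' @export
gen_calibration_targets <- function(truth, initial,
                                    landmark_months = c(12, 24, 36, 48, 60),
                                    life_table = NULL, start_age = 75,
                                    recovery_window_months = 12,
                                    start_month = 3) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (length(landmark_months) == 0) {
    return(as_calibration_targets(data.frame(
      month = integer(0), survival = numeric(0),
      p02_among_alive = numeric(0))))
  }
  if (is.null(life_table)) {
    horizon_years <- ceiling(max(landmark_months) / 12) + 1
    life_table <- gen_life_table(truth$q75, truth$gompertz_slope,
                                 ages = start_age:(start_age + horizon_years))
  }
  par <- c(truth$rr_mort_mrs02, truth$rr_mort_mrs35,
           truth$p_recover_monthly, truth$p_worsen_monthly)
  targets_stub <- data.frame(month = sort(landmark_months),
                             survival = NA_real_,
                             p02_among_alive = NA_real_)
  pred <- predict_targets(par, targets_stub, life_table, initial, start_age,
                          recovery_window_months, start_month)
  as_calibration_targets(pred)
}

#' Generate a seeded uniform onset-weekday cohort
#'
#' Onset day of the week is i.i.d. uniform over Sunday-Saturday; used to
#' cross-check the exact onset-day enumeration in [expected_acute_cost()]
#' against a simulated cohort.
#'
#' @param n Cohort size (>= 1).
#' @param seed Integer seed.
#' @return Character vector of weekdays, length `n`.
#' @export
gen_onset_cohort <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed(sample(WEEKDAYS, n, replace = TRUE))
}

#' Write synthetic inputs to CSV
#'
#' Emits a life table and a calibration-targets file in the same CSV
#' dialects the calibration readers consume, guaranteeing a format
#' round-trip.
#'
#' @param dir Output directory (created if missing).
#' @param truth A [synthetic_truth].
#' @param initial Model-entry [mrs_distribution]; defaults to the base-case
#'   control arm.
#' @param landmark_months Landmarks for the targets.
#' @return Named character vector of the two paths written.
#' @export
write_synthetic_inputs <- function(dir, truth = synthetic_truth(),
                                   initial = NULL,
                                   landmark_months = c(12, 24, 36, 48, 60)) {
  if (is.null(initial)) initial <- control_initial(base_case_config())
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lt <- gen_life_table(truth$q75, truth$gompertz_slope)
  targets <- gen_calibration_targets(truth, initial, landmark_months,
                                     life_table = lt)
  lt_path <- file.path(dir, "life_table.csv")
  tg_path <- file.path(dir, "calibration_targets.csv")
  utils::write.csv(as.data.frame(lt), lt_path, row.names = FALSE)
  utils::write.csv(as.data.frame(targets), tg_path, row.names = FALSE)
  c(life_table = lt_path, calibration_targets = tg_path)
}
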