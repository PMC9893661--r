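# Markov cohort engine over the three coarse mRS states
# {mRS0-2 (independent), mRS3-5 (disabled), mRS6 (dead)}.

COARSE_STATES <- c("mRS02", "mRS35", "dead")

#' Coarse mRS occupancy distribution
#'
#' Constructs the occupancy vector over the three coarse disability states
#' used by the cohort model: mRS0-2 (functionally independent), mRS3-5
#' (disabled) and mRS6 (dead). Probabilities must be in `[0, 1]` and sum to 1.
#'
#' @param p02 Probability of being functionally independent (mRS0-2).
#' @param p35 Probability of being disabled (mRS3-5).
#' @param p_dead Probability of being dead (mRS6).
#' @return A named numeric vector of class `mrs_distribution`.
#' @examples
#' mrs_distribution(0.376, 0.585, 0.039)
#' @export
mrs_distribution <- function(p02, p35, p_dead) {
  p <- c(mRS02 = p02, mRS35 = p35, dead = p_dead)
  if (any(!is.finite(p)) || any(p < -1e-12) || any(p > 1 + 1e-12)) {
    stop("mrs_distribution: probabilities must lie in [0, 1], got (",
         paste(signif(p, 6), collapse = ", "), ")", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("mrs_distribution: probabilities must sum to 1 (got ",
         format(sum(p), digits = 12), ")", call. = FALSE)
  }
  structure(pmin(pmax(p, 0), 1), class = "mrs_distribution")
}

#' Convert an odds ratio to a risk ratio at a baseline risk
#'
#' Standard conversion `RR = OR / (1 - p0 + p0 * OR)` used to translate the
#' adjusted odds ratio for functional independence into the risk ratio
#' applied to the control arm's month-3 mRS0-2 proportion.
#'
#' @param odds_ratio Adjusted odds ratio (> 0).
#' @param baseline_risk Control-arm risk `p0`, strictly inside (0, 1).
#' @return The risk ratio (positive numeric scalar).
#' @examples
#' odds_ratio_to_risk_ratio(1.62, 0.376) # ~1.31
#' @export
odds_ratio_to_risk_ratio <- function(odds_ratio, baseline_risk) {
  if (!is.finite(odds_ratio) || odds_ratio <= 0) {
    stop("odds_ratio_to_risk_ratio: odds_ratio must be > 0", call. = FALSE)
  }
  if (!is.finite(baseline_risk) || baseline_risk <= 0 || baseline_risk >= 1) {
    stop("odds_ratio_to_risk_ratio: baseline_risk must be strictly inside ",
         "(0, 1)", call. = FALSE)
  }
  odds_ratio / (1 - baseline_risk + baseline_risk * odds_ratio)
}

#' Derive the intervention arm's initial mRS distribution
#'
#' The intervention (7-days-per-week) arm's month-3 probability of
#' functional independence is the control arm's probability multiplied by
#' the risk ratio; the death proportion is assumed equal across arms and the
#' disabled proportion takes the remainder.
#'
#' @param control_p02 Control-arm month-3 probability of mRS0-2.
#' @param risk_ratio Risk ratio for mRS0-2 (> 0).
#' @param p_dead Shared month-3 probability of death.
#' @return An [mrs_distribution].
#' @examples
#' derive_initial_distribution(0.376, 1.31, 0.039)
#' @export
derive_initial_distribution <- function(control_p02, risk_ratio, p_dead) {
  if (!is.finite(risk_ratio) || risk_ratio <= 0) {
    stop("derive_initial_distribution: risk_ratio must be > 0", call. = FALSE)
  }
  p02 <- control_p02 * risk_ratio
  if (p02 + p_dead > 1 + 1e-12) {
    stop("derive_initial_distribution: control_p02 * risk_ratio + p_dead = ",
         format(p02 + p_dead, digits = 6), " exceeds 1", call. = FALSE)
  }
  mrs_distribution(p02, 1 - p02 - p_dead, p_dead)
}

#' Per-cycle transition schedule
#'
#' Low-level constructor assembling one 3x3 row-stochastic matrix per
#' monthly cycle from per-cycle transition probabilities. Cycle `t` carries
#' the transition from calendar month `start_month + t - 1` to
#' `start_month + t` (months counted from stroke onset). The dead state is
#' absorbing.
#'
#' @param d02 Numeric vector, per-cycle death probability from mRS0-2.
#' @param d35 Per-cycle death probability from mRS3-5.
#' @param recover Per-cycle probability of mRS3-5 -> mRS0-2 recovery.
#' @param worsen Per-cycle probability of mRS0-2 -> mRS3-5 worsening.
#' @param start_month Calendar month (since onset) of the first trace point.
#' @return A `transition_schedule`: list with the 3x3xT array `mats`,
#'   `month_from`/`month_to` vectors and the per-cycle probability vectors.
#' @export
transition_schedule <- function(d02, d35, recover, worsen = 0,
                                start_month = 3) {
  n <- length(d02)
  stopifnot(length(d35) == n)
  recover <- rep_len(recover, n)
  worsen <- rep_len(worsen, n)
  bad <- which(d02 < 0 | d35 < 0 | recover < 0 | worsen < 0 |
                 d02 + worsen > 1 + 1e-12 | d35 + recover > 1 + 1e-12)
  if (length(bad)) {
    stop("transition_schedule: rows not stochastic at cycle(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (transition month ", start_month + bad[1] - 1, " -> ",
         start_month + bad[1], ")", call. = FALSE)
  }
  mats <- array(0, dim = c(3, 3, n),
                dimnames = list(COARSE_STATES, COARSE_STATES, NULL))
  mats[1, 1, ] <- 1 - d02 - worsen
  mats[1, 2, ] <- worsen
  mats[1, 3, ] <- d02
  mats[2, 1, ] <- recover
  mats[2, 2, ] <- 1 - d35 - recover
  mats[2, 3, ] <- d35
  mats[3, 3, ] <- 1
  structure(
    list(mats = mats, n_cycles = n,
         month_from = start_month + seq_len(n) - 1,
         month_to = start_month + seq_len(n),
         d02 = d02, d35 = d35, recover = recover, worsen = worsen,
         start_month = start_month),
    class = "transition_schedule"
  )
}

#' @export
print.transition_schedule <- function(x, ...) {
  cat("Transition schedule:", x$n_cycles, "monthly cycles, months",
      x$month_from[1], "->", x$month_to[x$n_cycles], "since onset\n")
  cat("  mean monthly P(death | mRS0-2):", signif(mean(x$d02), 4), "\n")
  cat("  mean monthly P(death | mRS3-5):", signif(mean(x$d35), 4), "\n")
  cat("  recovery active in", sum(x$recover > 0), "cycle(s)\n")
  invisible(x)
}

validate_schedule <- function(schedule) {
  if (!inherits(schedule, "transition_schedule")) {
    stop("expected a 'transition_schedule' object", call. = FALSE)
  }
  rs <- apply(schedule$mats, c(1, 3), sum)
  if (any(abs(rs - 1) > 1e-9) || any(schedule$mats < -1e-12)) {
    stop("transition matrices are not row-stochastic", call. = FALSE)
  }
  invisible(schedule)
}

#' Run the cohort simulation
#'
#' Propagates the initial coarse occupancy through the monthly transition
#' schedule: row `t+1` of the trace is row `t` times matrix `t`. The first
#' trace row is the initial distribution at `start_month` (month 3 after
#' onset in the base case).
#'
#' @param initial An [mrs_distribution] (month-3 occupancy).
#' @param schedule A [transition_schedule].
#' @return A `cohort_trace`: list with `months` (calendar months since
#'   onset) and `coarse`, a `(n_cycles + 1) x 3` occupancy matrix.
#' @examples
#' sched <- transition_schedule(d02 = rep(0.001, 57), d35 = rep(0.01, 57),
#'                              recover = c(rep(0.02, 9), rep(0, 48)))
#' tr <- run_cohort(mrs_distribution(0.376, 0.585, 0.039), sched)
#' utils::head(tr$coarse)
#' @export
run_cohort <- function(initial, schedule) {
  if (!inherits(initial, "mrs_distribution")) {
    initial <- do.call(mrs_distribution, as.list(unname(initial)))
  }
  validate_schedule(schedule)
  n <- schedule$n_cycles
  coarse <- matrix(NA_real_, n + 1, 3,
                   dimnames = list(NULL, COARSE_STATES))
  coarse[1, ] <- as.numeric(initial)
  row <- coarse[1, ]
  for (t in seq_len(n)) {
    row <- as.numeric(row %*% schedule$mats[, , t])
    coarse[t + 1, ] <- row
  }
  structure(
    list(months = schedule$start_month + 0:n, coarse = coarse),
    class = "cohort_trace"
  )
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x$coarse)
  cat("Cohort trace: months", x$months[1], "to", x$months[n],
      "since onset (", n - 1, "cycles )\n")
  cat("  final occupancy: mRS0-2", signif(x$coarse[n, 1], 4),
      "| mRS3-5", signif(x$coarse[n, 2], 4),
      "| dead", signif(x$coarse[n, 3], 4), "\n")
  if (!is.null(x$fine)) cat("  fine mRS0..6 split attached\n")
  invisible(x)
}

#' Fine split of coarse occupancy into mRS grades 0-6
#'
#' Splits mRS0-2 occupancy into grades 0:1:2 and mRS3-5 occupancy into
#' grades 3:4:5 using fixed proportions (assumed constant over the time
#' horizon). Each triple is renormalised to sum exactly to 1 before use, so
#' occupancy is conserved even when the printed proportions round to 99.9%.
#'
#' @param split02 Length-3 nonnegative proportions for grades 0, 1, 2.
#' @param split35 Length-3 nonnegative proportions for grades 3, 4, 5.
#' @return A `fine_split` object (list of the two renormalised triples).
#' @examples
#' fine_split(c(30.5, 29.8, 39.6), c(37.5, 36.9, 25.6))
#' @export
fine_split <- function(split02 = c(0.305, 0.298, 0.396),
                       split35 = c(0.375, 0.369, 0.256)) {
  norm3 <- function(x, what) {
    if (length(x) != 3 || any(!is.finite(x)) || any(x < 0) || sum(x) <= 0) {
      stop("fine_split: ", what, " must be 3 nonnegative proportions with ",
           "positive sum", call. = FALSE)
    }
    x / sum(x)
  }
  structure(list(split02 = norm3(split02, "split02"),
                 split35 = norm3(split35, "split35")),
            class = "fine_split")
}

#' Attach fine mRS grade occupancies to a cohort trace
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param split A [fine_split].
#' @return The trace with a `fine` matrix (columns `mRS0`..`mRS6`) attached;
#'   each fine row sums to the same total (1) as the coarse row.
#' @export
split_fine <- function(trace, split) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(split, "fine_split"))
  fine <- cbind(
    trace$coarse[, 1, drop = FALSE] %*% matrix(split$split02, 1, 3),
    trace$coarse[, 2, drop = FALSE] %*% matrix(split$split35, 1, 3),
    trace$coarse[, 3, drop = FALSE]
  )
  colnames(fine) <- paste0("mRS", 0:6)
  trace$fine <- fine
  trace
}

#' Export a cohort trace as a data frame / CSV
#'
#' @param trace A `cohort_trace` with fine occupancies attached.
#' @param path Optional CSV path; when given the table is also written.
#' @return Invisibly, a data frame with columns
#'   `month, mRS0..mRS6, mRS02, mRS35, dead`.
#' @export
trace_as_table <- function(trace, path = NULL) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (is.null(trace$fine)) {
    stop("trace_as_table: attach fine occupancies with split_fine() first",
         call. = FALSE)
  }
  out <- data.frame(month = trace$months, trace$fine, trace$coarse,
                    check.names = FALSE)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
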