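# Shared fixtures: built in code, no files beyond the packaged extdata.

ALL_WEEK <- c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")
MON_FRI <- c("Mon", "Tue", "Wed", "Thu", "Fri")

flat_life_table <- function(q = 0.024, ages = 75:90) {
  as_life_table(data.frame(age = ages, qx = q))
}

base_init_control <- function() mrs_distribution(0.376, 0.585, 0.039)

# random-but-valid transition schedule for property tests
random_schedule <- function(n = 57, seed = 1) {
  set.seed(seed)
  transition_schedule(
    d02 = runif(n, 0, 0.05),
    d35 = runif(n, 0, 0.10),
    recover = c(runif(min(9, n), 0, 0.05), rep(0, max(0, n - 9))),
    worsen = runif(1, 0, 0.02)
  )
}

# calibrate() is the slow step; freeze it once for the whole suite
frozen_base_config <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- freeze_calibration(base_case_config())
    cache
  }
})
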