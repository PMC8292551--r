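#' Simulate a cohort of individual life histories
#'
#' Exact event-driven (Gillespie) simulation of the full natural history:
#' BE onset drawn from the subgroup's age-dependent conversion hazard by
#' inversion, segment length drawn from the Beta law, then a stochastic
#' event loop over the one-hit / premalignant / malignant cell compartments
#' with the same "parent persists, spawns" semantics as the analytic
#' backward ODEs, until OAC detection or `max_age`. Each individual uses a
#' named substream derived from the master seed, so results are
#' reproducible and independent of simulation order.
#'
#' @param n number of individuals (>= 1).
#' @param config an [load_config()] configuration.
#' @param sex,cohort,subgroup stratum simulated (see [onset_rate()]).
#' @param rr optional GERD relative-risk override.
#' @param max_age censoring age, years.
#' @param seed master seed (nonnegative integer).
#' @param event_cap safety cap on events per individual; exceeding it is an
#'   error, not a silent truncation.
#' @return data frame of class `individual_histories`, one row per
#'   individual, with columns `id`, `be_onset_age`, `be_length`,
#'   `n_stem_cells`, `oac_detection_age`, `n_events` (`NA` where the event
#'   never occurred), plus `sex`, `cohort`, `subgroup`, `seed` attributes
#'   echoed as columns.
#' @examples
#' cfg <- load_config()
#' cohort <- simulate_cohort(100, cfg, seed = 1)
#' mean(!is.na(cohort$be_onset_age))  # fraction ever developing BE
#' @export
simulate_cohort <- function(n, config, sex = "M",
                            cohort = names(config$onset$cohort_multipliers)[1],
                            subgroup = "population", rr = NULL,
                            max_age = config$grid$age_max, seed = 0,
                            event_cap = 1e7) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (max_age <= 0) stop("max_age must be positive", call. = FALSE)
  onset <- config_onset_model(config, sex)
  grid <- seq(0, max_age, by = config$grid$step)
  nu <- onset_rate(onset, grid, subgroup, cohort, rr)
  Lambda <- cumtrapz_uniform(nu, config$grid$step)
  s <- config$segment
  out <- sim_cohort_cpp(as.integer(n), unlist(config$params), grid, Lambda,
                        s$beta_a, s$beta_b, s$length_max, s$cells_per_cm,
                        max_age, as.double(seed), event_cap)
  out$sex <- sex
  out$cohort <- cohort
  out$subgroup <- subgroup
  out$seed <- seed
  attr(out, "max_age") <- max_age
  class(out) <- c("individual_histories", "data.frame")
  out
}

#' Simulate a single individual history
#'
#' Equivalent to the first substream of [simulate_cohort()] with `n = 1`.
#'
#' @inheritParams simulate_cohort
#' @return one-row `individual_histories` data frame.
#' @export
simulate_individual <- function(config, sex = "M",
                                cohort = names(config$onset$cohort_multipliers)[1],
                                subgroup = "population", rr = NULL,
                                max_age = config$grid$age_max, seed = 0,
                                event_cap = 1e7) {
  simulate_cohort(1, config, sex, cohort, subgroup, rr, max_age, seed, event_cap)
}

#' Empirical incidence table from simulated histories
#'
#' Accumulates person-years until OAC detection (or censoring at the
#' simulation's `max_age`) and counts detections per age bin, producing a
#' registry-style incidence table consumable by the calibration module.
#'
#' @param cohort an `individual_histories` data frame.
#' @param breaks increasing age-bin edges; bins are half-open `[lo, hi)`.
#' @return data frame with columns `sex`, `cohort`, `age_low`, `age_high`,
#'   `cases`, `person_years`.
#' @export
empirical_incidence <- function(cohort, breaks = seq(40, 90, by = 5)) {
  if (!inherits(cohort, "individual_histories") || nrow(cohort) == 0)
    stop("cohort must be a non-empty individual_histories data frame", call. = FALSE)
  if (any(diff(breaks) <= 0)) stop("breaks must be strictly increasing", call. = FALSE)
  max_age <- attr(cohort, "max_age")
  if (is.null(max_age)) max_age <- max(breaks)
  end <- ifelse(is.na(cohort$oac_detection_age), max_age, cohort$oac_detection_age)
  nb <- length(breaks) - 1
  cases <- integer(nb); py <- numeric(nb)
  for (b in seq_len(nb)) {
    lo <- breaks[b]; hi <- breaks[b + 1]
    py[b] <- sum(pmax(0, pmin(end, hi) - lo) * (end > lo))
    cases[b] <- sum(!is.na(cohort$oac_detection_age) &
                      cohort$oac_detection_age >= lo &
                      cohort$oac_detection_age < hi)
  }
  data.frame(sex = cohort$sex[1], cohort = cohort$cohort[1],
             age_low = breaks[-length(breaks)], age_high = breaks[-1],
             cases = cases, person_years = py, stringsAsFactors = FALSE)
}
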