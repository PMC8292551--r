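#' GERD prevalence model
#'
#' Age- and sex-specific prevalence of symptomatic gastro-oesophageal reflux
#' disease (GERD), either logistic-parameterised,
#' `p(t) = p_max / (1 + exp(-k (t - t0)))`, or tabulated from a
#' `(sex, age, prevalence)` table with linear interpolation between tabulated
#' ages. GERD multiplies the BE conversion rate by a relative risk `rr`.
#'
#' @param p_max asymptotic prevalence in `[0, 1]`; a single value or a named
#'   vector by sex (e.g. `c(M = 0.3, F = 0.25)`).
#' @param k logistic steepness per year (> 0).
#' @param t0 age of half-maximal prevalence, years.
#' @param rr relative risk (>= 1) of BE conversion for GERD vs non-GERD.
#' @param table optional data frame with columns `sex`, `age`, `prevalence`;
#'   overrides the logistic parameters when supplied.
#' @return An object of class `gerd_model`.
#' @export
gerd_model <- function(p_max = 0.25, k = 0.12, t0 = 35, rr = 5, table = NULL) {
  if (rr < 1) stop("gerd_model: rr must be >= 1", call. = FALSE)
  if (is.null(table)) {
    if (any(p_max < 0 | p_max > 1)) stop("p_max must lie in [0, 1]", call. = FALSE)
    if (any(k <= 0)) stop("k must be positive", call. = FALSE)
  } else {
    req <- c("sex", "age", "prevalence")
    if (!all(req %in% names(table)))
      stop("GERD table needs columns sex, age, prevalence", call. = FALSE)
    if (any(table$prevalence < 0 | table$prevalence > 1))
      stop("GERD table prevalence outside [0, 1]", call. = FALSE)
  }
  structure(list(p_max = p_max, k = k, t0 = t0, rr = rr, table = table),
            class = "gerd_model")
}

#' GERD prevalence at given ages
#'
#' @param gerd a [gerd_model()].
#' @param age ages in years (vectorised).
#' @param sex sex label used to select a sex-specific `p_max` or table rows.
#' @return prevalence values in `[0, 1]`.
#' @export
gerd_prevalence <- function(gerd, age, sex = "M") {
  stopifnot(inherits(gerd, "gerd_model"))
  if (!is.null(gerd$table)) {
    tab <- gerd$table[gerd$table$sex == sex, , drop = FALSE]
    if (nrow(tab) == 0) stop("GERD table has no rows for sex '", sex, "'", call. = FALSE)
    tab <- tab[order(tab$age), ]
    return(stats::approx(tab$age, tab$prevalence, xout = age, rule = 2)$y)
  }
  pm <- if (length(gerd$p_max) > 1) {
    if (is.null(names(gerd$p_max)) || !sex %in% names(gerd$p_max))
      stop("p_max has no entry for sex '", sex, "'", call. = FALSE)
    gerd$p_max[[sex]]
  } else gerd$p_max
  pm / (1 + exp(-gerd$k * (age - gerd$t0)))
}

#' BE onset model
#'
#' BE onset is a single-conversion event with age-dependent hazard
#' `nu(t) = nu0 * m_cohort * [1 + (rr - 1) * p_GERD(t)]` in the general
#' population; in the GERD subgroup `nu = nu0 * m_cohort * rr` and in the
#' non-GERD subgroup `nu = nu0 * m_cohort`. Birth-cohort effects enter only
#' through the multiplier on `nu0`.
#'
#' @param nu0 baseline BE conversion rate per year (nonnegative).
#' @param gerd a [gerd_model()].
#' @param sex sex label of this model (one onset model per sex).
#' @param cohort_multiplier named numeric vector of positive multipliers
#'   keyed by decade start year (e.g. `c("1930" = 0.8, "1950" = 1.2)`).
#' @return An object of class `be_onset_model`.
#' @export
be_onset_model <- function(nu0, gerd = gerd_model(), sex = "M",
                           cohort_multiplier = c("1950" = 1)) {
  if (nu0 < 0 || !is.finite(nu0)) stop("nu0 must be finite and >= 0", call. = FALSE)
  if (any(cohort_multiplier <= 0)) stop("cohort multipliers must be positive", call. = FALSE)
  if (is.null(names(cohort_multiplier)))
    stop("cohort_multiplier must be named by decade start year", call. = FALSE)
  structure(list(nu0 = nu0, gerd = gerd, sex = sex,
                 cohort_multiplier = cohort_multiplier),
            class = "be_onset_model")
}

cohort_mult <- function(model, cohort) {
  key <- as.character(cohort)
  m <- model$cohort_multiplier
  if (key %in% names(m)) return(unname(m[key]))
  # clamp to nearest fitted cohort
  avail <- as.numeric(names(m))
  nearest <- avail[which.min(abs(avail - as.numeric(cohort)))]
  warning("cohort ", cohort, " outside fitted range; clamped to ", nearest,
          call. = FALSE)
  unname(m[as.character(nearest)])
}

#' BE conversion rate nu(t) for a subgroup
#'
#' @param model a [be_onset_model()].
#' @param age ages in years (vectorised), >= 0.
#' @param subgroup one of `"population"`, `"gerd"`, `"non_gerd"`.
#' @param cohort birth-cohort decade used to look up the multiplier.
#' @param rr optional relative-risk override (defaults to the model's GERD rr).
#' @return onset rate per year at each age.
#' @export
onset_rate <- function(model, age, subgroup = "population",
                       cohort = names(model$cohort_multiplier)[1], rr = NULL) {
  stopifnot(inherits(model, "be_onset_model"))
  if (any(age < 0)) stop("age must be >= 0", call. = FALSE)
  if (!subgroup %in% c("population", "gerd", "non_gerd"))
    stop("unknown subgroup '", subgroup, "' (use population, gerd or non_gerd)",
         call. = FALSE)
  if (is.null(rr)) rr <- model$gerd$rr
  base <- model$nu0 * cohort_mult(model, cohort)
  switch(subgroup,
         population = base * (1 + (rr - 1) * gerd_prevalence(model$gerd, age, model$sex)),
         gerd = rep(base * rr, length(age)),
         non_gerd = rep(base, length(age)))
}

#' Cumulative BE onset Lambda(age)
#'
#' Trapezoid integral of [onset_rate()] from 0 to each requested age on a
#' uniform grid of the given step.
#'
#' @inheritParams onset_rate
#' @param step integration grid step, years.
#' @return Lambda at each age; `Lambda(0) = 0`, non-decreasing.
#' @export
cumulative_onset <- function(model, age, subgroup = "population",
                             cohort = names(model$cohort_multiplier)[1],
                             rr = NULL, step = 0.1) {
  if (any(age < 0)) stop("age must be >= 0", call. = FALSE)
  grid <- seq(0, max(age, step), by = step)
  nu <- onset_rate(model, grid, subgroup, cohort, rr)
  Lam <- cumtrapz_uniform(nu, step)
  stats::approx(grid, Lam, xout = age, rule = 2)$y
}

#' Unconditional BE prevalence 1 - exp(-Lambda)
#'
#' The cancer-ignored prevalence of having converted to BE by a given age.
#' The cancer-free conditional prevalence is the `be_prevalence_cancer_free`
#' column of [population_hazard()].
#'
#' @inheritParams cumulative_onset
#' @return probabilities in `[0, 1]`.
#' @export
be_prevalence <- function(model, age, subgroup = "population",
                          cohort = names(model$cohort_multiplier)[1],
                          rr = NULL, step = 0.1) {
  1 - exp(-cumulative_onset(model, age, subgroup, cohort, rr, step))
}

#' Cancer-free BE prevalence curves for the GERD subgroup across RR values
#'
#' For each relative risk in `rr_values`, feeds the GERD-subgroup onset rate
#' `rr * nu0 * m_cohort` through [population_hazard()] and returns the
#' cancer-free BE prevalence curve. Curves are pointwise monotone in rr.
#'
#' @param model a [be_onset_model()].
#' @param be_surv a [be_survival()] result on a grid compatible with `age_grid`.
#' @param age_grid uniform age grid starting at 0.
#' @param rr_values relative risks, all >= 1.
#' @param cohort birth-cohort decade for the multiplier.
#' @return named list mapping each rr to its `hazard_curve`.
#' @export
gerd_subgroup_prevalence_curve <- function(model, be_surv, age_grid,
                                           rr_values,
                                           cohort = names(model$cohort_multiplier)[1]) {
  if (length(rr_values) == 0) stop("rr_values must be non-empty", call. = FALSE)
  if (any(rr_values < 1)) stop("rr_values must all be >= 1", call. = FALSE)
  out <- lapply(rr_values, function(rr) {
    nu <- onset_rate(model, age_grid, "gerd", cohort, rr = rr)
    population_hazard(be_surv, nu, age_grid, sex = model$sex, cohort = cohort,
                      subgroup = paste0("gerd_rr", rr))
  })
  names(out) <- as.character(rr_values)
  out
}
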