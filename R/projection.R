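#' Hazard curves for every (sex, cohort) stratum needed by a census year
#'
#' @param config configuration.
#' @param sexes sex labels.
#' @param cohorts cohort decade start years.
#' @param model optional precomputed [msce_model()] (reused when supplied).
#' @return named list `"sex|cohort" -> hazard_curve`.
#' @keywords internal
strata_hazards <- function(config, sexes, cohorts, model = NULL) {
  if (is.null(model)) model <- msce_model(config)
  out <- list()
  for (sx in sexes) {
    onset <- config_onset_model(config, sx)
    for (co in cohorts) {
      nu <- onset_rate(onset, model$age_grid, "population", co)
      out[[paste(sx, co, sep = "|")]] <-
        population_hazard(model$be_surv, nu, model$age_grid, sex = sx, cohort = co)
    }
  }
  out
}

cohort_bin <- function(year, age) floor((year - age) / 10) * 10

lookup_curve <- function(hazards, sex, cohort) {
  key <- paste(sex, cohort, sep = "|")
  if (!is.null(hazards[[key]])) return(hazards[[key]])
  # clamp to the nearest available cohort for this sex
  keys <- names(hazards)
  mine <- keys[startsWith(keys, paste0(sex, "|"))]
  if (length(mine) == 0) stop("no hazard curve for sex '", sex, "'", call. = FALSE)
  cohorts <- as.numeric(sub(".*\\|", "", mine))
  nearest <- cohorts[which.min(abs(cohorts - cohort))]
  warning("no hazard curve for cohort ", cohort, " (", sex,
          "); using nearest cohort ", nearest, call. = FALSE)
  hazards[[paste(sex, nearest, sep = "|")]]
}

#' Expected OAC case count for a census year
#'
#' Multiplies person-years by the age-specific hazard of the matching
#' (sex, birth-cohort) curve and sums over the age range:
#' `cases = sum PY(year, sex, age) * h_OAC(age; sex, cohort = year - age)`,
#' with the cohort floored to its decade bin. Hazards are evaluated at the
#' mid-year of each single age (`age + 0.5`).
#'
#' @param hazards named list of hazard curves keyed `"sex|cohort"`, e.g.
#'   from [strata_hazards()].
#' @param census census table with columns `year`, `sex`, `age`,
#'   `person_years`.
#' @param year calendar year to project.
#' @param age_range inclusive age range, default 40--90.
#' @return object of class `case_prediction`: `year`, `total`, per-stratum
#'   data frame `by_stratum`, and the settings used.
#' @export
expected_cases <- function(hazards, census, year, age_range = c(40, 90)) {
  validate_census(census)
  sub <- census[census$year == year & census$age >= age_range[1] &
                  census$age <= age_range[2], , drop = FALSE]
  if (nrow(sub) == 0) stop("census has no rows for year ", year, call. = FALSE)
  max_grid <- max(hazards[[1]]$age)
  if (age_range[2] + 1 > max_grid)
    stop("age range exceeds the hazard grid (max age ", max_grid, ")", call. = FALSE)
  sub$cohort <- cohort_bin(year, sub$age)
  h <- numeric(nrow(sub))
  for (i in seq_len(nrow(sub))) {
    curve <- lookup_curve(hazards, sub$sex[i], sub$cohort[i])
    h[i] <- curve_at(curve, sub$age[i] + 0.5)
  }
  sub$expected_cases <- sub$person_years * h
  structure(list(year = year,
                 total = sum(sub$expected_cases),
                 by_stratum = sub[, c("year", "sex", "age", "cohort",
                                      "person_years", "expected_cases")],
                 age_range = age_range),
            class = "case_prediction")
}

#' @export
print.case_prediction <- function(x, ...) {
  cat("Expected OAC cases in", x$year, "(ages", x$age_range[1], "-",
      x$age_range[2], "):", format(x$total, digits = 6), "\n")
  if (!is.null(x$interval))
    cat(sprintf("  %g%% interval: %.1f - %.1f\n", 100 * x$interval$level,
                x$interval$lo, x$interval$hi))
  invisible(x)
}

#' Percentile interval for the expected case count
#'
#' Recomputes [expected_cases()] for each parameter draw and takes the
#' percentile interval of the resulting totals. Deterministic given the
#' draw matrix. Draws with non-finite or nonpositive parameters are skipped
#' with a count; more than 50% skipped is an error.
#'
#' @param fit an [fit_incidence_model()] result.
#' @param draws draw matrix from [parameter_uncertainty()].
#' @param census,year,age_range as in [expected_cases()].
#' @param level interval level (default 0.95).
#' @return `case_prediction` with an added `interval` element
#'   (`lo`, `hi`, `level`, `totals`, `n_skipped`).
#' @export
prediction_interval <- function(fit, draws, census, year,
                                age_range = c(40, 90), level = 0.95) {
  stopifnot(inherits(fit, "msce_fit"))
  if (nrow(draws) < 100) stop("need at least 100 parameter draws", call. = FALSE)
  validate_census(census)
  sexes <- unique(census$sex[census$year == year])
  ages <- age_range[1]:age_range[2]
  cohorts <- sort(unique(cohort_bin(year, ages)))

  base_model <- msce_model(fit$config)
  point <- expected_cases(strata_hazards(fit$config, sexes, cohorts, base_model),
                          census, year, age_range)
  reuse_biology <- !touches_biology(colnames(draws))

  bad <- !apply(draws, 1, function(d) all(is.finite(d) & d > 0))
  n_skipped <- sum(bad)
  if (n_skipped > 0.5 * nrow(draws))
    stop("more than 50% of parameter draws infeasible (", n_skipped, " of ",
         nrow(draws), ")", call. = FALSE)
  totals <- rep(NA_real_, nrow(draws))
  for (i in which(!bad)) {
    cfg <- apply_free_params(fit$config, draws[i, ])
    model_i <- if (reuse_biology) base_model else msce_model(cfg)
    hz <- strata_hazards(cfg, sexes, cohorts, model_i)
    totals[i] <- expected_cases(hz, census, year, age_range)$total
  }
  qs <- stats::quantile(totals, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  point$interval <- list(lo = qs[1], hi = qs[2], level = level,
                         totals = totals, n_skipped = n_skipped)
  point
}

#' BE carrier count implied by a census year
#'
#' Sums person-years weighted by the cancer-free BE prevalence
#' `p_be_cf(age; sex, cohort)` over the age range, returning the carrier
#' count and the prevalence fraction `count / total person-years`.
#'
#' @inheritParams expected_cases
#' @return list with `carriers`, `person_years`, `fraction`.
#' @export
be_carrier_count <- function(hazards, census, year, age_range = c(40, 90)) {
  validate_census(census)
  sub <- census[census$year == year & census$age >= age_range[1] &
                  census$age <= age_range[2], , drop = FALSE]
  if (nrow(sub) == 0) stop("census has no rows for year ", year, call. = FALSE)
  sub$cohort <- cohort_bin(year, sub$age)
  p <- numeric(nrow(sub))
  for (i in seq_len(nrow(sub))) {
    curve <- lookup_curve(hazards, sub$sex[i], sub$cohort[i])
    p[i] <- curve_at(curve, sub$age[i] + 0.5, "be_prevalence_cancer_free")
  }
  carriers <- sum(sub$person_years * p)
  list(carriers = carriers, person_years = sum(sub$person_years),
       fraction = carriers / sum(sub$person_years))
}

#' Annual BE-to-OAC progression rate at an age
#'
#' The model attributes every OAC case to BE, so the annual OAC incidence
#' among prevalent cancer-free BE carriers is
#' `h_OAC(age) / p_be_cf(age)`.
#'
#' @param curve a `hazard_curve`.
#' @param age age(s) in years.
#' @param floor smallest admissible `p_be_cf`; below it the rate is
#'   undefined and an error is raised.
#' @return annual progression rate(s).
#' @export
progression_rate <- function(curve, age, floor = 1e-8) {
  stopifnot(inherits(curve, "hazard_curve"))
  p <- curve_at(curve, age, "be_prevalence_cancer_free")
  if (any(p < floor))
    stop("p_be_cf below floor (", floor, ") at requested age; progression ",
         "rate undefined", call. = FALSE)
  curve_at(curve, age, "hazard") / p
}

#' Fraction of observed cases attributable to the BE pathway
#'
#' @param predicted_cases model-predicted case count.
#' @param observed_cases observed registry case count (> 0).
#' @return list with `fraction` (`min(1, predicted / observed)`) and
#'   `unexplained` (`1 - fraction`).
#' @export
attributable_fraction <- function(predicted_cases, observed_cases) {
  if (observed_cases <= 0) stop("observed_cases must be > 0", call. = FALSE)
  if (predicted_cases < 0) stop("predicted_cases must be >= 0", call. = FALSE)
  f <- min(1, predicted_cases / observed_cases)
  list(fraction = f, unexplained = 1 - f,
       excess = max(0, predicted_cases - observed_cases))
}

#' Sensitivity sweep over GERD relative risk and prevalence scaling
#'
#' Re-runs the projection pipeline over a grid of scenarios: GERD relative
#' risks and multiplicative scalings of the GERD prevalence curve. Each row
#' reports expected cases, the population cancer-free BE prevalence
#' fraction, the GERD-subgroup BE prevalence at a reference age, and the
#' progression rate at that age. The base scenario
#' (`rr = config rr`, `gerd_scale = 1`) reproduces the non-sweep pipeline
#' output exactly.
#'
#' @param config configuration.
#' @param census census table.
#' @param year calendar year.
#' @param rr_values GERD relative risks to sweep (>= 1).
#' @param gerd_scales multiplicative scalings of `p_max` (clipped to keep
#'   prevalence in `[0, 1]`).
#' @param age_range projection age range.
#' @param ref_age reference age for subgroup prevalence and progression.
#' @return data frame, one row per scenario, with scenario columns
#'   (`rr`, `gerd_scale`) prepended.
#' @export
sweep_scenarios <- function(config, census, year,
                            rr_values = config$onset$rr,
                            gerd_scales = 1,
                            age_range = c(40, 90), ref_age = 60) {
  if (length(rr_values) == 0 || length(gerd_scales) == 0)
    stop("scenario grid must be non-empty", call. = FALSE)
  if (any(rr_values < 1))
    stop("invalid scenario: rr must be >= 1 (got ",
         paste(rr_values[rr_values < 1], collapse = ", "), ")", call. = FALSE)
  if (any(gerd_scales < 0))
    stop("invalid scenario: gerd_scale must be >= 0", call. = FALSE)
  sexes <- unique(census$sex[census$year == year])
  ages <- age_range[1]:age_range[2]
  cohorts <- sort(unique(cohort_bin(year, ages)))
  grid <- expand.grid(rr = rr_values, gerd_scale = gerd_scales,
                      KEEP.OUT.ATTRS = FALSE)
  base_model <- msce_model(config)   # biology unchanged across scenarios
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$onset$rr <- grid$rr[i]
    pm <- lapply(cfg$onset$gerd$p_max, function(x) min(1, x * grid$gerd_scale[i]))
    if (!is.list(cfg$onset$gerd$p_max)) pm <- min(1, cfg$onset$gerd$p_max * grid$gerd_scale[i])
    cfg$onset$gerd$p_max <- pm
    hz <- strata_hazards(cfg, sexes, cohorts, base_model)
    pred <- expected_cases(hz, census, year, age_range)
    carriers <- be_carrier_count(hz, census, year, age_range)
    ref_sex <- sexes[1]
    ref_cohort <- cohort_bin(year, ref_age)
    ref_curve <- lookup_curve(hz, ref_sex, ref_cohort)
    onset_ref <- config_onset_model(cfg, ref_sex)
    gerd_curve <- population_hazard(
      base_model$be_surv,
      onset_rate(onset_ref, base_model$age_grid, "gerd", ref_cohort),
      base_model$age_grid, sex = ref_sex, cohort = ref_cohort, subgroup = "gerd")
    rows[[i]] <- data.frame(
      rr = grid$rr[i], gerd_scale = grid$gerd_scale[i],
      expected_cases = pred$total,
      be_prevalence = carriers$fraction,
      gerd_be_prevalence_ref = curve_at(gerd_curve, ref_age,
                                        "be_prevalence_cancer_free"),
      progression_rate_ref = progression_rate(ref_curve, ref_age))
  }
  do.call(rbind, rows)
}
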