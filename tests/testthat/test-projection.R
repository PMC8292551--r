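# fabricate a flat hazard curve for arithmetic tests
flat_curve <- function(h, p_be = 0.016, ages = 0:100, sex = "M", cohort = 1950) {
  structure(data.frame(age = ages, hazard = h, survival = 1,
                       be_prevalence_cancer_free = p_be,
                       incidence_per_100k = 1e5 * h, sex = sex,
                       cohort = cohort, subgroup = "population",
                       stringsAsFactors = FALSE),
            class = c("hazard_curve", "data.frame"))
}

test_that("expected cases reproduce hand-computed sums exactly", {
  hz <- list(`M|1950` = flat_curve(1e-4))
  census <- data.frame(year = 2010, sex = "M", age = 55, person_years = 1e5)
  pred <- expected_cases(hz, census, 2010, age_range = c(55, 55))
  expect_equal(pred$total, 10.0)

  hz2 <- list(`M|1950` = flat_curve(2e-4), `F|1950` = flat_curve(5e-5, sex = "F"))
  census2 <- data.frame(year = 2010, sex = c("M", "F"), age = 55,
                        person_years = c(5e4, 2e5))
  pred2 <- expected_cases(hz2, census2, 2010, age_range = c(55, 55))
  expect_equal(pred2$total, 20.0)
  expect_equal(sum(pred2$by_stratum$expected_cases), pred2$total, tolerance = 1e-9)
  expect_error(expected_cases(hz, census, 1999), "no rows")
})

test_that("expected cases equal an independent row-by-row sum and are linear in person-years", {
  cfg <- fast_cfg()
  census <- make_census_table(2010, total_py = 2e6)
  cohorts <- sort(unique(msceoac:::cohort_bin(2010, 40:90)))
  hz <- msceoac:::strata_hazards(cfg, c("M", "F"), cohorts)
  pred <- expected_cases(hz, census, 2010)

  # brute-force spreadsheet-style oracle
  manual <- 0
  for (i in seq_len(nrow(census))) {
    a <- census$age[i]
    if (a < 40 || a > 90 || census$year[i] != 2010) next
    co <- floor((2010 - a) / 10) * 10
    cu <- hz[[paste(census$sex[i], co, sep = "|")]]
    manual <- manual + census$person_years[i] *
      approx(cu$age, cu$hazard, a + 0.5)$y
  }
  expect_equal(pred$total, manual, tolerance = 1e-9)

  census2 <- census; census2$person_years <- 2 * census$person_years
  pred2 <- expected_cases(hz, census2, 2010)
  expect_equal(pred2$total, 2 * pred$total, tolerance = 1e-9)
})

test_that("prediction interval collapses for identical draws and ignores draw order", {
  cfg <- fast_cfg()
  tab <- synth_incidence_table(cfg, cohorts = 1950, py_per_stratum = 1e6, seed = 2)
  fit <- fit_incidence_model(tab, fit_spec(free = "nu0"), cfg, n_starts = 1, seed = 4)
  census <- make_census_table(2010, total_py = 1e6)

  same <- matrix(rep(fit$estimates, each = 120), nrow = 120,
                 dimnames = list(NULL, names(fit$estimates)))
  pred <- prediction_interval(fit, same, census, 2010)
  expect_equal(pred$interval$lo, pred$interval$hi)
  expect_equal(pred$interval$lo, pred$total, tolerance = 1e-9)

  draws <- parameter_uncertainty(fit, n_draws = 120, seed = 5)
  p1 <- prediction_interval(fit, draws, census, 2010)
  p2 <- prediction_interval(fit, draws[rev(seq_len(nrow(draws))), ], census, 2010)
  expect_equal(p1$interval$lo, p2$interval$lo)
  expect_equal(p1$interval$hi, p2$interval$hi)
  expect_true(p1$interval$lo <= p1$total && p1$total <= p1$interval$hi)
  expect_error(prediction_interval(fit, draws[1:50, ], census, 2010),
               "at least 100")
})

test_that("BE carrier counts follow the prevalence-weighted person-years", {
  hz <- list(`M|1950` = flat_curve(1e-4, p_be = 0))
  census <- data.frame(year = 2010, sex = "M", age = 55, person_years = 1e6)
  expect_equal(be_carrier_count(hz, census, 2010, c(55, 55))$carriers, 0)

  hz16 <- list(`M|1950` = flat_curve(1e-4, p_be = 0.016))
  out <- be_carrier_count(hz16, census, 2010, c(55, 55))
  expect_equal(out$carriers, 16000)
  expect_equal(out$fraction, 0.016)
})

test_that("progression rate is hazard over prevalence with saturation and floor behaviour", {
  expect_equal(progression_rate(flat_curve(0, p_be = 0.02), 60), 0)
  expect_error(progression_rate(flat_curve(1e-4, p_be = 0), 60), "floor")

  # identity h = rate * p_be_cf on the whole grid
  cfg <- fast_cfg()
  curve <- msce_hazard(msce_model(cfg), "M", 1950)
  ages <- seq(20, 90, by = 5)
  rates <- progression_rate(curve, ages)
  p <- approx(curve$age, curve$be_prevalence_cancer_free, ages)$y
  h <- approx(curve$age, curve$hazard, ages)$y
  expect_equal(rates * p, h, tolerance = 1e-12)

  # nu0 large enough that nearly everyone has BE: progression ~ hazard
  cfg$onset$nu0$M <- cfg$onset$nu0$M * 1000
  sat <- msce_hazard(msce_model(cfg), "M", 1950)
  expect_gt(curve_value(sat, 70, "be_prevalence_cancer_free"), 0.99)
  expect_lt(abs(progression_rate(sat, 70) / curve_value(sat, 70) - 1), 0.01)
})

test_that("attributable fraction is capped at one and complements unexplained", {
  expect_equal(attributable_fraction(9400, 9400)$fraction, 1)
  expect_equal(attributable_fraction(0, 9400)$fraction, 0)
  out <- attributable_fraction(9970, 9400)
  expect_equal(out$fraction, 1)         # model over-predicts: capped
  expect_equal(out$excess, 570)
  half <- attributable_fraction(4700, 9400)
  expect_equal(half$fraction, 0.5)
  expect_equal(half$unexplained, 0.5)
  expect_error(attributable_fraction(10, 0), "observed_cases")
})

test_that("scenario sweeps reproduce the base pipeline and are monotone in RR", {
  cfg <- fast_cfg()
  census <- make_census_table(2010, total_py = 1e6)
  base <- sweep_scenarios(cfg, census, 2010)   # single base scenario
  expect_equal(nrow(base), 1)

  cohorts <- sort(unique(msceoac:::cohort_bin(2010, 40:90)))
  hz <- msceoac:::strata_hazards(cfg, c("M", "F"), cohorts)
  expect_equal(base$expected_cases, expected_cases(hz, census, 2010)$total)
  expect_equal(base$be_prevalence, be_carrier_count(hz, census, 2010)$fraction)

  grid <- sweep_scenarios(cfg, census, 2010, rr_values = c(2, 4, 6),
                          gerd_scales = c(0.8, 1.2))
  expect_equal(nrow(grid), 6)
  byscale <- split(grid, grid$gerd_scale)
  for (g in byscale)
    expect_true(all(diff(g$gerd_be_prevalence_ref[order(g$rr)]) >= 0))

  # each scenario reproducible independently
  single <- sweep_scenarios(cfg, census, 2010, rr_values = 4, gerd_scales = 1.2)
  row <- grid[grid$rr == 4 & grid$gerd_scale == 1.2, ]
  rownames(row) <- NULL
  expect_equal(row, single)
  expect_error(sweep_scenarios(cfg, census, 2010, rr_values = 0.5), "rr must be")
})
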