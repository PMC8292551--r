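test_that("poisson log-likelihood matches the closed formula on a single row", {
  cfg <- fast_cfg()
  model <- msce_model(cfg)
  curve <- msce_hazard(model, "M", 1950)
  h_mid <- curve_value(curve, 62.5)
  py <- 2 / h_mid    # engineered so lambda = 2
  tab <- data.frame(sex = "M", cohort = 1950, age_low = 60, age_high = 65,
                    cases = 2, person_years = py)
  ll <- poisson_loglik(cfg, tab)
  expect_equal(ll, 2 * log(2) - 2 - log(2), tolerance = 1e-4)

  # zero cases under a zero-hazard model contribute exactly 0
  cfg0 <- fast_cfg()
  cfg0$onset$nu0 <- list(M = 0, F = 0)
  tab0 <- data.frame(sex = "M", cohort = 1950, age_low = c(60, 65),
                     age_high = c(65, 70), cases = 0, person_years = 1e5)
  expect_equal(poisson_loglik(cfg0, tab0), 0)
  # positive cases under a zero hazard hit the -Inf guard
  tab1 <- tab0; tab1$cases <- c(1, 0)
  expect_lt(poisson_loglik(cfg0, tab1), -1e9)
  # unknown cohort is a configuration error
  tabx <- tab; tabx$cohort <- 1890
  expect_error(poisson_loglik(cfg, tabx), "cohort")
})

test_that("log-likelihood at the generating truth beats 10%-perturbed parameters", {
  cfg <- fast_cfg()
  tab <- synth_incidence_table(cfg, py_per_stratum = 1e7, seed = 3)
  ll_truth <- poisson_loglik(cfg, tab)
  set.seed(41)
  wins <- 0
  n_pert <- 20
  for (k in seq_len(n_pert)) {
    cfg2 <- cfg
    cfg2$onset$nu0$M <- cfg$onset$nu0$M * runif(1, 0.9, 1.1)
    cfg2$onset$nu0$F <- cfg$onset$nu0$F * runif(1, 0.9, 1.1)
    cfg2$params$mu2 <- cfg$params$mu2 * runif(1, 0.9, 1.1)
    if (ll_truth >= poisson_loglik(cfg2, tab)) wins <- wins + 1
  }
  expect_gte(wins / n_pert, 0.95)
})

test_that("fits are deterministic given the seed and recover a boundary nu0 of zero", {
  cfg <- fast_cfg()
  tab <- synth_incidence_table(cfg, cohorts = 1950, py_per_stratum = 1e6, seed = 5)
  f1 <- fit_incidence_model(tab, fit_spec(free = "nu0"), cfg, n_starts = 2, seed = 9)
  f2 <- fit_incidence_model(tab, fit_spec(free = "nu0"), cfg, n_starts = 2, seed = 9)
  expect_identical(f1$estimates, f2$estimates)

  # all-zero table drives nu0 to (effectively) zero hazard
  cfg0 <- fast_cfg()
  cfg0$onset$nu0 <- list(M = 0, F = 0)
  tab0 <- synth_incidence_table(cfg0, cohorts = 1950, py_per_stratum = 1e6, seed = 5)
  expect_true(all(tab0$cases == 0))
  f0 <- fit_incidence_model(tab0, fit_spec(free = "nu0", nu0_by_sex = FALSE),
                            cfg0, n_starts = 1, seed = 1)
  expect_lt(f0$estimates[["nu0"]], 1e-9)
})

test_that("adding a free parameter never decreases the maximised log-likelihood", {
  cfg <- fast_cfg()
  tab <- synth_incidence_table(cfg, cohorts = c(1940, 1950),
                               py_per_stratum = 1e6, seed = 13)
  f_small <- fit_incidence_model(tab, fit_spec(free = "nu0", nu0_by_sex = FALSE),
                                 cfg, n_starts = 1, seed = 2)
  f_mid <- fit_incidence_model(tab, fit_spec(free = "nu0"), cfg,
                               n_starts = 1, seed = 2)
  f_big <- fit_incidence_model(tab, fit_spec(free = c("nu0", "mu2")), cfg,
                               n_starts = 2, seed = 2)
  expect_gte(f_mid$loglik, f_small$loglik - 1e-6)
  expect_gte(f_big$loglik, f_mid$loglik - 1e-6)

  lrt <- likelihood_ratio_test(f_small, f_mid)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 1)
  expect_true(lrt$p_value >= 0 && lrt$p_value <= 1)
  expect_error(likelihood_ratio_test(f_mid, f_small), "more free parameters")
})

test_that("likelihood-ratio test handles the degenerate and textbook cases", {
  fit0 <- structure(list(estimates = c(nu0 = 1e-4), loglik = -100, n_free = 1),
                    class = "msce_fit")
  fit1 <- structure(list(estimates = c(`nu0[M]` = 1e-4, `nu0[F]` = 1e-4),
                         loglik = -100, n_free = 2), class = "msce_fit")
  lrt <- likelihood_ratio_test(fit0, fit1)
  expect_equal(lrt$statistic, 0)
  expect_equal(lrt$p_value, 1)
  fit2 <- fit1; fit2$loglik <- -100 + 3.841 / 2
  expect_equal(likelihood_ratio_test(fit0, fit2)$p_value, 0.05, tolerance = 1e-3)
  fit3 <- structure(list(estimates = c(mu2 = 1e-3), loglik = -99, n_free = 1),
                    class = "msce_fit")
  expect_error(likelihood_ratio_test(fit3, fit1), "not nested")
})

test_that("parameter draws are seed-deterministic, positive, and centred near the estimate", {
  cfg <- fast_cfg()
  tab <- synth_incidence_table(cfg, cohorts = 1950, py_per_stratum = 1e7, seed = 21)
  fit <- fit_incidence_model(tab, fit_spec(free = "nu0"), cfg, n_starts = 1, seed = 3)
  d1 <- parameter_uncertainty(fit, n_draws = 300, seed = 17)
  d2 <- parameter_uncertainty(fit, n_draws = 300, seed = 17)
  expect_identical(d1, d2)
  expect_true(all(d1 > 0))
  expect_equal(attr(d1, "method"), "normal")
  med <- apply(d1, 2, median)
  expect_equal(unname(med), unname(fit$estimates), tolerance = 0.1)
})

test_that("nu0 estimation bias shrinks as person-years grow", {
  cfg <- fast_cfg()
  truth <- cfg$onset$nu0$M
  err_at <- function(py) {
    errs <- vapply(1:3, function(r) {
      tab <- synth_incidence_table(cfg, sexes = "M", cohorts = 1950,
                                   py_per_stratum = py, seed = 100 + r)
      f <- fit_incidence_model(tab, fit_spec(free = "nu0"), cfg,
                               n_starts = 1, seed = r)
      abs(f$estimates[["nu0[M]"]] - truth) / truth
    }, numeric(1))
    mean(errs)
  }
  expect_lt(err_at(1e8), err_at(1e5))
})
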