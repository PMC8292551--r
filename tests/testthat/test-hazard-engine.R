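tau <- seq(0, 80, by = 0.1)

test_that("without a detection channel all survival probabilities are one", {
  p <- biological_params(1e-3, 1e-3, 2, 1.8, 1e-3, 3, 2.4, rho = 0)
  sol <- solve_backward_system(p, tau)
  expect_equal(sol$S_M, rep(1, length(tau)))
  expect_equal(sol$S_P, rep(1, length(tau)))
  expect_equal(sol$S_0, rep(1, length(tau)))
})

test_that("pure-detection malignant survival is exponential", {
  p <- biological_params(0, 0, 0, 0, 0, alphaM = 0, betaM = 0, rho = 0.5)
  sol <- solve_backward_system(p, c(0, 1, 2))
  expect_equal(sol$S_M[3], exp(-1), tolerance = 1e-7)
})

test_that("ODE-solved S_M matches the constant-coefficient Riccati closed form", {
  sets <- list(c(3, 2.4, 0.02), c(10, 9.5, 0.02), c(1, 2, 0.5))
  for (s in sets) {
    p <- biological_params(1e-4, 1e-4, 10, 9.9, 1e-5, s[1], s[2], s[3])
    sol <- solve_backward_system(p, tau)
    expect_lt(max(abs(sol$S_M - sm_closed_form(s[1], s[2], s[3], tau))), 1e-6)
  }
})

test_that("S_M agrees with a direct single-cell Gillespie estimate", {
  aM <- 10; bM <- 9.5; rho <- 0.02
  p <- biological_params(1e-4, 1e-4, 10, 9.9, 1e-5, aM, bM, rho)
  sol <- solve_backward_system(p, seq(0, 10, by = 0.5))
  for (tt in c(5, 10)) {
    mc <- gillespie_single_malignant(aM, bM, rho, tt, n_rep = 8000, seed = 7 + tt)
    ana <- sol$S_M[sol$tau_grid == tt]
    expect_lt(abs(ana - mc$p), 3 * mc$se)
  }
})

test_that("solution invariants hold: S in [0,1], non-increasing, S(0)=1, dS0 <= 0", {
  p <- biological_params(6e-3, 6e-3, 2, 1.75, 1e-3, 3, 2.4, 0.02)
  sol <- solve_backward_system(p, tau)
  for (comp in list(sol$S_M, sol$S_P, sol$S_1, sol$S_0)) {
    expect_true(all(comp >= 0 & comp <= 1))
    expect_equal(comp[1], 1)
    expect_true(all(diff(comp) <= 1e-12))
  }
  expect_true(all(sol$dS0 <= 0))
  expect_error(solve_backward_system(p, c(1, 2)), "start at 0")
  expect_error(solve_backward_system(p, c(0, 2, 1)), "increasing")
})

test_that("be_survival reduces to identities in degenerate cases", {
  p0 <- biological_params(1e-3, 1e-3, 2, 1.8, 1e-3, 3, 2.4, rho = 0)
  sol <- solve_backward_system(p0, tau)
  seg <- be_segment_model()
  bs <- be_survival(sol, seg)
  expect_equal(bs$S_BE, rep(1, length(tau)))   # S_0 == 1 regardless of segment

  # degenerate length law concentrated at L = 1 with cells_per_cm * L = 1:
  # a single-node mixture, for which S_BE must equal S_0 exactly
  p <- biological_params(6e-3, 6e-3, 2, 1.75, 1e-3, 3, 2.4, 0.02)
  sol <- solve_backward_system(p, tau)
  seg1 <- structure(list(beta_a = 1, beta_b = 1, length_max = 1,
                         cells_per_cm = 1, n_quad = 1,
                         lengths = 1, weights = 1),
                    class = "be_segment_model")
  bs1 <- be_survival(sol, seg1)
  expect_equal(bs1$S_BE, sol$S_0, tolerance = 1e-12)
})

test_that("be_survival matches Monte-Carlo marginalisation over segment lengths", {
  # synthetic stem-cell survival S_0 = exp(-0.001 tau)
  tg <- seq(0, 10, by = 0.5)
  s0 <- exp(-0.001 * tg)
  sol <- structure(list(tau_grid = tg, S_M = s0, S_P = s0, S_1 = s0,
                        S_0 = s0, dS0 = -0.001 * s0),
                   class = "survival_solution")
  seg <- be_segment_model(beta_a = 2, beta_b = 6, length_max = 10,
                          cells_per_cm = 100)
  bs <- be_survival(sol, seg)
  set.seed(11)
  L <- 10 * rbeta(1e6, 2, 6)
  draws <- exp(-0.001 * 5)^(100 * L)
  mc <- mean(draws); se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(bs$S_BE[tg == 5] - mc), 3 * se)
})

test_that("population hazard vanishes without onset and reduces to cumulative onset without progression", {
  p <- biological_params(6e-3, 6e-3, 2, 1.75, 1e-3, 3, 2.4, 0.02)
  age <- seq(0, 80, by = 0.1)
  bs <- be_survival(solve_backward_system(p, age), be_segment_model())
  cv0 <- population_hazard(bs, rep(0, length(age)), age)
  expect_equal(cv0$hazard, rep(0, length(age)))
  expect_equal(cv0$be_prevalence_cancer_free, rep(0, length(age)))
  expect_equal(cv0$survival, rep(1, length(age)))

  # S_BE == 1: prevalence equals 1 - exp(-Lambda), hazard 0
  bs1 <- bs
  bs1$S_BE <- rep(1, length(age)); bs1$dS_BE <- rep(0, length(age))
  nu <- rep(0.002, length(age))
  cv1 <- population_hazard(bs1, nu, age)
  expect_equal(cv1$hazard, rep(0, length(age)))
  expect_equal(cv1$be_prevalence_cancer_free[age == 50], 1 - exp(-0.1),
               tolerance = 1e-8)
})

test_that("hazard increases pointwise in nu0, mu2 and rho", {
  cfg <- fast_cfg()
  idx <- NULL
  base_curve <- function(cfg) {
    m <- msce_model(cfg)
    msce_hazard(m, "M", 1950)$hazard
  }
  for (knob in c("nu0", "mu2", "rho")) {
    hs <- lapply(c(1, 2, 4), function(f) {
      cfg2 <- cfg
      if (knob == "nu0") cfg2$onset$nu0$M <- cfg$onset$nu0$M * f
      else cfg2$params[[knob]] <- cfg$params[[knob]] * f
      base_curve(cfg2)
    })
    sel <- -(1:2)  # skip ages ~0 where everything is 0
    expect_true(all(hs[[2]][sel] >= hs[[1]][sel]), label = paste("monotone in", knob))
    expect_true(all(hs[[3]][sel] >= hs[[2]][sel]), label = paste("monotone in", knob))
  }
  expect_true(all(base_curve(cfg) >= 0))
})

test_that("per-cell hazard has log-log slope 3 in the four-rare-event limit", {
  p <- biological_params(1e-3, 1e-3, alphaP = 0, betaP = 0, mu2 = 1e-3,
                         alphaM = 0, betaM = 0, rho = 1e-3)
  tg <- seq(0, 1, by = 0.001)
  sol <- solve_backward_system(p, tg)
  h <- -sol$dS0 / sol$S_0
  idx <- tg >= 0.1 & tg <= 1
  slope <- coef(lm(log(h[idx]) ~ log(tg[idx])))[2]
  expect_lt(abs(slope - 3), 0.05)
})

test_that("incidence per 100k is the unit-scaled hazard", {
  cfg <- fast_cfg()
  curve <- msce_hazard(msce_model(cfg), "M", 1950)
  expect_equal(incidence_per_100k(curve), 1e5 * curve$hazard)
  curve$hazard <- rep(1e-4, nrow(curve))
  expect_equal(unique(incidence_per_100k(curve)), 10)
  curve$hazard <- c(1e-5, 2e-5, rep(0, nrow(curve) - 2))
  expect_equal(incidence_per_100k(curve)[1:2], c(1, 2))
})
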