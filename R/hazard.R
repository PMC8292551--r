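#' Solve the backward survival ODEs of the clonal expansion process
#'
#' Computes, as a function of time-since-event tau, the probability that a
#' single cell of each type produces *no detected cancer* within tau years:
#' `S_M` for a malignant cell, `S_P` for a premalignant cell, `S_1` for a
#' one-hit cell and `S_0` for a BE stem cell. The system uses
#' "parent persists, spawns" mutation semantics:
#' \deqn{S_M' = \beta_M - (\alpha_M+\beta_M+\rho) S_M + \alpha_M S_M^2}
#' \deqn{S_P' = \beta_P - (\alpha_P+\beta_P+\mu_2) S_P + \alpha_P S_P^2 + \mu_2 S_P S_M}
#' \deqn{S_1' = \mu_1 S_1 (S_P - 1)}
#' \deqn{S_0' = \mu_0 S_0 (S_1 - 1)}
#' with all initial values 1. Detection is size based: a malignant clone of n
#' cells is detected at rate n*rho.
#'
#' @param params a [biological_params()] bundle.
#' @param tau_grid strictly increasing grid of nonnegative times (years since
#'   BE onset), starting at 0.
#' @param rtol,atol relative/absolute solver tolerances passed to
#'   [deSolve::ode()].
#' @return An object of class `survival_solution`: a list with `tau_grid`,
#'   `S_M`, `S_P`, `S_1`, `S_0` and `dS0` (the derivative of `S_0`, <= 0).
#' @examples
#' p <- biological_params(1e-3, 1e-3, 2, 1.8, 1e-3, 3, 2.4, 0.02)
#' sol <- solve_backward_system(p, seq(0, 80, by = 0.5))
#' range(sol$S_0)
#' @export
solve_backward_system <- function(params, tau_grid, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "biological_params"))
  if (length(tau_grid) < 2 || tau_grid[1] != 0 || any(diff(tau_grid) <= 0) ||
      any(tau_grid < 0) || any(!is.finite(tau_grid)))
    stop("tau_grid must start at 0 and be strictly increasing and finite", call. = FALSE)

  rhs <- function(t, y, p) {
    sM <- y[1]; sP <- y[2]; s1 <- y[3]; s0 <- y[4]
    dM <- p$betaM - (p$alphaM + p$betaM + p$rho) * sM + p$alphaM * sM^2
    dP <- p$betaP - (p$alphaP + p$betaP + p$mu2) * sP + p$alphaP * sP^2 +
      p$mu2 * sP * sM
    d1 <- p$mu1 * s1 * (sP - 1)
    d0 <- p$mu0 * s0 * (s1 - 1)
    list(c(dM, dP, d1, d0))
  }
  out <- deSolve::ode(y = c(1, 1, 1, 1), times = tau_grid, func = rhs,
                      parms = params, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("backward survival ODE solver failed to converge", call. = FALSE)
  S <- unname(out[, 2:5, drop = FALSE])
  tol <- 1e-6
  comp <- c("S_M", "S_P", "S_1", "S_0")
  for (j in 1:4) {
    if (any(S[, j] < -tol | S[, j] > 1 + tol))
      stop("survival component ", comp[j], " left [0,1] beyond solver tolerance",
           call. = FALSE)
  }
  S <- pmin(pmax(S, 0), 1)
  dim(S) <- c(length(tau_grid), 4)
  s1 <- S[, 3]; s0 <- S[, 4]
  structure(list(tau_grid = tau_grid,
                 S_M = S[, 1], S_P = S[, 2], S_1 = s1, S_0 = s0,
                 dS0 = params$mu0 * s0 * (s1 - 1)),
            class = "survival_solution")
}

#' Survival of a whole BE segment, marginalised over segment length
#'
#' A segment of length L carries `N(L) = cells_per_cm * L` independent stem
#' cells, so its no-detection probability is `S_0(tau)^N(L)`. This function
#' returns the expectation over the Beta length law by fixed-node quadrature,
#' \eqn{S_{BE}(\tau) = E_L[S_0(\tau)^{N(L)}]}, together with its analytic
#' derivative \eqn{E_L[N(L) S_0^{N(L)-1} S_0']}.
#'
#' @param solution a [solve_backward_system()] result.
#' @param segment a [be_segment_model()].
#' @return A list of class `be_survival` with `tau_grid`, `S_BE` and `dS_BE`
#'   (non-positive).
#' @export
be_survival <- function(solution, segment) {
  stopifnot(inherits(solution, "survival_solution"),
            inherits(segment, "be_segment_model"))
  N <- segment_cells(segment)
  w <- segment$weights
  if (sum(w) <= 0) stop("degenerate segment-length quadrature", call. = FALSE)
  s0 <- solution$S_0
  ds0 <- solution$dS0
  # outer(s0, N, `^`) is n_tau x n_quad; weight-collapse to the mixture
  powm <- outer(s0, N, `^`)
  S_BE <- as.vector(powm %*% w)
  # d/dtau S_0^N = N S_0^(N-1) dS0; guard 0^negative when s0 == 0
  s0g <- pmax(s0, .Machine$double.xmin)
  dS_BE <- as.vector((outer(s0g, N - 1, `^`) %*% (w * N)) * ds0)
  structure(list(tau_grid = solution$tau_grid,
                 S_BE = pmin(pmax(S_BE, 0), 1),
                 dS_BE = pmin(dS_BE, 0)),
            class = "be_survival")
}

#' Population age-specific OAC hazard by mixing over BE onset age
#'
#' BE onset is a single-conversion event with age-dependent hazard nu(t)
#' (cumulative Lambda). Conditional on onset at age s, the no-detection
#' probability at age t is `S_BE(t - s)`. The population quantities are
#' \deqn{S_{pop}(t) = e^{-\Lambda(t)} + \int_0^t \nu(s) e^{-\Lambda(s)} S_{BE}(t-s)\,ds}
#' \deqn{h_{OAC}(t) = \frac{\int_0^t \nu(s) e^{-\Lambda(s)} (-S_{BE}'(t-s))\,ds}{S_{pop}(t)}}
#' \deqn{p^{cf}_{BE}(t) = \frac{\int_0^t \nu(s) e^{-\Lambda(s)} S_{BE}(t-s)\,ds}{S_{pop}(t)}}
#' i.e. the hazard of first OAC detection and the prevalence of cancer-free
#' BE, both among persons alive and cancer-free at age t. The convolution
#' integrals are evaluated by trapezoid rule on the common uniform grid
#' (FFT-accelerated), so `age_grid` must be uniform and match the tau grid of
#' `be_surv` in step.
#'
#' @param be_surv a [be_survival()] result on a uniform tau grid.
#' @param nu BE onset rate nu(t) evaluated on `age_grid` (per year), or a
#'   function of age.
#' @param age_grid uniform, strictly increasing ages starting at 0; the step
#'   must equal the `be_surv` tau step and the grid must not extend past it.
#' @param sex,cohort,subgroup stratum labels attached to the result.
#' @param spop_floor lower floor for `S_pop` below which the mixture is
#'   declared numerically unusable.
#' @return An object of class `hazard_curve`: a data frame with columns
#'   `age`, `hazard`, `survival` (S_pop), `be_prevalence_cancer_free`,
#'   `incidence_per_100k`, `sex`, `cohort`, `subgroup`.
#' @export
population_hazard <- function(be_surv, nu, age_grid,
                              sex = NA_character_, cohort = NA,
                              subgroup = "population", spop_floor = 1e-12) {
  stopifnot(inherits(be_surv, "be_survival"))
  n <- length(age_grid)
  if (n < 2 || age_grid[1] != 0) stop("age_grid must start at 0", call. = FALSE)
  h_step <- diff(age_grid)
  if (any(h_step <= 0) || diff(range(h_step)) > 1e-9 * h_step[1])
    stop("age_grid must be uniform and strictly increasing", call. = FALSE)
  dt <- h_step[1]
  tau <- be_surv$tau_grid
  if (length(tau) < n || abs(tau[2] - tau[1] - dt) > 1e-9)
    stop("age_grid incompatible with the tau grid of be_surv (step or range mismatch)",
         call. = FALSE)
  if (is.function(nu)) nu <- nu(age_grid)
  if (length(nu) != n || any(nu < 0) || any(!is.finite(nu)))
    stop("nu must be a nonnegative finite rate on age_grid", call. = FALSE)

  Lambda <- cumtrapz_uniform(nu, dt)
  g <- nu * exp(-Lambda)                    # onset density among never-BE
  q <- be_surv$S_BE[seq_len(n)]
  dq <- be_surv$dS_BE[seq_len(n)]

  int_q  <- conv_trapz(g, q, dt)            # \int g(s) q(t-s) ds
  int_dq <- conv_trapz(g, -dq, dt)          # \int g(s) (-q'(t-s)) ds

  S_pop <- exp(-Lambda) + int_q
  if (any(S_pop < spop_floor))
    stop("S_pop fell below the configured floor (", spop_floor, ")", call. = FALSE)
  h <- pmax(int_dq, 0) / S_pop
  p_be <- pmin(pmax(int_q / S_pop, 0), 1)
  h[1] <- 0; p_be[1] <- 0

  structure(data.frame(age = age_grid, hazard = h, survival = S_pop,
                       be_prevalence_cancer_free = p_be,
                       incidence_per_100k = 1e5 * h,
                       sex = sex, cohort = cohort, subgroup = subgroup,
                       stringsAsFactors = FALSE),
            class = c("hazard_curve", "data.frame"))
}

#' Incidence per 100,000 person-years from a hazard curve
#'
#' @param curve a [population_hazard()] result.
#' @return numeric vector `1e5 * hazard`, one value per grid age.
#' @export
incidence_per_100k <- function(curve) {
  stopifnot(inherits(curve, "hazard_curve"))
  1e5 * curve$hazard
}

# cumulative trapezoid on a uniform grid, C(1) = 0
cumtrapz_uniform <- function(y, dt) {
  n <- length(y)
  c(0, cumsum((y[-n] + y[-1]) / 2) * dt)
}

# trapezoid-rule convolution \int_0^{t_i} f(s) g(t_i - s) ds on a uniform grid.
# FFT full convolution plus endpoint half-weight corrections.
conv_trapz <- function(f, g, dt) {
  n <- length(f)
  full <- stats::convolve(f, rev(g), type = "open")[seq_len(n)]
  (full - 0.5 * f[1] * g - 0.5 * g[1] * f) * dt
}

#' Interpolate a hazard-curve column at arbitrary ages
#' @param curve a `hazard_curve`.
#' @param age ages (years) inside the curve's grid.
#' @param what column to interpolate.
#' @return numeric vector of interpolated values.
#' @keywords internal
curve_at <- function(curve, age, what = "hazard") {
  stats::approx(curve$age, curve[[what]], xout = age, rule = 2)$y
}
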