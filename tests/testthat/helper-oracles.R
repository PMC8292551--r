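# Independent oracles used across tests. These never call the solution
# path they are checking.

# Closed-form survival of a single malignant cell under constant
# birth/death/detection rates: the Riccati ODE
#   S' = aM S^2 - (aM + bM + rho) S + bM
# has constant roots r1 <= r2 of aM x^2 - (aM+bM+rho) x + bM, giving
#   (S - r1)/(S - r2) = (1 - r1)/(1 - r2) * exp(aM (r1 - r2) tau).
sm_closed_form <- function(aM, bM, rho, tau) {
  if (aM == 0) {
    if (bM + rho == 0) return(rep(1, length(tau)))
    return(bM / (bM + rho) + rho / (bM + rho) * exp(-(bM + rho) * tau))
  }
  disc <- sqrt((aM + bM + rho)^2 - 4 * aM * bM)
  r1 <- ((aM + bM + rho) - disc) / (2 * aM)
  r2 <- ((aM + bM + rho) + disc) / (2 * aM)
  K <- (1 - r1) / (1 - r2) * exp(aM * (r1 - r2) * tau)
  (r1 - r2 * K) / (1 - K)
}

# Direct Gillespie estimate of P(no detection by tau) for a clone started
# from a single malignant cell (birth aM, death bM, per-cell detection rho).
gillespie_single_malignant <- function(aM, bM, rho, tau_max, n_rep, seed) {
  set.seed(seed)
  survived <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    t <- 0; n <- 1; alive <- TRUE
    while (n > 0) {
      total <- n * (aM + bM + rho)
      t <- t + stats::rexp(1, total)
      if (t >= tau_max) break
      u <- stats::runif(1) * (aM + bM + rho)
      if (u < aM) n <- n + 1
      else if (u < aM + bM) n <- n - 1
      else { alive <- FALSE; break }
    }
    survived[r] <- alive
  }
  list(p = mean(survived), se = stats::sd(survived) / sqrt(n_rep))
}

# demo config with a coarser grid for calibration-heavy tests
fast_cfg <- function(step = 0.5, age_max = 95) {
  cfg <- load_config()
  cfg$grid$step <- step
  cfg$grid$age_max <- age_max
  cfg
}

# interpolate a hazard-curve column at an age
curve_value <- function(curve, age, what = "hazard") {
  stats::approx(curve$age, curve[[what]], xout = age)$y
}
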