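#' Specify which parameters are free in a calibration
#'
#' @param free character vector of free parameters among `"nu0"`, `"mu0"`
#'   (which ties `mu1 = mu0`), `"mu2"`, `"rho"`.
#' @param nu0_by_sex if `TRUE`, `nu0` is stratified by sex (one free value
#'   per sex present in the table); if `FALSE` a single pooled `nu0` is used
#'   for all sexes.
#' @param free_cohorts if `TRUE`, cohort multipliers for all table cohorts
#'   except the reference (lowest) are freed; the reference stays at its
#'   configured value to keep `nu0` identifiable.
#' @return object of class `fit_spec`.
#' @export
fit_spec <- function(free = c("nu0", "mu2"), nu0_by_sex = TRUE,
                     free_cohorts = FALSE) {
  allowed <- c("nu0", "mu0", "mu2", "rho")
  if (length(free) == 0 || !all(free %in% allowed))
    stop("free parameters must be among: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  structure(list(free = free, nu0_by_sex = nu0_by_sex,
                 free_cohorts = free_cohorts),
            class = "fit_spec")
}

# named vector of free-parameter starting values (natural scale) for a table
free_param_template <- function(spec, config, table) {
  sexes <- sort(unique(table$sex))
  cohorts <- sort(unique(table$cohort))
  theta <- numeric(0)
  if ("nu0" %in% spec$free) {
    if (spec$nu0_by_sex) {
      v <- vapply(sexes, function(s) config_nu0(config, s), numeric(1))
      names(v) <- paste0("nu0[", sexes, "]")
      theta <- c(theta, v)
    } else {
      theta <- c(theta, nu0 = mean(vapply(sexes, function(s)
        config_nu0(config, s), numeric(1))))
    }
  }
  if ("mu0" %in% spec$free) theta <- c(theta, mu0 = config$params$mu0)
  if ("mu2" %in% spec$free) theta <- c(theta, mu2 = config$params$mu2)
  if ("rho" %in% spec$free) theta <- c(theta, rho = config$params$rho)
  if (isTRUE(spec$free_cohorts) && length(cohorts) > 1) {
    mult <- unlist(config$onset$cohort_multipliers)
    for (co in cohorts[-1]) {
      key <- as.character(co)
      v <- if (key %in% names(mult)) mult[[key]] else 1
      theta[paste0("cohort[", key, "]")] <- v
    }
  }
  theta
}

# overlay free parameters (natural scale, named as in the template) on a config
apply_free_params <- function(config, theta) {
  for (nm in names(theta)) {
    v <- as.numeric(theta[[nm]])
    if (nm == "nu0") {
      if (is.list(config$onset$nu0)) {
        config$onset$nu0 <- lapply(config$onset$nu0, function(x) v)
      } else config$onset$nu0 <- v
    } else if (grepl("^nu0\\[", nm)) {
      sx <- sub("^nu0\\[(.*)\\]$", "\\1", nm)
      config$onset$nu0[[sx]] <- v
    } else if (nm == "mu0") {
      config$params$mu0 <- v
      config$params$mu1 <- v   # tied
    } else if (grepl("^cohort\\[", nm)) {
      co <- sub("^cohort\\[(.*)\\]$", "\\1", nm)
      config$onset$cohort_multipliers[[co]] <- v
    } else if (nm %in% c("mu2", "rho")) {
      config$params[[nm]] <- v
    } else stop("unknown free parameter '", nm, "'", call. = FALSE)
  }
  config
}

# does theta touch the biological params (forcing an ODE re-solve)?
touches_biology <- function(theta_names)
  any(sub("\\[.*", "", theta_names) %in% c("mu0", "mu2", "rho"))

#' Poisson log-likelihood of an incidence table under a configuration
#'
#' The expected count in a table row is `lambda = person_years * h(mid)`,
#' the model hazard at the bin midpoint for that row's (sex, cohort)
#' stratum. The log-likelihood is `sum(c * log(lambda) - lambda - log(c!))`,
#' with the convention that a zero-count row with `lambda = 0` contributes
#' 0, and a positive count with `lambda = 0` contributes a large negative
#' guard value instead of `-Inf`.
#'
#' @param config an [load_config()] configuration (free parameters already
#'   overlaid).
#' @param table incidence table with columns `sex`, `cohort`, `age_low`,
#'   `age_high`, `cases`, `person_years`.
#' @param model optional precomputed [msce_model()] for `config` (reused
#'   when only onset parameters changed).
#' @return scalar log-likelihood.
#' @export
poisson_loglik <- function(config, table, model = NULL) {
  validate_incidence(table)
  known <- names(config$onset$cohort_multipliers)
  bad <- setdiff(unique(as.character(table$cohort)), known)
  if (length(bad) > 0)
    stop("incidence table references cohorts with no multiplier: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(model)) model <- msce_model(config)
  ll <- 0
  mids <- (table$age_low + table$age_high) / 2
  for (stratum in split(seq_len(nrow(table)),
                        list(table$sex, table$cohort), drop = TRUE)) {
    sx <- table$sex[stratum[1]]
    co <- table$cohort[stratum[1]]
    onset <- config_onset_model(config, sx)
    nu <- onset_rate(onset, model$age_grid, "population", co)
    curve <- population_hazard(model$be_surv, nu, model$age_grid,
                               sex = sx, cohort = co)
    lam <- table$person_years[stratum] * curve_at(curve, mids[stratum])
    cc <- table$cases[stratum]
    term <- ifelse(lam > 0, cc * log(lam) - lam - lgamma(cc + 1),
                   ifelse(cc == 0, 0, -1e10))
    ll <- ll + sum(term)
  }
  ll
}

#' Fit free parameters to an incidence table by Poisson maximum likelihood
#'
#' Derivative-free Nelder-Mead maximisation on the log-parameter scale with
#' seeded multi-start: the first start is the configured value, the rest are
#' log-uniform draws within a factor-of-10 band around it. Deterministic
#' given `seed`.
#'
#' @param table incidence table (see [poisson_loglik()]).
#' @param spec a [fit_spec()].
#' @param config baseline configuration supplying all fixed parameters.
#' @param n_starts number of Nelder-Mead starts.
#' @param seed seed for the start draws.
#' @param reltol convergence tolerance on the log-likelihood.
#' @return object of class `msce_fit`: `estimates` (named, natural scale),
#'   `loglik`, `n_free`, `convergence` (per-start status and the winning
#'   start), `spec`, `config` (with estimates overlaid), `seed`.
#' @export
fit_incidence_model <- function(table, spec = fit_spec(), config = load_config(),
                                n_starts = 5, seed = 0, reltol = 1e-8) {
  validate_incidence(table)
  if (nrow(table) == 0) stop("incidence table is empty", call. = FALSE)
  theta0 <- free_param_template(spec, config, table)
  if (length(theta0) == 0) stop("no free parameters to fit", call. = FALSE)
  theta0 <- pmax(theta0, 1e-10)  # log-scale needs positives
  base_model <- if (!touches_biology(names(theta0))) msce_model(config) else NULL

  negll <- function(ltheta) {
    theta <- stats::setNames(exp(ltheta), names(theta0))
    cfg <- apply_free_params(config, theta)
    -poisson_loglik(cfg, table, model = base_model)
  }

  set.seed(as.integer(seed) %% .Machine$integer.max)
  starts <- vector("list", n_starts)
  starts[[1]] <- log(theta0)
  if (n_starts > 1) {
    for (k in 2:n_starts)
      starts[[k]] <- log(theta0) + stats::runif(length(theta0), -log(10), log(10))
  }

  fits <- lapply(starts, function(st) {
    if (length(st) == 1) {
      stats::optim(st, negll, method = "Brent",
                   lower = st - log(1e4), upper = st + log(1e4),
                   control = list(reltol = reltol))
    } else {
      stats::optim(st, negll, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = 2000))
    }
  })
  vals <- vapply(fits, function(f) f$value, numeric(1))
  if (all(!is.finite(vals)))
    stop("fit failed to converge from any start", call. = FALSE)
  best <- which.min(vals)
  fit <- fits[[best]]
  est <- stats::setNames(exp(fit$par), names(theta0))
  structure(list(estimates = est,
                 loglik = -fit$value,
                 n_free = length(est),
                 convergence = list(status = fit$convergence,
                                    counts = fit$counts,
                                    start_values = -vals,
                                    winning_start = best),
                 spec = spec,
                 config = apply_free_params(config, est),
                 table = table,
                 seed = seed),
            class = "msce_fit")
}

#' @export
print.msce_fit <- function(x, ...) {
  cat("MSCE Poisson ML fit:", x$n_free, "free parameter(s), loglik =",
      format(x$loglik, digits = 8), "\n")
  print(x$estimates)
  invisible(x)
}

#' Likelihood-ratio test between nested calibrations
#'
#' @param fit_null,fit_alt `msce_fit` objects; the null's free-parameter set
#'   must be nested in the alternative's (a pooled parameter counts as
#'   nested in its sex-stratified version).
#' @return list with `statistic` (`2 * (ll_alt - ll_null)`, clipped at 0),
#'   `df` and `p_value` from the chi-square upper tail.
#' @export
likelihood_ratio_test <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "msce_fit"), inherits(fit_alt, "msce_fit"))
  if (fit_alt$n_free <= fit_null$n_free)
    stop("alternative must have more free parameters than the null", call. = FALSE)
  base <- function(x) unique(sub("\\[.*", "", names(x$estimates)))
  if (!all(base(fit_null) %in% base(fit_alt)))
    stop("models are not nested: null frees ",
         paste(setdiff(base(fit_null), base(fit_alt)), collapse = ", "),
         " absent from the alternative", call. = FALSE)
  stat <- max(0, 2 * (fit_alt$loglik - fit_null$loglik))
  df <- fit_alt$n_free - fit_null$n_free
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Parameter draws from the asymptotic normal approximation
#'
#' Draws free parameters from a multivariate normal on the log-parameter
#' (estimation) scale with covariance the inverse observed information
#' (numerical Hessian of the log-likelihood at the optimum), which keeps
#' every draw in the feasible (positive) region. If the information matrix
#' is singular even after a small ridge, falls back to a nonparametric
#' bootstrap over table rows and logs the fallback.
#'
#' @param fit an [fit_incidence_model()] result.
#' @param n_draws number of draws.
#' @param seed RNG seed; same seed gives an identical draw matrix.
#' @param n_boot bootstrap refits used only in the singular-information
#'   fallback.
#' @return matrix `n_draws x n_free` of natural-scale parameter draws with
#'   an attribute `method` (`"normal"` or `"bootstrap"`).
#' @export
parameter_uncertainty <- function(fit, n_draws = 1000, seed = 0, n_boot = 100) {
  stopifnot(inherits(fit, "msce_fit"))
  est <- fit$estimates
  lhat <- log(est)
  base_model <- if (!touches_biology(names(est))) msce_model(fit$config) else NULL
  llfun <- function(ltheta) {
    theta <- stats::setNames(exp(ltheta), names(est))
    poisson_loglik(apply_free_params(fit$config, theta), fit$table,
                   model = base_model)
  }
  H <- pracma::hessian(llfun, lhat)
  info <- -(H + t(H)) / 2
  cov <- tryCatch(solve(info), error = function(e) NULL)
  ok <- !is.null(cov) && all(is.finite(cov)) && all(eigen(cov, TRUE)$values > 0)
  if (!ok) {
    cov <- tryCatch(solve(info + diag(1e-8, nrow(info))), error = function(e) NULL)
    ok <- !is.null(cov) && all(is.finite(cov)) && all(eigen(cov, TRUE)$values > 0)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  if (ok) {
    R <- chol(cov)
    z <- matrix(stats::rnorm(n_draws * length(est)), n_draws)
    draws <- exp(sweep(z %*% R, 2, lhat, `+`))
    colnames(draws) <- names(est)
    attr(draws, "method") <- "normal"
    return(draws)
  }
  message("observed information singular; falling back to nonparametric bootstrap")
  boot_est <- matrix(NA_real_, n_boot, length(est), dimnames = list(NULL, names(est)))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(fit$table), replace = TRUE)
    bf <- try(fit_incidence_model(fit$table[idx, , drop = FALSE], fit$spec,
                                  fit$config, n_starts = 1, seed = seed + b),
              silent = TRUE)
    if (!inherits(bf, "try-error")) boot_est[b, ] <- bf$estimates
  }
  boot_est <- boot_est[stats::complete.cases(boot_est), , drop = FALSE]
  if (nrow(boot_est) == 0) stop("bootstrap fallback failed", call. = FALSE)
  draws <- boot_est[sample.int(nrow(boot_est), n_draws, replace = TRUE), , drop = FALSE]
  attr(draws, "method") <- "bootstrap"
  draws
}
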