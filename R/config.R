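#' Default model configuration
#'
#' The packaged demo configuration: a ground-truth parameter set chosen so
#' that the model produces order-of-magnitude realistic outputs (BE
#' prevalence near 1--2% by age 60, lifetime OAC risk near 1%, a 4:1
#' male:female baseline BE conversion ratio, GERD relative risk 5). These are
#' synthetic demonstration values, not any published calibration.
#'
#' @return nested configuration list (see [load_config()] for the schema).
#' @export
default_config <- function() {
  list(
    params = list(mu0 = 6e-3, mu1 = 6e-3, alphaP = 2, betaP = 1.75,
                  mu2 = 1e-3, alphaM = 3, betaM = 2.4, rho = 0.02),
    segment = list(beta_a = 2, beta_b = 6, length_max = 10,
                   cells_per_cm = 100, n_quad = 16),
    onset = list(nu0 = list(M = 2e-4, F = 5e-5),
                 rr = 5,
                 cohort_multipliers = list(`1900` = 0.5, `1910` = 0.6,
                                           `1920` = 0.7, `1930` = 0.8,
                                           `1940` = 0.9, `1950` = 1.0,
                                           `1960` = 1.1, `1970` = 1.2),
                 gerd = list(p_max = list(M = 0.30, F = 0.25),
                             k = 0.12, t0 = 35)),
    grid = list(age_max = 100, step = 0.1),
    ages = list(min = 40, max = 90),
    seed = 0
  )
}

#' Load and validate a model configuration
#'
#' Reads a YAML (or JSON) configuration file, fills every missing key from
#' [default_config()] and validates all values against the type invariants
#' (rates nonnegative, rr >= 1, probabilities in `[0, 1]`, positive grid
#' step). Unknown keys are rejected with the list of valid keys.
#'
#' @param path path to a YAML/JSON config file, or `NULL` for the full
#'   default set.
#' @return validated configuration list of class `msce_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user, prefix = character())
  }
  validate_config(cfg)
  structure(cfg, class = c("msce_config", "list"))
}

# overlay user keys on defaults; unknown scalar-section keys are errors.
# cohort_multipliers, nu0, p_max are open mappings and replaced wholesale.
merge_config <- function(base, user, prefix) {
  open_maps <- c("onset.cohort_multipliers", "onset.nu0", "onset.gerd.p_max")
  for (key in names(user)) {
    here <- paste(c(prefix, key), collapse = ".")
    if (!key %in% names(base))
      stop("unknown config key '", here, "'; valid keys here: ",
           paste(names(base), collapse = ", "), call. = FALSE)
    if (is.list(base[[key]]) && !here %in% open_maps) {
      if (!is.list(user[[key]]))
        stop("config key '", here, "' must be a mapping", call. = FALSE)
      base[[key]] <- merge_config(base[[key]], user[[key]], c(prefix, key))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

validate_config <- function(cfg) {
  p <- cfg$params
  for (nm in c("mu0", "mu1", "alphaP", "betaP", "mu2", "alphaM", "betaM", "rho"))
    if (is.null(p[[nm]]) || p[[nm]] < 0 || !is.finite(p[[nm]]))
      stop("config params.", nm, " must be finite and >= 0", call. = FALSE)
  s <- cfg$segment
  if (s$beta_a <= 0 || s$beta_b <= 0 || s$length_max <= 0 || s$cells_per_cm <= 0)
    stop("config segment parameters must be positive", call. = FALSE)
  o <- cfg$onset
  if (any(unlist(o$nu0) < 0)) stop("config onset.nu0 must be >= 0", call. = FALSE)
  if (o$rr < 1) stop("config onset.rr must be >= 1", call. = FALSE)
  if (any(unlist(o$cohort_multipliers) <= 0))
    stop("config onset.cohort_multipliers must be positive", call. = FALSE)
  g <- o$gerd
  if (any(unlist(g$p_max) < 0 | unlist(g$p_max) > 1))
    stop("config onset.gerd.p_max must lie in [0, 1]", call. = FALSE)
  if (g$k <= 0) stop("config onset.gerd.k must be positive", call. = FALSE)
  if (cfg$grid$step <= 0 || cfg$grid$age_max <= 0)
    stop("config grid step and age_max must be positive", call. = FALSE)
  if (cfg$ages$min >= cfg$ages$max)
    stop("config ages.min must be below ages.max", call. = FALSE)
  invisible(cfg)
}

#' Write a configuration to YAML
#' @param cfg configuration list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_nu0 <- function(cfg, sex) {
  nu0 <- cfg$onset$nu0
  if (is.list(nu0) || length(nu0) > 1) {
    if (!sex %in% names(nu0)) stop("no nu0 for sex '", sex, "'", call. = FALSE)
    as.numeric(nu0[[sex]])
  } else as.numeric(nu0)
}

config_gerd <- function(cfg) {
  g <- cfg$onset$gerd
  pm <- unlist(g$p_max)
  gerd_model(p_max = pm, k = g$k, t0 = g$t0, rr = cfg$onset$rr)
}

config_onset_model <- function(cfg, sex) {
  be_onset_model(nu0 = config_nu0(cfg, sex), gerd = config_gerd(cfg), sex = sex,
                 cohort_multiplier = unlist(cfg$onset$cohort_multipliers))
}

config_params <- function(cfg) do.call(biological_params, cfg$params)

config_segment <- function(cfg) {
  s <- cfg$segment
  be_segment_model(s$beta_a, s$beta_b, s$length_max, s$cells_per_cm, s$n_quad)
}

#' Assemble the analytic model context from a configuration
#'
#' Solves the backward survival system once on the configured tau grid,
#' marginalises over the segment-length law, and returns a context from
#' which stratum-specific hazard curves are cheap to produce.
#'
#' @param config an [load_config()] configuration (or plain list with the
#'   same shape).
#' @return object of class `msce_model` holding the biological params,
#'   segment model, `be_survival` mixture and the uniform age grid.
#' @seealso [msce_hazard()]
#' @export
msce_model <- function(config) {
  params <- config_params(config)
  segment <- config_segment(config)
  age_grid <- seq(0, config$grid$age_max, by = config$grid$step)
  sol <- solve_backward_system(params, age_grid)
  structure(list(config = config, params = params, segment = segment,
                 be_surv = be_survival(sol, segment), age_grid = age_grid),
            class = "msce_model")
}

#' Stratum-specific hazard curve from a model context
#'
#' @param model an [msce_model()] context.
#' @param sex sex label (must have a `nu0` entry in the config).
#' @param cohort birth-cohort decade start year.
#' @param subgroup `"population"`, `"gerd"` or `"non_gerd"`.
#' @param rr optional relative-risk override for the GERD subgroup.
#' @return a `hazard_curve` (see [population_hazard()]).
#' @export
msce_hazard <- function(model, sex = "M",
                        cohort = names(model$config$onset$cohort_multipliers)[1],
                        subgroup = "population", rr = NULL) {
  stopifnot(inherits(model, "msce_model"))
  onset <- config_onset_model(model$config, sex)
  nu <- onset_rate(onset, model$age_grid, subgroup, cohort, rr)
  population_hazard(model$be_surv, nu, model$age_grid,
                    sex = sex, cohort = cohort, subgroup = subgroup)
}
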