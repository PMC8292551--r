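#' Tabulated logistic GERD prevalence curve
#'
#' Tabulates `p(t) = p_max / (1 + exp(-k (t - t0)))` on integer ages 0--100
#' for each sex, in the `(sex, age, prevalence)` schema consumed by
#' [gerd_model()].
#'
#' @param p_max asymptotic prevalence in `[0, 1]`; scalar or named by sex.
#' @param k logistic steepness (> 0), per year.
#' @param t0 age of half-maximal prevalence.
#' @param sexes sex labels.
#' @return data frame with columns `sex`, `age`, `prevalence`.
#' @export
make_gerd_curve <- function(p_max = 0.3, k = 0.12, t0 = 35, sexes = c("M", "F")) {
  if (any(p_max < 0 | p_max > 1)) stop("p_max must lie in [0, 1]", call. = FALSE)
  if (k <= 0) stop("k must be positive", call. = FALSE)
  ages <- 0:100
  rows <- lapply(sexes, function(sx) {
    pm <- if (length(p_max) > 1) p_max[[sx]] else p_max
    data.frame(sex = sx, age = ages,
               prevalence = pm / (1 + exp(-k * (ages - t0))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Census-style person-year table with a smooth age pyramid
#'
#' Spreads `total_py` person-years over single ages 0--100 per sex. The
#' default pyramid is flat up to `plateau_age` and declines linearly to zero
#' at `zero_age`; ages at or beyond `zero_age` get zero weight.
#'
#' @param year calendar year label.
#' @param total_py total person-years across all ages and sexes (> 0).
#' @param sexes sex labels; person-years are split by `sex_share`.
#' @param sex_share shares summing to 1, one per sex.
#' @param plateau_age age up to which the pyramid is flat.
#' @param zero_age age at which the linear decline reaches zero.
#' @return data frame with columns `year`, `sex`, `age`, `person_years`,
#'   summing to `total_py` within 1e-6 relative.
#' @export
make_census_table <- function(year = 2010, total_py = 1e6, sexes = c("M", "F"),
                              sex_share = rep(1 / length(sexes), length(sexes)),
                              plateau_age = 60, zero_age = 100) {
  if (total_py <= 0) stop("total_py must be positive", call. = FALSE)
  if (length(sex_share) != length(sexes) || abs(sum(sex_share) - 1) > 1e-9)
    stop("sex_share must have one share per sex and sum to 1", call. = FALSE)
  if (plateau_age < 0 || zero_age <= plateau_age)
    stop("invalid pyramid: need 0 <= plateau_age < zero_age", call. = FALSE)
  ages <- 0:100
  w <- ifelse(ages <= plateau_age, 1,
              pmax(0, (zero_age - ages) / (zero_age - plateau_age)))
  w <- w / sum(w)
  rows <- lapply(seq_along(sexes), function(i) {
    data.frame(year = year, sex = sexes[i], age = ages,
               person_years = total_py * sex_share[i] * w,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Poisson-sampled registry-style incidence table
#'
#' For each (sex, cohort, 5-year age bin on 40--89) stratum, draws
#' `cases ~ Poisson(PY_bin * h(mid))` with the analytic hazard of the
#' ground-truth configuration at the bin midpoint. Person-years per stratum
#' are split equally across the age bins. The generating configuration and
#' seed are attached as attributes for recovery tests.
#'
#' @param config ground-truth configuration.
#' @param sexes,cohorts strata to emulate.
#' @param py_per_stratum person-years per (sex, cohort) stratum (> 0).
#' @param breaks age-bin edges (default 5-year bins 40--89).
#' @param seed RNG seed; same seed reproduces the table exactly.
#' @return incidence table (`sex`, `cohort`, `age_low`, `age_high`, `cases`,
#'   `person_years`) with attributes `truth` (the config) and `seed`.
#' @export
synth_incidence_table <- function(config, sexes = c("M", "F"),
                                  cohorts = c(1930, 1940, 1950),
                                  py_per_stratum = 1e7,
                                  breaks = seq(40, 90, by = 5), seed = 0) {
  if (py_per_stratum <= 0) stop("py_per_stratum must be positive", call. = FALSE)
  model <- msce_model(config)
  nb <- length(breaks) - 1
  py_bin <- py_per_stratum / nb
  mids <- (breaks[-length(breaks)] + breaks[-1]) / 2
  set.seed(as.integer(seed) %% .Machine$integer.max)
  rows <- list()
  for (sx in sexes) {
    onset <- config_onset_model(config, sx)
    for (co in cohorts) {
      nu <- onset_rate(onset, model$age_grid, "population", co)
      curve <- population_hazard(model$be_surv, nu, model$age_grid,
                                 sex = sx, cohort = co)
      lam <- py_bin * curve_at(curve, mids)
      rows[[paste(sx, co)]] <- data.frame(
        sex = sx, cohort = co, age_low = breaks[-length(breaks)],
        age_high = breaks[-1], cases = stats::rpois(nb, lam),
        person_years = py_bin, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- config
  attr(out, "seed") <- seed
  out
}

#' Screening-yield cohort (endoscopy-style BE detection table)
#'
#' Samples cancer-free individuals with (age, sex, GERD status) and assigns
#' each a BE-found indicator drawn Bernoulli from the cancer-free BE
#' prevalence of their subgroup's hazard curve, emulating the yield of an
#' endoscopic screening programme.
#'
#' @param n number of screened individuals (>= 1).
#' @param config configuration.
#' @param ages ages to sample from (uniformly).
#' @param sexes sex labels to sample from (uniformly).
#' @param p_gerd_sample probability a sampled individual has GERD.
#' @param cohort birth-cohort decade used for the hazard curves.
#' @param seed RNG seed.
#' @return data frame with columns `age`, `sex`, `gerd`, `be_found`.
#' @export
make_screening_cohort <- function(n, config, ages = 40:79, sexes = c("M", "F"),
                                  p_gerd_sample = 0.3,
                                  cohort = names(config$onset$cohort_multipliers)[1],
                                  seed = 0) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (length(ages) == 0 || length(sexes) == 0)
    stop("sampling spec must be non-empty", call. = FALSE)
  model <- msce_model(config)
  curves <- list()
  for (sx in sexes) {
    onset <- config_onset_model(config, sx)
    for (sub in c("gerd", "non_gerd")) {
      nu <- onset_rate(onset, model$age_grid, sub, cohort)
      curves[[paste(sx, sub)]] <-
        population_hazard(model$be_surv, nu, model$age_grid,
                          sex = sx, cohort = cohort, subgroup = sub)
    }
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  # index-based sampling: safe when ages/sexes have length 1
  age <- ages[sample.int(length(ages), n, replace = TRUE)]
  sex <- sexes[sample.int(length(sexes), n, replace = TRUE)]
  gerd <- stats::runif(n) < p_gerd_sample
  p <- numeric(n)
  for (sx in sexes) {
    for (g in c(TRUE, FALSE)) {
      idx <- which(sex == sx & gerd == g)
      if (length(idx) == 0) next
      curve <- curves[[paste(sx, if (g) "gerd" else "non_gerd")]]
      p[idx] <- curve_at(curve, age[idx] + 0.5, "be_prevalence_cancer_free")
    }
  }
  data.frame(age = age, sex = sex, gerd = gerd,
             be_found = stats::runif(n) < p, stringsAsFactors = FALSE)
}
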