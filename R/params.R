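#' Biological rate parameters of the post-BE clonal expansion process
#'
#' Bundles the per-cell per-year rates governing progression inside a
#' Barrett's oesophagus (BE) segment: two-hit initiation of a premalignant
#' clone, stochastic clonal expansion of premalignant and malignant cells,
#' malignant transformation and size-based clinical detection.
#'
#' @param mu0 first-hit rate per BE stem cell per year.
#' @param mu1 second-hit rate per one-hit cell per year; each hit spawns the
#'   founder cell of the next compartment while the parent persists.
#' @param alphaP premalignant cell division rate per year.
#' @param betaP premalignant cell death/differentiation rate per year.
#' @param mu2 malignant transformation rate per premalignant cell per year.
#' @param alphaM malignant cell division rate per year.
#' @param betaM malignant cell death/differentiation rate per year.
#' @param rho detection rate per malignant cell per year, so a clone of n
#'   cells is detected at rate `n * rho` (size-based detection).
#' @return An object of class `biological_params` (a named list of rates).
#' @examples
#' p <- biological_params(mu0 = 1e-3, mu1 = 1e-3, alphaP = 2, betaP = 1.8,
#'                        mu2 = 1e-3, alphaM = 3, betaM = 2.4, rho = 0.02)
#' p$alphaP - p$betaP  # net premalignant growth rate
#' @export
biological_params <- function(mu0, mu1, alphaP, betaP, mu2, alphaM, betaM, rho) {
  p <- list(mu0 = mu0, mu1 = mu1, alphaP = alphaP, betaP = betaP,
            mu2 = mu2, alphaM = alphaM, betaM = betaM, rho = rho)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("biological_params: '", nm, "' must be a single finite nonnegative number",
           call. = FALSE)
    p[[nm]] <- as.numeric(v)
  }
  structure(p, class = "biological_params")
}

#' @export
print.biological_params <- function(x, ...) {
  cat("MSCE biological rates (per cell per year):\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' Barrett's segment-length model
#'
#' Segment lengths are Beta-distributed on `[0, length_max]` cm and converted
#' to BE stem-cell numbers at `cells_per_cm` stem cells per cm. The stem-cell
#' exponent is kept continuous (cell independence), so non-integer counts are
#' allowed in the analytic survival mixture.
#'
#' @param beta_a,beta_b positive shape parameters of the Beta length law.
#' @param length_max scale of the Beta support, cm.
#' @param cells_per_cm BE stem cells per cm of segment.
#' @param n_quad number of Gauss-Legendre nodes used to marginalise over the
#'   length distribution.
#' @return An object of class `be_segment_model` with precomputed quadrature
#'   nodes (`lengths`, cm) and weights (`weights`, normalised to sum to 1).
#' @seealso [segment_mean_length()], [be_survival()]
#' @export
be_segment_model <- function(beta_a = 2, beta_b = 6, length_max = 10,
                             cells_per_cm = 100, n_quad = 16) {
  if (beta_a <= 0 || beta_b <= 0) stop("Beta shape parameters must be positive", call. = FALSE)
  if (length_max <= 0) stop("length_max must be positive", call. = FALSE)
  if (cells_per_cm <= 0) stop("cells_per_cm must be positive", call. = FALSE)
  if (n_quad < 2) stop("n_quad must be at least 2", call. = FALSE)
  gl <- pracma::gaussLegendre(n_quad, 0, 1)
  dens <- stats::dbeta(gl$x, beta_a, beta_b)
  w <- gl$w * dens
  if (sum(w) <= 0) stop("degenerate segment-length quadrature: all weights zero", call. = FALSE)
  w <- w / sum(w)
  structure(list(beta_a = beta_a, beta_b = beta_b, length_max = length_max,
                 cells_per_cm = cells_per_cm, n_quad = n_quad,
                 lengths = gl$x * length_max, weights = w),
            class = "be_segment_model")
}

#' Mean BE segment length implied by a segment model
#'
#' @param segment a [be_segment_model()].
#' @return Mean length in cm, `beta_a / (beta_a + beta_b) * length_max`.
#' @export
segment_mean_length <- function(segment) {
  stopifnot(inherits(segment, "be_segment_model"))
  segment$beta_a / (segment$beta_a + segment$beta_b) * segment$length_max
}

#' Stem-cell exponents at the quadrature nodes
#' @param segment a [be_segment_model()].
#' @return numeric vector `cells_per_cm * lengths` at the quadrature nodes.
#' @keywords internal
segment_cells <- function(segment) segment$cells_per_cm * segment$lengths
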