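#' Sampling configuration probabilities at one site
#'
#' For a site at population frequency `x` of the derived allele, a random
#' sample of `k` sequences is polymorphic unless every sequence carries the
#' same allele, so
#' \eqn{P(\mathrm{poly}) = 1 - x^k - (1-x)^k} and
#' \eqn{P(\mathrm{all\ derived}) = x^k}.
#'
#' @param x Frequency (or vector of frequencies) in \eqn{[0,1]}.
#' @param k Sample size (integer >= 1).
#' @return A list with vectors `prob_poly` and `prob_all_derived`.
#' @export
sampling_probabilities <- function(x, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("`x` must lie in [0, 1]", call. = FALSE)
  }
  list(prob_poly = 1 - x^k - (1 - x)^k,
       prob_all_derived = x^k)
}

# Relative stationary frequency spectrum g_gamma(x) (theta = 1), i.e. the
# expected density of segregating sites at mutation-selection-drift
# equilibrium per unit scaled mutation rate:
#   g_gamma(x) = (1 - e^{-2 gamma (1 - x)}) / ((1 - e^{-2 gamma}) x (1 - x)),
# with the neutral limit 1/x.  Evaluated in a form stable for large |gamma|.
spectrum_shape <- function(x, gamma) {
  if (abs(gamma) < 1e-9) return(1 / x)
  if (gamma > 0) {
    ratio <- exp(log1p(-exp(-2 * gamma * (1 - x))) - log1p(-exp(-2 * gamma)))
  } else {
    # multiply numerator and denominator by e^{2 gamma} so every
    # exponential decays: ratio = (e^{-ax} - e^{-a})/(1 - e^{-a}), a = -2 gamma
    a <- -2 * gamma
    ratio <- (exp(-a * x) - exp(-a)) / (1 - exp(-a))
  }
  ratio / (x * (1 - x))
}

#' Stationary frequency spectrum of segregating sites
#'
#' Density (per unit frequency) of the expected number of segregating sites
#' under the equilibrium Poisson random field with scaled mutation rate
#' `theta` (\eqn{\theta = 2 N_e \mu}) and scaled selection coefficient
#' `gamma` (\eqn{\gamma = N_e s}):
#' \deqn{f(x) = \theta \frac{1 - e^{-2\gamma(1-x)}}{(1 - e^{-2\gamma})\,
#'   x(1-x)},}
#' with neutral limit \eqn{\theta/x}.  This is the initial condition for
#' legacy polymorphisms at the species split.
#'
#' @param theta Scaled mutation rate (> 0).
#' @param gamma Scaled selection coefficient.
#' @return A vectorised function of frequency on \eqn{(0,1)}.
#' @export
stationary_density <- function(theta, gamma) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0) {
    stop("`theta` must be positive", call. = FALSE)
  }
  force(gamma)
  function(x) theta * spectrum_shape(x, gamma)
}

#' Fixation probability of the Wright-Fisher diffusion
#'
#' \eqn{P_p(\mathrm{fix}) = (1 - e^{-2\gamma p}) / (1 - e^{-2\gamma})}, the
#' classical formula under the haploid scaling \eqn{\gamma = N_e s};
#' neutral limit \eqn{p}.
#'
#' @param p Initial frequency in \eqn{[0,1]}.
#' @param gamma Scaled selection coefficient.
#' @return Fixation probability (vectorised over `p`).
#' @export
fixation_probability <- function(p, gamma) {
  if (any(p < 0) || any(p > 1)) stop("`p` must lie in [0,1]", call. = FALSE)
  if (abs(gamma) < 1e-9) return(p)
  expm1(-2 * gamma * p) / expm1(-2 * gamma)
}

#' Per-locus model parameters
#'
#' @param theta_s,theta_r Scaled silent / replacement mutation rates (> 0).
#' @param gamma Scaled selection coefficient of replacement mutations
#'   (silent sites are neutral).
#' @param m,n Sample sizes in species 1 and species 2 (integers >= 1).
#' @param locus_id Optional label.
#' @return An object of class `"locus_parameters"`.
#' @export
locus_parameters <- function(theta_s, theta_r, gamma, m, n, locus_id = NULL) {
  stopifnot(is.numeric(theta_s), theta_s > 0, is.numeric(theta_r), theta_r > 0,
            is.finite(gamma))
  if (m < 1 || n < 1 || m != round(m) || n != round(n)) {
    stop("sample sizes `m`, `n` must be integers >= 1", call. = FALSE)
  }
  structure(
    list(theta_s = theta_s, theta_r = theta_r, gamma = gamma,
         m = as.integer(m), n = as.integer(n), locus_id = locus_id),
    class = "locus_parameters"
  )
}

#' Convert scaled divergence time to years
#'
#' One diffusion time unit equals \eqn{N_e} haploid generations, so
#' `years = t * N_e / generations_per_year`.
#'
#' @param t Scaled divergence time (>= 0).
#' @param N_e Haploid effective population size (> 0).
#' @param generations_per_year Generations per year (> 0).
#' @return Time in years.
#' @export
scaled_time_to_years <- function(t, N_e, generations_per_year) {
  if (!is.numeric(t) || any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  if (!is.numeric(N_e) || N_e <= 0 || !is.numeric(generations_per_year) ||
      generations_per_year <= 0) {
    stop("`N_e` and `generations_per_year` must be positive", call. = FALSE)
  }
  t * N_e / generations_per_year
}
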