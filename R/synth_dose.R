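#' Simulate a dose-response growth curve
#'
#' Growth fraction follows the two-parameter logistic (Hill) form
#' \deqn{g(c) = 1 / (1 + (c / IC50)^h) + \epsilon,}
#' so \eqn{g(IC50) = 0.5} exactly (50\% growth inhibition) and
#' \eqn{g(0) = 1} in the noiseless limit. Additive Gaussian noise with
#' standard deviation `noise_sd` is applied and the result clipped at 0.
#'
#' @param ic50 True half-maximal inhibitory concentration (mM, > 0).
#' @param hill_slope Hill coefficient (> 0).
#' @param concentrations Numeric vector of concentrations (mM, >= 0).
#' @param noise_sd Additive noise standard deviation (growth-fraction units).
#' @param seed Integer seed.
#' @param compound Optional compound name carried on the result.
#' @return A `dose_response_curve`: data.frame with columns `concentration`
#'   and `growth_fraction`, sorted by concentration.
#' @export
simulate_dose_response <- function(ic50, hill_slope, concentrations,
                                   noise_sd = 0, seed = 1L, compound = NULL) {
  check_scalar_number(ic50, "ic50", min = 0, strict_min = TRUE)
  if (!is.numeric(hill_slope) || length(hill_slope) != 1L || hill_slope <= 0) {
    ps_abort("hill_slope must be > 0", "config_error")
  }
  if (any(concentrations < 0)) {
    ps_abort("concentrations must be >= 0", "config_error")
  }
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  g <- 1 / (1 + (concentrations / ic50)^hill_slope)
  if (noise_sd > 0) {
    g <- g + with_seed(seed, stats::rnorm(length(g), 0, noise_sd))
  }
  dose_response_curve(concentrations, pmax(g, 0), compound = compound)
}
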