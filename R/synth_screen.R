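#' Simulate a deletion-library chemical-genomic screen with known truth
#'
#' Generates a synthetic screen in the structure the scoring pipeline
#' consumes: per strain, compound and replicate, a colony density on the
#' treated plate and on its paired solvent-control plate. Each strain
#' carries a true relative fitness \eqn{\rho} per compound (\eqn{\rho = 1}
#' neutral, \eqn{\rho < 1} inhibited, \eqn{\rho > 1} resistant); treated
#' densities are \code{base_density * rho * noise} and control densities
#' \code{base_density * noise}, with multiplicative lognormal noise of mean
#' 1 and coefficient of variation `noise_cv` (densitometry errors scale with
#' intensity, hence the multiplicative model). A wild-type reference strain
#' with \eqn{\rho = 1} under every compound is always included.
#'
#' @param n_strains Number of deletion strains (the wild type is added on
#'   top of these).
#' @param compounds Character vector of compound names.
#' @param frac_sensitive Fraction of strains planted as sensitive per
#'   compound (drawn independently per compound).
#' @param frac_resistant Fraction planted as resistant per compound.
#' @param effect_ranges List with elements `sensitive` and `resistant`, each
#'   a length-2 interval from which true \eqn{\rho} values are drawn
#'   uniformly. Defaults \code{[0.1, 0.4]} and \code{[2.5, 6]}, spanning the
#'   kind of growth-score extremes focused spot screens report.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise (0 = noiseless).
#' @param n_replicates Number of trials (>= 1).
#' @param base_density Mean colony density of an unperturbed strain, in the
#'   arbitrary units of the densitometry stage.
#' @param seed Integer seed; identical seeds give bitwise-identical output.
#' @param wt_strain Name of the wild-type strain.
#' @return A list with components:
#'   \describe{
#'     \item{truth}{`screen_truth` object: `strains`, `effect` (strain x
#'       compound matrix of true \eqn{\rho}), `sensitive_truth` and
#'       `resistant_truth` (data.frames of planted strain/compound pairs),
#'       `noise_cv`, `seed`.}
#'     \item{densities}{data.frame with columns `strain`, `compound`,
#'       `replicate`, `density_treated`, `density_control`.}
#'   }
#' @export
simulate_screen <- function(n_strains = 1000,
                            compounds = c("BHA", "BHT", "BPA"),
                            frac_sensitive = 0.1,
                            frac_resistant = 0.02,
                            effect_ranges = list(sensitive = c(0.1, 0.4),
                                                 resistant = c(2.5, 6)),
                            noise_cv = 0.15,
                            n_replicates = 3,
                            base_density = 1000,
                            seed = 1L,
                            wt_strain = "wt") {
  check_scalar_number(n_strains, "n_strains", min = 1)
  check_scalar_number(frac_sensitive, "frac_sensitive", min = 0, max = 1)
  check_scalar_number(frac_resistant, "frac_resistant", min = 0, max = 1)
  if (frac_sensitive + frac_resistant > 1) {
    ps_abort("frac_sensitive + frac_resistant must be <= 1", "config_error")
  }
  check_scalar_number(n_replicates, "n_replicates", min = 1)
  check_scalar_number(noise_cv, "noise_cv", min = 0)
  check_scalar_number(base_density, "base_density", min = 0,
                      strict_min = TRUE)
  for (nm in c("sensitive", "resistant")) {
    rg <- effect_ranges[[nm]]
    if (is.null(rg) || length(rg) != 2L || any(rg <= 0) || rg[1] > rg[2]) {
      ps_abort(sprintf("effect_ranges$%s must be a positive interval", nm),
               "config_error")
    }
  }
  if (any(effect_ranges$sensitive >= 1) || any(effect_ranges$resistant <= 1)) {
    ps_abort("sensitive effects must lie below 1 and resistant above 1",
             "config_error")
  }

  with_seed(seed, {
    strains <- sprintf("strain%05d", seq_len(n_strains))
    all_strains <- c(wt_strain, strains)
    effect <- matrix(1, nrow = length(all_strains), ncol = length(compounds),
                     dimnames = list(all_strains, compounds))
    n_sens <- round(frac_sensitive * n_strains)
    n_res <- round(frac_resistant * n_strains)
    for (cp in compounds) {
      hit <- sample(strains, n_sens + n_res)
      sens <- hit[seq_len(n_sens)]
      res <- if (n_res > 0) hit[n_sens + seq_len(n_res)] else character(0)
      effect[sens, cp] <- stats::runif(n_sens, effect_ranges$sensitive[1],
                                       effect_ranges$sensitive[2])
      effect[res, cp] <- stats::runif(n_res, effect_ranges$resistant[1],
                                      effect_ranges$resistant[2])
    }
    grid <- expand.grid(strain = all_strains, compound = compounds,
                        replicate = seq_len(n_replicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rho <- effect[cbind(grid$strain, grid$compound)]
    n <- nrow(grid)
    grid$density_treated <- base_density * rho * lognormal_noise(n, noise_cv)
    grid$density_control <- base_density * lognormal_noise(n, noise_cv)

    sens_idx <- which(effect <= 0.5, arr.ind = TRUE)
    res_idx <- which(effect >= 2.0, arr.ind = TRUE)
    truth <- structure(
      list(strains = all_strains,
           effect = effect,
           sensitive_truth = data.frame(
             strain = all_strains[sens_idx[, 1]],
             compound = compounds[sens_idx[, 2]]),
           resistant_truth = data.frame(
             strain = all_strains[res_idx[, 1]],
             compound = compounds[res_idx[, 2]]),
           noise_cv = noise_cv, seed = as.integer(seed),
           wt_strain = wt_strain),
      class = "screen_truth")
    list(truth = truth, densities = grid)
  })
}

#' @export
print.screen_truth <- function(x, ...) {
  cat(sprintf(
    "screen_truth: %d strains x %d compounds; %d planted sensitive, %d resistant (noise_cv = %.3g)\n",
    length(x$strains), ncol(x$effect), nrow(x$sensitive_truth),
    nrow(x$resistant_truth), x$noise_cv))
  invisible(x)
}
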