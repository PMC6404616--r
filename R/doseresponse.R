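#' Dose-response curve container
#'
#' @param concentration Numeric vector of compound concentrations (mM,
#'   >= 0); duplicates are averaged, the result is sorted.
#' @param growth_fraction Culture density relative to the solvent-only
#'   control at matched time (dimensionless, >= 0; values slightly above 1
#'   occur with noise).
#' @param compound Optional compound name.
#' @return data.frame of class `dose_response_curve` with columns
#'   `concentration`, `growth_fraction`.
#' @export
dose_response_curve <- function(concentration, growth_fraction,
                                compound = NULL) {
  if (length(concentration) != length(growth_fraction)) {
    ps_abort("concentration and growth_fraction lengths differ",
             "value_error")
  }
  if (any(concentration < 0)) {
    ps_abort("concentrations must be >= 0", "value_error")
  }
  if (any(growth_fraction < 0)) {
    ps_abort("growth fractions must be >= 0", "value_error")
  }
  agg <- stats::aggregate(
    list(growth_fraction = growth_fraction),
    by = list(concentration = concentration), FUN = mean)
  agg <- agg[order(agg$concentration), ]
  rownames(agg) <- NULL
  structure(agg, class = c("dose_response_curve", "data.frame"),
            compound = compound)
}

#' Percent growth inhibition
#'
#' `100 * (1 - od_treated / od_control)`, clipped below at 0 (cultures that
#' outgrow the control report 0\% inhibition, not negative inhibition).
#'
#' @param od_treated,od_control Culture densities (e.g. OD600) of the
#'   treated and solvent-control cultures; vectors recycle as usual.
#' @return Percent inhibition in `[0, 100]`.
#' @export
growth_inhibition <- function(od_treated, od_control) {
  if (any(od_control <= 0)) {
    ps_abort("control density must be > 0", "value_error")
  }
  if (any(od_treated < 0)) {
    ps_abort("treated density must be >= 0", "value_error")
  }
  pmax(0, 100 * (1 - od_treated / od_control))
}

#' Estimate an inhibitory concentration (IC level) from a dose-response curve
#'
#' `IC_x` is the concentration producing `x`\% growth inhibition. Two
#' estimators:
#' \describe{
#'   \item{interp}{monotone linear interpolation of inhibition against
#'     log10 concentration between the two observations bracketing the
#'     requested level (linear in concentration when the lower bracket is
#'     the zero-dose point). Requires the observed inhibition to span the
#'     level, otherwise an extrapolation error is raised.}
#'   \item{logistic}{least-squares fit of the two-parameter logistic
#'     \eqn{g(c) = 1/(1 + (c/IC50)^h)} (>= 4 points), inverted analytically
#'     at the requested level: \eqn{IC_x = IC50 (x/(100-x))^{1/h}}.}
#' }
#'
#' @param curve A [dose_response_curve()] (or data.frame with columns
#'   `concentration`, `growth_fraction`).
#' @param level Requested inhibition level in percent, 0 < level < 100 (the
#'   screening window of interest is 50-80).
#' @param method `"interp"` or `"logistic"`.
#' @return The estimated concentration (same units as the curve).
#' @export
estimate_ic <- function(curve, level = 50,
                        method = c("interp", "logistic")) {
  method <- match.arg(method)
  check_scalar_number(level, "level", min = 0, max = 100,
                      strict_min = TRUE)
  if (level >= 100) ps_abort("level must be < 100", "value_error")
  conc <- curve$concentration
  inh <- growth_inhibition(curve$growth_fraction, 1)

  if (method == "interp") {
    hit <- which(inh == level)
    if (length(hit)) return(conc[hit[1]])
    above <- which(inh > level)
    if (!length(above) || min(above) == 1) {
      ps_abort(sprintf(
        "requested IC%g outside the observed inhibition range (max %.1f%%)",
        level, max(inh)), "extrapolation_error")
    }
    j <- min(above)   # first observation above the level; j-1 is below it
    i <- j - 1
    if (conc[i] > 0) {
      lx <- log10(conc[c(i, j)])
      10^(lx[1] + (level - inh[i]) * diff(lx) / (inh[j] - inh[i]))
    } else {
      conc[i] + (level - inh[i]) * (conc[j] - conc[i]) / (inh[j] - inh[i])
    }
  } else {
    if (length(conc) < 4) {
      ps_abort("logistic fit needs at least 4 points", "fit_error")
    }
    start_ic <- conc[which.min(abs(inh - 50))]
    if (start_ic <= 0) start_ic <- stats::median(conc[conc > 0])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        growth_fraction ~ 1 / (1 + (concentration / ic50)^h),
        data = as.data.frame(curve),
        start = list(ic50 = start_ic, h = 1),
        lower = c(1e-12, 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        ps_abort(sprintf("logistic fit did not converge: %s",
                         conditionMessage(e)), "fit_error")
      })
    cf <- stats::coef(fit)
    unname(cf["ic50"] * (level / (100 - level))^(1 / cf["h"]))
  }
}
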