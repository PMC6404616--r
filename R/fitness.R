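#' Screen scoring configuration
#'
#' Holds the thresholds and rules of the growth-score stage: the sensitivity
#' and resistance cutoffs applied to GSVs (inclusive boundaries: a GSV equal
#' to the cutoff is called), the replicate-consensus rule `m` of `t`, the
#' wild-type strain identifier used for plate normalization, and the log
#' floor used when profiles are built.
#'
#' @param t_sens Sensitivity cutoff (call SENSITIVE when GSV <= `t_sens`);
#'   default 0.5.
#' @param t_res Resistance cutoff (call RESISTANT when GSV >= `t_res`);
#'   default 2.0.
#' @param consensus_m,consensus_t Consensus rule: a category becomes the
#'   final call when it is reached in at least `consensus_m` of
#'   `consensus_t` trials. Genome-scale screens conventionally use 2 of 2;
#'   focused rescreens 3 of 4.
#' @param wt_strain Wild-type strain identifier.
#' @param log_floor Floor applied to GSVs before log2 conversion in profile
#'   matrices.
#' @param alpha Significance level for enrichment calls.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(t_sens = 0.5, t_res = 2.0,
                          consensus_m = 2L, consensus_t = 2L,
                          wt_strain = "wt", log_floor = 0.05,
                          alpha = 0.05) {
  check_scalar_number(t_sens, "t_sens", min = 0, strict_min = TRUE)
  check_scalar_number(t_res, "t_res", min = 0, strict_min = TRUE)
  if (!(t_sens < 1 && 1 < t_res)) {
    ps_abort("thresholds must satisfy 0 < t_sens < 1 < t_res", "config_error")
  }
  check_scalar_number(consensus_m, "consensus_m", min = 1)
  check_scalar_number(consensus_t, "consensus_t", min = consensus_m)
  check_scalar_number(log_floor, "log_floor", min = 0, strict_min = TRUE)
  check_scalar_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  structure(
    list(t_sens = t_sens, t_res = t_res,
         consensus_m = as.integer(consensus_m),
         consensus_t = as.integer(consensus_t),
         wt_strain = wt_strain, log_floor = log_floor, alpha = alpha),
    class = "screen_config"
  )
}

#' Growth score value (GSV)
#'
#' The GSV of a strain is the ratio of its treated over untreated colony
#' density, normalized by the wild-type treated over untreated ratio on the
#' same plates:
#' \deqn{GSV = (d_T / d_U) / (wt_T / wt_U).}
#' A GSV of 1 means wild-type-like growth; values at or below the
#' sensitivity cutoff mark sensitive strains, values at or above the
#' resistance cutoff resistant ones. The score is scale-free: multiplying
#' all densities of either plate by any constant leaves it unchanged.
#'
#' @param d_treated,d_untreated Strain colony densities on the treated and
#'   untreated (solvent-control) plates; vectors of equal length.
#' @param wt_treated,wt_untreated Wild-type densities on the same plates
#'   (scalars; when several wild-type positions exist, pass their mean).
#' @return Numeric vector of GSVs (>= 0).
#' @export
compute_gsv <- function(d_treated, d_untreated, wt_treated, wt_untreated) {
  if (any(d_treated < 0)) {
    ps_abort("treated densities must be >= 0", "value_error")
  }
  if (any(!is.finite(d_untreated) | d_untreated <= 0)) {
    ps_abort("untreated density is zero or undefined; GSV undefined",
             "undefined_gsv_error")
  }
  if (!is.finite(wt_untreated) || wt_untreated <= 0 ||
      !is.finite(wt_treated) || wt_treated <= 0) {
    ps_abort("wild-type normalization densities must be positive; plate rejected",
             "plate_normalization_error")
  }
  (d_treated / d_untreated) / (wt_treated / wt_untreated)
}

#' Classify a GSV as sensitive, normal or resistant
#'
#' Boundaries are inclusive: `gsv <= t_sens` is SENSITIVE and
#' `gsv >= t_res` is RESISTANT. `NA` GSVs come back as NO_CALL.
#'
#' @param gsv Numeric vector of GSVs (>= 0, or `NA`).
#' @param config A [screen_config()].
#' @return Character vector with values in
#'   `c("SENSITIVE", "NORMAL", "RESISTANT", "NO_CALL")`.
#' @export
classify_sensitivity <- function(gsv, config = screen_config()) {
  if (any(gsv < 0, na.rm = TRUE)) {
    ps_abort("GSVs must be >= 0", "value_error")
  }
  out <- rep("NORMAL", length(gsv))
  out[gsv <= config$t_sens] <- "SENSITIVE"
  out[gsv >= config$t_res] <- "RESISTANT"
  out[is.na(gsv)] <- "NO_CALL"
  out
}

#' Aggregate replicate GSVs into one growth score
#'
#' The strain's GSV is the arithmetic mean of its defined trial values
#' (undefined trials, e.g. zero untreated density, enter as `NA` and are
#' excluded). When every trial is undefined the strain gets a NO_CALL
#' record, never a silent drop.
#'
#' @param replicate_gsvs Numeric vector of per-trial GSVs (`NA` = undefined).
#' @param strain,compound Optional identifiers carried on the result.
#' @return An object of class `growth_score`: list with `strain`,
#'   `compound`, `gsv` (mean; `NA` when no trial is defined),
#'   `replicate_gsvs`, `n_replicates` (count of defined trials).
#' @export
aggregate_replicates <- function(replicate_gsvs, strain = NA_character_,
                                 compound = NA_character_) {
  defined <- replicate_gsvs[!is.na(replicate_gsvs)]
  structure(
    list(strain = strain, compound = compound,
         gsv = if (length(defined)) mean(defined) else NA_real_,
         replicate_gsvs = replicate_gsvs,
         n_replicates = length(defined)),
    class = "growth_score"
  )
}

#' @export
print.growth_score <- function(x, ...) {
  cat(sprintf("growth_score %s / %s: gsv = %s over %d defined trial(s)\n",
              x$strain, x$compound,
              ifelse(is.na(x$gsv), "NA", format(x$gsv, digits = 4)),
              x$n_replicates))
  invisible(x)
}

#' Consensus call across trials
#'
#' The final call is the category reached in at least `m` evaluable trials.
#' If no category reaches `m`, if two categories tie at `>= m`, or if fewer
#' than `m` trials are evaluable, the result is NO_CALL (ties always break
#' toward NO_CALL). The 3-of-4 rule reproduces the convention of calling a
#' strain sensitive when it shows impaired growth in at least three of four
#' screening trials.
#'
#' @param calls Character vector of per-trial calls
#'   (`SENSITIVE`/`NORMAL`/`RESISTANT`/`NO_CALL`).
#' @param m Required number of concordant trials (1 <= m <= length(calls)).
#' @return A single call string.
#' @export
consensus_call <- function(calls, m) {
  t <- length(calls)
  if (m < 1 || m > t) {
    ps_abort("consensus rule requires 1 <= m <= number of trials",
             "config_error")
  }
  evaluable <- calls[calls != "NO_CALL" & !is.na(calls)]
  if (length(evaluable) < m) return("NO_CALL")
  counts <- table(evaluable)
  winners <- names(counts)[counts >= m]
  if (length(winners) == 1L) winners else "NO_CALL"
}

#' Score a screen: GSVs, replicate aggregation and calls
#'
#' Takes the per-strain density table a screen produces (one treated and one
#' control density per strain, compound and replicate), normalizes each
#' treated/control plate pair by the mean wild-type densities on those
#' plates, computes per-trial GSVs, averages them per strain and compound,
#' and classifies. Two call columns are reported: `call` applies the
#' thresholds to the averaged GSV (the primary caller), and
#' `consensus_call` applies the m-of-t rule to the per-trial calls (when the
#' table holds fewer trials than `consensus_m`, the rule is capped at the
#' available trial count).
#'
#' @param densities data.frame with columns `strain`, `compound`,
#'   `replicate`, `density_treated`, `density_control` (the format
#'   [simulate_screen()] emits and [quant_to_strain_densities()] feeds).
#' @param config A [screen_config()].
#' @return data.frame of class `screen_scores` with columns `strain`,
#'   `compound`, `gsv`, `n_replicates`, `call`, `consensus_call`, plus one
#'   `gsv_rep<k>` column per trial.
#' @export
score_screen <- function(densities, config = screen_config()) {
  req <- c("strain", "compound", "replicate", "density_treated",
           "density_control")
  if (!all(req %in% names(densities))) {
    ps_abort(sprintf("density table must have columns %s",
                     paste(req, collapse = ", ")), "config_error")
  }
  if (!nrow(densities)) ps_abort("empty density table", "empty_input_error")
  wt <- densities[densities$strain == config$wt_strain, ]
  if (!nrow(wt)) {
    ps_abort(sprintf("wild-type strain '%s' absent from the density table",
                     config$wt_strain), "plate_normalization_error")
  }

  # per (compound, replicate) wild-type normalization: mean over wt rows
  wt_t <- tapply(wt$density_treated, list(wt$compound, wt$replicate), mean)
  wt_u <- tapply(wt$density_control, list(wt$compound, wt$replicate), mean)
  if (any(!is.finite(wt_t) | wt_t <= 0 | !is.finite(wt_u) | wt_u <= 0,
          na.rm = TRUE)) {
    ps_abort("wild-type densities non-positive on some plate; plate rejected",
             "plate_normalization_error")
  }

  d <- densities
  key <- cbind(as.character(d$compound), as.character(d$replicate))
  d$gsv_rep <- rep(NA_real_, nrow(d))
  undefined <- !is.finite(d$density_control) | d$density_control <= 0
  if (any(undefined)) {
    ps_warn(sprintf("%d strain/replicate record(s) with zero untreated density: GSV undefined",
                    sum(undefined)), "undefined_gsv")
  }
  ok <- !undefined
  wt_ratio <- wt_t[key[ok, , drop = FALSE]] / wt_u[key[ok, , drop = FALSE]]
  d$gsv_rep[ok] <- (d$density_treated[ok] / d$density_control[ok]) / wt_ratio

  reps <- sort(unique(d$replicate))
  strains <- unique(d$strain)
  compounds <- unique(d$compound)
  out <- expand.grid(strain = strains, compound = compounds,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gsv_mat <- matrix(NA_real_, nrow(out), length(reps),
                    dimnames = list(NULL, paste0("gsv_rep", reps)))
  out_key <- paste(out$strain, out$compound)
  d_key <- paste(d$strain, d$compound)
  for (k in seq_along(reps)) {
    sel <- d$replicate == reps[k]
    gsv_mat[match(d_key[sel], out_key), k] <- d$gsv_rep[sel]
  }
  out$gsv <- apply(gsv_mat, 1, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  out$n_replicates <- rowSums(!is.na(gsv_mat))
  out$call <- classify_sensitivity(out$gsv, config)
  per_trial <- apply(gsv_mat, 1, classify_sensitivity, config = config)
  if (is.null(dim(per_trial))) per_trial <- matrix(per_trial, nrow = 1)
  out$consensus_call <- apply(per_trial, 2, consensus_call,
                              m = min(config$consensus_m, length(reps)))
  out <- cbind(out, gsv_mat)
  class(out) <- c("screen_scores", "data.frame")
  out
}

#' Select a screening concentration from a library growth table
#'
#' Screening doses are chosen so that only about 10\% of library mutants
#' still display wild-type-like growth while more than 10\% of mutants can
#' still grow at all — strong enough to expose sensitivity differences,
#' weak enough to keep most of the library scorable. Among the candidate
#' concentrations satisfying the growth constraint, the one whose
#' wild-type-like fraction is closest to the target is returned (ties break
#' toward the lower concentration).
#'
#' @param growth_table data.frame with columns `concentration`, `wt_like`
#'   (logical: does this strain grow like wild type at this concentration?)
#'   and `grows` (logical: does it grow at all?), one row per strain x
#'   concentration. Alternatively a pre-summarized data.frame with columns
#'   `concentration`, `frac_wt_like`, `frac_growing`.
#' @param target_wt_frac Target fraction of wild-type-like mutants (0.10).
#' @param min_growing_frac Minimum fraction of growing mutants (strict
#'   lower bound, 0.10).
#' @return A list with `concentration`, `frac_wt_like`, `frac_growing` and
#'   the per-concentration summary table (`candidates`).
#' @export
select_screening_concentration <- function(growth_table,
                                           target_wt_frac = 0.10,
                                           min_growing_frac = 0.10) {
  if (all(c("frac_wt_like", "frac_growing") %in% names(growth_table))) {
    summ <- growth_table[, c("concentration", "frac_wt_like", "frac_growing")]
  } else {
    req <- c("concentration", "wt_like", "grows")
    if (!all(req %in% names(growth_table))) {
      ps_abort("growth table needs concentration + wt_like/grows (or the frac_* summary columns)",
               "config_error")
    }
    concs <- sort(unique(growth_table$concentration))
    summ <- data.frame(
      concentration = concs,
      frac_wt_like = vapply(concs, function(cc) {
        mean(growth_table$wt_like[growth_table$concentration == cc])
      }, numeric(1)),
      frac_growing = vapply(concs, function(cc) {
        mean(growth_table$grows[growth_table$concentration == cc])
      }, numeric(1))
    )
  }
  if (nrow(summ) < 2) {
    ps_abort("need at least two candidate concentrations", "config_error")
  }
  eligible <- summ$frac_growing > min_growing_frac
  if (!any(eligible)) {
    ps_abort(sprintf(
      "no concentration leaves more than %.0f%% of mutants growing",
      100 * min_growing_frac), "no_valid_concentration_error")
  }
  cand <- summ[eligible, ]
  cand <- cand[order(abs(cand$frac_wt_like - target_wt_frac),
                     cand$concentration), ]
  list(concentration = cand$concentration[1],
       frac_wt_like = cand$frac_wt_like[1],
       frac_growing = cand$frac_growing[1],
       candidates = summ)
}
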