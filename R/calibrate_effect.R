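#' Calibrate the wealth effect to hit a target concentration index
#'
#' Finds the logit-scale wealth effect `beta` for one indicator such that the
#' mean concentration index estimated by the full pipeline (PCA wealth index,
#' weighted ranks, covariance-form index) over `R` independent simulation
#' replicates equals `target_ci` to within `tol`.  The search is monotone
#' bisection on `beta`; all replicates reuse the same substream seeds across
#' bisection steps (common random numbers), so the objective is a
#' deterministic nondecreasing function of `beta` and the bisection is
#' well-posed.  `target_ci = 0` returns `beta = 0` exactly, by the symmetry
#' of the logit link in the latent wealth.
#'
#' @param target_ci target concentration index, |target_ci| < 0.9.
#' @param config a [sim_config()]; its first indicator (or `indicator`) is
#'   recalibrated, all other settings are kept.
#' @param indicator name of the indicator whose `beta` is calibrated.
#' @param R simulation replicates per objective evaluation.
#' @param tol convergence tolerance on the achieved mean index.
#' @param beta_bracket initial search interval; an error is raised if it does
#'   not bracket the target.
#' @param max_iter bisection iteration cap.
#' @return object of class `ci_calibration`: list with `beta`, `achieved`
#'   (mean estimated index at `beta`), `R`, `target_ci`, `iterations`.
#' @export
calibrate_effect <- function(target_ci, config, indicator = NULL,
                             R = 20, tol = 0.01,
                             beta_bracket = c(-4, 4), max_iter = 40) {
  stopifnot(inherits(config, "sim_config"))
  if (abs(target_ci) >= 0.9) stop("|target_ci| must be below 0.9")
  if (is.null(indicator)) indicator <- config$indicators_spec$name[1]
  if (!indicator %in% config$indicators_spec$name) {
    stop(sprintf("unknown indicator '%s'", indicator))
  }
  if (target_ci == 0) {
    return(structure(list(beta = 0, achieved = 0, R = R, target_ci = 0,
                          iterations = 0L),
                     class = "ci_calibration"))
  }

  rep_seeds <- vapply(seq_len(R), function(r) stage_seed(config$seed, "calibration", r),
                      integer(1))
  mean_ci <- function(beta) {
    cis <- vapply(rep_seeds, function(s) {
      cfg <- config
      cfg$indicators_spec$beta[cfg$indicators_spec$name == indicator] <- beta
      cfg$seed <- s
      estimate_survey_ci(generate_survey(cfg), indicator)
    }, numeric(1))
    mean(cis)
  }

  lo <- beta_bracket[1]; hi <- beta_bracket[2]
  f_lo <- mean_ci(lo); f_hi <- mean_ci(hi)
  if ((f_lo - target_ci) * (f_hi - target_ci) > 0) {
    stop(sprintf("calibration error: beta bracket [%g, %g] does not bracket target %g (achieves [%g, %g])",
                 lo, hi, target_ci, f_lo, f_hi))
  }
  achieved <- NA_real_; beta <- NA_real_
  for (it in seq_len(max_iter)) {
    beta <- (lo + hi) / 2
    achieved <- mean_ci(beta)
    if (abs(achieved - target_ci) <= tol) break
    if ((achieved - target_ci) * (f_lo - target_ci) > 0) {
      lo <- beta; f_lo <- achieved
    } else {
      hi <- beta
    }
  }
  structure(list(beta = beta, achieved = achieved, R = R,
                 target_ci = target_ci, iterations = it),
            class = "ci_calibration")
}

#' @export
print.ci_calibration <- function(x, ...) {
  cat(sprintf("Calibrated beta = %.4f for target CI %.3f (achieved %.4f over R = %d replicates, %d bisection steps)\n",
              x$beta, x$target_ci, x$achieved, x$R, x$iterations))
  invisible(x)
}
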