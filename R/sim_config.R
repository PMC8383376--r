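#' Simulation configuration for a synthetic household survey
#'
#' Describes the statistical structure of the survey to simulate: a latent
#' standard-normal household wealth factor driving binary asset ownership
#' (one-factor model), sampling strata with population shares and sampling
#' fractions (unequal fractions induce unequal design weights, as in surveys
#' that oversample some regions), an education model, and a set of binary
#' health indicators whose prevalence depends on wealth through a logit link.
#'
#' @param n_households number of households to simulate.
#' @param n_assets number of binary asset indicators.
#' @param asset_loading_range length-2 range for the per-asset wealth
#'   loadings (slopes on the logit scale); all positive by default so every
#'   asset is a "richer owns more" asset.
#' @param strata_spec data frame with columns `stratum` (label), `residence`
#'   (`"urban"` or `"rural"`), `share` (population share; must sum to 1) and
#'   `sampling_fraction` (relative sampling intensity, > 0).  A stratum
#'   sampled more intensely than its population share receives a smaller
#'   design weight.
#' @param indicators_spec data frame with columns `name`, `class`
#'   (`"outcome"` or `"coverage"`), `alpha` (baseline prevalence on the logit
#'   scale), `beta` (wealth effect on the logit scale), `residence_effect`
#'   (logit shift for urban residence) and `education_effect` (logit shift
#'   for higher education).
#' @param education_model list with `intercept`, `wealth` and `urban`:
#'   P(higher education) = plogis(intercept + wealth * w + urban * 1\{urban\}).
#' @param records_per_household individual records drawn per household
#'   (stands in for the unspecified per-household denominator of real
#'   indicators).
#' @param seed global integer seed; all stages draw from substreams derived
#'   from it.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_households = 5000,
                       n_assets = 10,
                       asset_loading_range = c(0.8, 2.0),
                       strata_spec = default_strata(),
                       indicators_spec = default_indicators(),
                       education_model = list(intercept = -1.5, wealth = 0.8, urban = 0.7),
                       records_per_household = 1,
                       seed = 1L) {
  cfg <- list(
    n_households = as.integer(n_households),
    n_assets = as.integer(n_assets),
    asset_loading_range = as.numeric(asset_loading_range),
    strata_spec = as.data.frame(strata_spec, stringsAsFactors = FALSE),
    indicators_spec = as.data.frame(indicators_spec, stringsAsFactors = FALSE),
    education_model = education_model,
    records_per_household = as.integer(records_per_household),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Default sampling strata
#'
#' Three strata: one urban and two rural, with the northern rural stratum
#' oversampled relative to its population share (so the design is not
#' self-weighting and its households carry smaller design weights).
#'
#' @return data frame with columns `stratum`, `residence`, `share`,
#'   `sampling_fraction`.
#' @export
default_strata <- function() {
  data.frame(
    stratum = c("urban", "rural_south", "rural_north"),
    residence = c("urban", "rural", "rural"),
    share = c(0.35, 0.45, 0.20),
    sampling_fraction = c(0.9, 0.9, 1.6),
    stringsAsFactors = FALSE
  )
}

#' Default indicator specification
#'
#' Three stylized binary indicators: a pro-poor outcome (more common among
#' poorer households, negative wealth effect), a mildly pro-rich coverage
#' indicator, and a strongly pro-rich coverage indicator — the pattern of
#' real maternal-health equity tables.
#'
#' @return data frame with columns `name`, `class`, `alpha`, `beta`,
#'   `residence_effect`, `education_effect`.
#' @export
default_indicators <- function() {
  data.frame(
    name = c("early_pregnancy", "contraception_use", "facility_delivery"),
    class = c("outcome", "coverage", "coverage"),
    alpha = stats::qlogis(c(0.08, 0.25, 0.14)),
    beta = c(-0.5, 0.3, 1.0),
    residence_effect = c(-0.3, 0.0, 0.4),
    education_effect = c(-0.5, 0.4, 0.5),
    stringsAsFactors = FALSE
  )
}

validate_sim_config <- function(cfg) {
  if (cfg$n_households < 1) stop("configuration error: n_households must be positive")
  if (cfg$n_assets < 1) stop("configuration error: n_assets must be positive")
  if (length(cfg$asset_loading_range) != 2 ||
      cfg$asset_loading_range[1] > cfg$asset_loading_range[2]) {
    stop("configuration error: asset_loading_range must be an increasing pair")
  }
  ss <- cfg$strata_spec
  need <- c("stratum", "residence", "share", "sampling_fraction")
  if (!all(need %in% names(ss))) {
    stop(sprintf("configuration error: strata_spec missing column(s) %s",
                 paste(setdiff(need, names(ss)), collapse = ", ")))
  }
  bad_f <- ss$stratum[!is.finite(ss$sampling_fraction) | ss$sampling_fraction <= 0]
  if (length(bad_f)) {
    stop(sprintf("configuration error: nonpositive sampling fraction in stratum '%s'", bad_f[1]))
  }
  bad_s <- ss$stratum[!is.finite(ss$share) | ss$share <= 0]
  if (length(bad_s)) {
    stop(sprintf("configuration error: nonpositive population share in stratum '%s'", bad_s[1]))
  }
  if (abs(sum(ss$share) - 1) > 1e-8) {
    stop(sprintf("configuration error: population shares sum to %.6f, not 1", sum(ss$share)))
  }
  if (!all(ss$residence %in% c("urban", "rural"))) {
    stop("configuration error: residence must be 'urban' or 'rural'")
  }
  is_ <- cfg$indicators_spec
  need_i <- c("name", "class", "alpha", "beta", "residence_effect", "education_effect")
  if (!all(need_i %in% names(is_))) {
    stop(sprintf("configuration error: indicators_spec missing column(s) %s",
                 paste(setdiff(need_i, names(is_)), collapse = ", ")))
  }
  if (anyDuplicated(is_$name)) stop("configuration error: duplicate indicator names")
  if (!all(is_$class %in% c("outcome", "coverage"))) {
    stop("configuration error: indicator class must be 'outcome' or 'coverage'")
  }
  if (any(!is.finite(is_$alpha))) {
    stop("configuration error: baseline prevalence (alpha) must be finite so the mean lies in (0,1) at beta = 0")
  }
  if (cfg$records_per_household < 1) {
    stop("configuration error: records_per_household must be positive")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Synthetic survey config: %d households, %d assets, %d strata, %d indicator(s), seed %d\n",
              x$n_households, x$n_assets, nrow(x$strata_spec),
              nrow(x$indicators_spec), x$seed))
  invisible(x)
}
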