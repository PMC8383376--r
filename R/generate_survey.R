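#' Generate a synthetic household survey with known ground-truth inequity
#'
#' Simulates the data model the equity analysis assumes: a latent standard
#' normal wealth factor `w` per household; binary assets owned with
#' probability `plogis(gamma_j * w + c_j)` with per-asset loadings `gamma_j`
#' drawn inside the configured range (one-factor model, assets conditionally
#' independent given wealth); sampling strata with design weights
#' `share / sampling_fraction` normalized to mean 1; an education tier drawn
#' from wealth and residence; and, per individual, each binary indicator
#' drawn with probability
#' `plogis(alpha + beta * w + residence_effect * urban + education_effect * higher)`.
#' All draws are governed by per-stage substreams of the global seed, so the
#' output is deterministic for a fixed config and adding an indicator leaves
#' earlier draws untouched.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_survey`: list with `households` (data
#'   frame: `household_id`, `weight`, `stratum`, `residence`,
#'   `asset_01`..`asset_K`), `individuals` (data frame: `unit_id`,
#'   `household_id`, `weight`, `residence`, `education`, one 0/1 column per
#'   indicator) and `truth` (latent wealth per household, per-indicator
#'   `(alpha, beta)`, asset loadings, config echo).
#' @export
generate_survey <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  n <- config$n_households
  ss <- config$strata_spec

  # strata: sampled counts proportional to share * sampling_fraction
  set.seed(stage_seed(config$seed, "strata"))
  p_sample <- ss$share * ss$sampling_fraction
  p_sample <- p_sample / sum(p_sample)
  stratum_idx <- sample.int(nrow(ss), n, replace = TRUE, prob = p_sample)
  raw_w <- (ss$share / ss$sampling_fraction)[stratum_idx]
  weight <- raw_w / mean(raw_w)  # design weights normalized to mean 1

  # latent wealth
  set.seed(stage_seed(config$seed, "wealth"))
  w <- stats::rnorm(n)

  # asset parameters and ownership, one substream per asset
  set.seed(stage_seed(config$seed, "asset_params"))
  gamma <- stats::runif(config$n_assets,
                        config$asset_loading_range[1],
                        config$asset_loading_range[2])
  c_j <- stats::runif(config$n_assets, -1.25, 1.25)
  assets <- matrix(0L, n, config$n_assets)
  for (j in seq_len(config$n_assets)) {
    set.seed(stage_seed(config$seed, "asset_draw", j))
    assets[, j] <- as.integer(stats::runif(n) < stats::plogis(gamma[j] * w + c_j[j]))
  }
  colnames(assets) <- sprintf("asset_%02d", seq_len(config$n_assets))

  households <- data.frame(
    household_id = seq_len(n),
    weight = weight,
    stratum = ss$stratum[stratum_idx],
    residence = ss$residence[stratum_idx],
    stringsAsFactors = FALSE
  )
  households <- cbind(households, as.data.frame(assets))

  # individuals: records_per_household records per household
  m <- config$records_per_household
  hid <- rep(households$household_id, each = m)
  urban <- as.integer(households$residence == "urban")[rep(seq_len(n), each = m)]
  w_ind <- w[rep(seq_len(n), each = m)]

  set.seed(stage_seed(config$seed, "education"))
  em <- config$education_model
  p_high <- stats::plogis(em$intercept + em$wealth * w_ind + em$urban * urban)
  higher <- as.integer(stats::runif(n * m) < p_high)

  individuals <- data.frame(
    unit_id = seq_len(n * m),
    household_id = hid,
    weight = households$weight[rep(seq_len(n), each = m)],
    residence = households$residence[rep(seq_len(n), each = m)],
    education = ifelse(higher == 1L, "higher", "lower"),
    stringsAsFactors = FALSE
  )

  is_ <- config$indicators_spec
  for (i in seq_len(nrow(is_))) {
    set.seed(stage_seed(config$seed, "indicator", i))
    p <- stats::plogis(is_$alpha[i] + is_$beta[i] * w_ind +
                         is_$residence_effect[i] * urban +
                         is_$education_effect[i] * higher)
    individuals[[is_$name[i]]] <- as.integer(stats::runif(n * m) < p)
  }

  structure(
    list(
      households = households,
      individuals = individuals,
      truth = list(
        wealth = data.frame(household_id = households$household_id, wealth = w),
        indicators = is_[, c("name", "class", "alpha", "beta",
                             "residence_effect", "education_effect")],
        asset_loadings = gamma,
        asset_intercepts = c_j,
        config = unclass(config)
      )
    ),
    class = "synthetic_survey"
  )
}

#' @export
print.synthetic_survey <- function(x, ...) {
  cat(sprintf("Synthetic survey: %d households, %d individuals, %d indicator(s)\n",
              nrow(x$households), nrow(x$individuals),
              nrow(x$truth$indicators)))
  invisible(x)
}

#' Estimate the wealth-related concentration index of one simulated indicator
#'
#' Runs the full downstream pipeline on a synthetic survey: builds the PCA
#' wealth index from the asset battery, ranks individuals by their
#' household's score, and returns the weighted covariance-form concentration
#' index of the named indicator.  Used by the effect calibration and by
#' recovery checks.
#'
#' @param survey a [generate_survey()] result.
#' @param indicator indicator name (default: first configured).
#' @param rank_convention passed through to the wealth index.
#' @return scalar estimated concentration index.
#' @export
estimate_survey_ci <- function(survey, indicator = NULL,
                               rank_convention = "endpoint") {
  if (is.null(indicator)) indicator <- survey$truth$indicators$name[1]
  wi <- build_wealth_index(survey$households, rank_convention = rank_convention)
  series <- indicator_series(survey$individuals, wi, indicator,
                             rank_convention = rank_convention)
  ci_covariance(series)
}

#' Order an indicator's records by household wealth and build a ranked series
#'
#' Joins individual records to the wealth index via `household_id`, drops
#' records where the indicator is not applicable (NA), orders them poorest to
#' richest by household score (ties broken by household then unit id), and
#' recomputes weighted fractional ranks at the individual level.
#'
#' @param individuals individual table with the indicator column.
#' @param wealth_index a [build_wealth_index()] result.
#' @param indicator indicator column name.
#' @param rank_convention passed to [ranked_series()].
#' @return a [ranked_series()].
#' @export
indicator_series <- function(individuals, wealth_index, indicator,
                             rank_convention = "endpoint") {
  idx <- wealth_index$index
  pos <- match(individuals$household_id, idx$household_id)
  if (anyNA(pos)) stop("individual references a household absent from the wealth index")
  df <- data.frame(
    h = individuals[[indicator]],
    weight = individuals$weight,
    score = idx$score[pos],
    household_id = individuals$household_id,
    unit_id = individuals$unit_id
  )
  df <- df[!is.na(df$h), , drop = FALSE]
  df <- df[order(df$score, df$household_id, df$unit_id), , drop = FALSE]
  ranked_series(df$h, df$weight, convention = rank_convention)
}
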