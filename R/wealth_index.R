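#' Standardize a binary asset matrix
#'
#' Centres and scales each asset column to mean 0, standard deviation 1,
#' using the population convention (denominator N).  Constant columns carry
#' no ranking information and are dropped with a warning; if every column is
#' constant the input is degenerate and an error is raised.
#'
#' @param assets numeric matrix or data frame of 0/1 asset indicators, one
#'   row per household.
#' @return list with `x` (standardized matrix over retained columns),
#'   `retained` (names/indices of retained columns), `dropped` (constant
#'   columns removed), `center`, `scale`.
#' @export
standardize_assets <- function(assets) {
  x <- as.matrix(assets)
  if (nrow(x) < 2) stop("need at least 2 households to standardize assets")
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("asset_", seq_len(ncol(x)))
  ctr <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2, ctr)^2))  # denominator N
  constant <- sdev == 0
  if (all(constant)) stop("degenerate input: all asset columns are constant")
  if (any(constant)) {
    warning(sprintf("dropping %d constant asset column(s): %s",
                    sum(constant), paste(colnames(x)[constant], collapse = ", ")))
  }
  keep <- which(!constant)
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2, sdev[keep], "/")
  list(x = xs, retained = colnames(x)[keep], dropped = colnames(x)[constant],
       center = ctr[keep], scale = sdev[keep])
}

#' First principal component of standardized assets
#'
#' Extracts the leading eigenvector of the sample correlation matrix of the
#' standardized asset indicators (equivalently, of `t(X) X / N` for the
#' standardized matrix `X`).  The loadings are the per-asset factor scores of
#' the wealth index.  Orientation rule: the sign is chosen so that household
#' scores correlate nonnegatively with the total asset count — owning more
#' assets means richer.
#'
#' @param std result of [standardize_assets()], or a standardized matrix.
#' @return list with `loadings` (unit-norm named vector), `explained_share`
#'   (fraction of total variance carried by the first component), and
#'   `flipped` (whether the orientation rule reversed the eigenvector sign).
#' @export
first_component <- function(std) {
  x <- if (is.list(std) && !is.null(std$x)) std$x else as.matrix(std)
  R <- crossprod(x) / nrow(x)  # correlation matrix of standardized columns
  eig <- eigen(R, symmetric = TRUE)
  if (any(!is.finite(eig$values))) stop("eigen-decomposition failed on asset correlation matrix")
  v <- eig$vectors[, 1L]
  scores <- drop(x %*% v)
  total <- rowSums(x)
  flipped <- FALSE
  orientation <- sum(scores * total)
  if (orientation < 0) {
    v <- -v
    flipped <- TRUE
  }
  names(v) <- colnames(x)
  list(loadings = v,
       explained_share = eig$values[1L] / sum(eig$values),
       flipped = flipped)
}

#' Score households on the wealth index and rank them
#'
#' Each household's raw index is the loading-weighted sum of its standardized
#' asset indicators; raw indices are re-standardized to mean 0, standard
#' deviation 1 (population convention) over the scored sample.  Households
#' are ranked ascending in score, ties broken deterministically by ascending
#' `household_id`, and weighted fractional ranks are computed from the design
#' weights in that order.
#'
#' @param households data frame with columns `household_id`, `weight`, and
#'   the asset columns named in `loadings`.
#' @param loadings named loadings vector from [first_component()]; the
#'   standardization (`center`, `scale`) used to fit them must be supplied
#'   via `std`.
#' @param std result of [standardize_assets()] on the same households.
#' @param rank_convention passed to [fractional_ranks()].
#' @return data frame (one row per household, sorted by rank): `household_id`,
#'   `score`, `rank`, `fractional_rank`, `weight`.
#' @export
score_households <- function(households, loadings, std,
                             rank_convention = c("endpoint", "midpoint")) {
  rank_convention <- match.arg(rank_convention)
  x <- as.matrix(households[, names(loadings), drop = FALSE])
  storage.mode(x) <- "double"
  xs <- sweep(sweep(x, 2, std$center), 2, std$scale, "/")
  raw <- drop(xs %*% loadings)
  score <- (raw - mean(raw)) / sqrt(mean((raw - mean(raw))^2))
  ord <- order(score, households$household_id)
  out <- data.frame(
    household_id = households$household_id[ord],
    score = score[ord],
    rank = seq_along(ord),
    weight = households$weight[ord],
    stringsAsFactors = FALSE
  )
  out$fractional_rank <- fractional_ranks(out$weight, rank_convention)
  out[, c("household_id", "score", "rank", "fractional_rank", "weight")]
}

#' Assign weighted wealth quantile groups
#'
#' Walks households in ascending score order (ties broken by household id)
#' and cuts the cumulative design weight at fractions `j/k`.  A household is
#' assigned the group containing the midpoint of its own weight interval:
#' `group = ceiling(k * (cumulative weight - w/2) / W)`, so a heavy household
#' spanning several cut fractions lands in the single group holding its
#' midpoint, and every group's total weight is within one household's weight
#' of `W/k`.  Label 1 is the poorest group, `k` the richest.
#'
#' @param index data frame from [score_households()] (ordered by rank).
#' @param k number of groups: 5 (quintiles) or 10 (deciles) unless
#'   `allow_any_k = TRUE`.
#' @param use_weights if `FALSE`, groups are cut on counts instead of weights.
#' @param allow_any_k permit k outside \{5, 10\}.
#' @return integer vector of group labels, aligned with the rows of `index`.
#' @export
assign_quantiles <- function(index, k, use_weights = TRUE, allow_any_k = FALSE) {
  if (!allow_any_k && !k %in% c(5L, 10L)) {
    stop("k must be 5 (quintiles) or 10 (deciles); set allow_any_k = TRUE to override")
  }
  w <- if (use_weights) index$weight else rep(1, nrow(index))
  W <- sum(w)
  mid <- (cumsum(w) - w / 2) / W
  grp <- ceiling(k * mid)
  pmin(pmax(grp, 1L), as.integer(k))
}

#' Build the full wealth index for a household table
#'
#' End-to-end convenience: standardizes the asset battery, extracts the first
#' principal component with the richer-is-higher orientation, scores and
#' ranks all households (a single index for the whole sample — urban and
#' rural are never fitted separately), and attaches weighted quintile and
#' decile labels.
#'
#' @param households data frame with `household_id`, `weight`, and asset
#'   columns (prefix `asset_` by default).
#' @param asset_cols character vector of asset column names; by default every
#'   column whose name starts with `"asset_"`.
#' @param rank_convention passed to [fractional_ranks()].
#' @param weighted_quantiles cut quantile groups on design weights (default)
#'   or raw counts.
#' @return object of class `wealth_index`: list with `index` (data frame:
#'   `household_id`, `score`, `rank`, `fractional_rank`, `weight`, `quintile`,
#'   `decile`), `loadings`, `explained_share`, `dropped_assets`.
#' @export
build_wealth_index <- function(households,
                               asset_cols = grep("^asset_", names(households), value = TRUE),
                               rank_convention = c("endpoint", "midpoint"),
                               weighted_quantiles = TRUE) {
  rank_convention <- match.arg(rank_convention)
  if (length(asset_cols) == 0) stop("no asset columns found")
  std <- standardize_assets(households[, asset_cols, drop = FALSE])
  pc <- first_component(std)
  idx <- score_households(households, pc$loadings, std, rank_convention)
  idx$quintile <- assign_quantiles(idx, 5L, use_weights = weighted_quantiles)
  idx$decile <- assign_quantiles(idx, 10L, use_weights = weighted_quantiles)
  structure(
    list(index = idx, loadings = pc$loadings,
         explained_share = pc$explained_share,
         flipped = pc$flipped, dropped_assets = std$dropped,
         rank_convention = rank_convention),
    class = "wealth_index"
  )
}

#' @export
print.wealth_index <- function(x, ...) {
  cat(sprintf("Wealth index over %d households (%d assets, first PC explains %.1f%% of variance)\n",
              nrow(x$index), length(x$loadings), 100 * x$explained_share))
  invisible(x)
}
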