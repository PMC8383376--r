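#' Weighted fractional ranks in the living-standards distribution
#'
#' Computes each unit's fractional rank after the sample has been ordered
#' poorest to richest.  Under the default `"endpoint"` convention the rank of
#' unit *i* is the cumulative design weight up to and including *i*, divided
#' by total weight; with equal weights this reduces to `i/N`, so the discrete
#' and covariance forms of the concentration index agree exactly.  The
#' `"midpoint"` convention places each unit at the centre of its weight
#' interval, `(cumulative weight - w_i/2)/W`; it does not reduce to `i/N` on
#' small samples but makes the index exactly antisymmetric under rank
#' reversal for arbitrary weights.
#'
#' @param weights positive design weights, ordered poorest to richest.
#' @param convention `"endpoint"` (default) or `"midpoint"`.
#' @return numeric vector of fractional ranks in (0, 1].
#' @export
#' @examples
#' fractional_ranks(rep(1, 4))      # 0.25 0.50 0.75 1.00
#' fractional_ranks(c(1, 3))        # 0.25 1.00
fractional_ranks <- function(weights, convention = c("endpoint", "midpoint")) {
  convention <- match.arg(convention)
  if (length(weights) == 0L) stop("empty weight vector")
  bad <- which(!is.finite(weights) | weights <= 0)
  if (length(bad)) {
    stop(sprintf("nonpositive or non-finite weight at index %d", bad[1L]))
  }
  W <- sum(weights)
  cw <- cumsum(weights)
  if (convention == "endpoint") cw / W else (cw - weights / 2) / W
}

#' Construct a ranked health series
#'
#' Bundles a health variable with its design weights and fractional ranks,
#' ordered poorest to richest, for concentration-index computation.  If
#' `fractional_rank` is omitted it is computed from the weights under the
#' given convention; the ordering of the inputs is taken as the wealth
#' ordering.
#'
#' @param h nonnegative health variable (binary for prevalence indicators),
#'   ordered poorest to richest.
#' @param weights positive design weights (default equal).
#' @param fractional_rank optional precomputed ranks.
#' @param convention rank convention passed to [fractional_ranks()].
#' @return object of class `ranked_series` with fields `h`, `weights`, `r`,
#'   `mu` (weighted mean of `h`) and `N`.
#' @export
ranked_series <- function(h, weights = rep(1, length(h)),
                          fractional_rank = NULL,
                          convention = c("endpoint", "midpoint")) {
  convention <- match.arg(convention)
  if (length(h) != length(weights)) stop("h and weights differ in length")
  if (any(!is.finite(h)) || any(h < 0)) stop("h must be finite and nonnegative")
  r <- if (is.null(fractional_rank)) fractional_ranks(weights, convention)
       else fractional_rank
  if (length(r) != length(h)) stop("fractional_rank length mismatch")
  mu <- sum(weights * h) / sum(weights)
  structure(
    list(h = as.numeric(h), weights = as.numeric(weights), r = as.numeric(r),
         mu = mu, N = length(h), convention = convention),
    class = "ranked_series"
  )
}

#' Concentration curve L_h(p)
#'
#' The concentration curve plots the cumulative share of the health variable
#' (vertical) against the cumulative population share ranked poorest to
#' richest (horizontal).  A curve above the 45-degree diagonal indicates the
#' variable is concentrated among the poor.  The curve is piecewise linear
#' through the per-unit cumulative points, with the origin `(0, 0)` appended;
#' it ends at `(1, 1)` by construction.
#'
#' @param series a [ranked_series()].
#' @param grid optional vector of population fractions at which to also
#'   evaluate the curve by linear interpolation.
#' @return object of class `concentration_curve`: list with `p` (cumulative
#'   population fraction) and `L` (cumulative health share), and optionally
#'   `grid_p`/`grid_L`.
#' @export
concentration_curve <- function(series, grid = NULL) {
  stopifnot(inherits(series, "ranked_series"))
  if (series$mu <= 0) stop("concentration curve undefined: mean of h is zero")
  W <- sum(series$weights)
  H <- sum(series$weights * series$h)
  p <- c(0, cumsum(series$weights) / W)
  L <- c(0, cumsum(series$weights * series$h) / H)
  out <- list(p = p, L = L)
  if (!is.null(grid)) {
    out$grid_p <- grid
    out$grid_L <- stats::approx(p, L, xout = grid, rule = 2)$y
  }
  structure(out, class = "concentration_curve")
}

#' Concentration index from the curve: C = 1 - 2 * area under L_h(p)
#'
#' Integrates the piecewise-linear concentration curve by the trapezoid rule.
#' Agrees with [ci_covariance()] on the same data to within 1/N.
#'
#' @param curve a [concentration_curve()].
#' @return scalar concentration index.
#' @export
ci_from_curve <- function(curve) {
  stopifnot(inherits(curve, "concentration_curve"))
  p <- curve$p
  L <- curve$L
  area <- sum(diff(p) * (L[-length(L)] + L[-1]) / 2)
  1 - 2 * area
}

#' Concentration index, discrete (equal-weight) form
#'
#' Direct evaluation of the discrete formula
#' `C = (2 / (N * mu)) * sum(h_i * r_i) - 1 - 1/N` with ranks `r_i = i/N`,
#' `i = 1` for the poorest unit.  Assumes equal weights; `h` must already be
#' ordered poorest to richest.
#'
#' @param h nonnegative health variable ordered poorest to richest.
#' @return scalar concentration index.
#' @export
#' @examples
#' ci_discrete(c(0, 0, 1, 1))   #  0.5
#' ci_discrete(c(1, 1, 0, 0))   # -0.5
ci_discrete <- function(h) {
  N <- length(h)
  mu <- mean(h)
  if (mu <= 0) stop("concentration index undefined: mean of h is zero")
  if (all(h == h[1L])) return(0)
  r <- seq_len(N) / N
  (2 / (N * mu)) * sum(h * r) - 1 - 1 / N
}

#' Concentration index, covariance form
#'
#' `C = (2 / mu) * cov_w(h, r)` where `cov_w` is the weighted population
#' covariance (total-weight denominator) between the health variable and the
#' fractional rank.  With equal weights and endpoint ranks this equals
#' [ci_discrete()] exactly (algebraic identity).
#'
#' @param series a [ranked_series()].
#' @return scalar concentration index.
#' @export
ci_covariance <- function(series) {
  stopifnot(inherits(series, "ranked_series"))
  if (series$mu <= 0) stop("concentration index undefined: mean of h is zero")
  # a constant health variable has zero covariance with any rank: exact zero,
  # short-circuited so no floating-point residue leaks through
  if (all(series$h == series$h[1L])) return(0)
  w <- series$weights
  W <- sum(w)
  rbar <- sum(w * series$r) / W
  cov_w <- sum(w * (series$h - series$mu) * (series$r - rbar)) / W
  (2 / series$mu) * cov_w
}

#' Standard error and p-value for the concentration index
#'
#' Analytic path: delta-method (influence function) variance of the weighted
#' covariance estimator `C = 2*cov_w(h, r)/mu`, which accounts for the
#' estimation of the mean `mu`; with equal weights it coincides with the
#' heteroskedasticity-robust slope standard error of the convenient
#' regression of `2*var(r)*h_i/mu` on `r_i`.  Requires `N >= 30`.
#' Bootstrap path: units are resampled with replacement `B` times (keeping
#' their weights), re-ordered by their original wealth ordering, ranks
#' recomputed, and the index recomputed; the SE is the standard deviation of
#' the replicates.  Two-sided p-values use the normal reference either way.
#'
#' @param series a [ranked_series()].
#' @param method `"analytic"` (default) or `"bootstrap"`.
#' @param B bootstrap replicates (default 1000); a warning is emitted below 100.
#' @param seed optional seed for the bootstrap resampling.
#' @return list with `se` and `p_value` (and `B` for the bootstrap path).
#' @export
ci_standard_error <- function(series, method = c("analytic", "bootstrap"),
                              B = 1000, seed = NULL) {
  stopifnot(inherits(series, "ranked_series"))
  method <- match.arg(method)
  if (series$mu <= 0) stop("standard error undefined: mean of h is zero")
  C <- ci_covariance(series)
  if (method == "analytic") {
    if (series$N < 30) {
      stop("analytic standard error requires N >= 30; use the bootstrap")
    }
    w <- series$weights
    W <- sum(w)
    mu <- series$mu
    rbar <- sum(w * series$r) / W
    T_ <- mu * C / 2  # weighted covariance
    # influence of unit i on C = 2T/mu
    phi <- (2 / mu) * ((series$h - mu) * (series$r - rbar) - T_) -
      (C / mu) * (series$h - mu)
    se <- sqrt(sum((w / W)^2 * phi^2))
  } else {
    if (B < 100) warning("bootstrap with B < 100 replicates is unreliable")
    if (!is.null(seed)) set.seed(seed)
    n <- series$N
    reps <- vapply(seq_len(B), function(b) {
      idx <- sort(sample.int(n, n, replace = TRUE))
      s <- ranked_series(series$h[idx], series$weights[idx],
                         convention = series$convention)
      if (s$mu <= 0) return(NA_real_)
      ci_covariance(s)
    }, numeric(1))
    se <- stats::sd(reps, na.rm = TRUE)
  }
  p <- 2 * stats::pnorm(-abs(C / se))
  out <- list(se = se, p_value = p)
  if (method == "bootstrap") out$B <- B
  out
}

#' Full concentration-index estimate for one indicator
#'
#' Convenience wrapper producing a `concentration_result`: the covariance-form
#' index, its standard error and p-value, significance stars, and the
#' direction classification.
#'
#' @param series a [ranked_series()].
#' @param se_method passed to [ci_standard_error()].
#' @param B bootstrap replicates if `se_method = "bootstrap"`.
#' @param seed bootstrap seed.
#' @return object of class `concentration_result` with fields `C`, `se`,
#'   `p_value`, `stars`, `direction`, `method`, `N`, `mu`.
#' @export
concentration_result <- function(series, se_method = "analytic",
                                 B = 1000, seed = NULL) {
  C <- ci_covariance(series)
  err <- ci_standard_error(series, method = se_method, B = B, seed = seed)
  structure(
    list(C = C, se = err$se, p_value = err$p_value,
         stars = significance_stars(err$p_value),
         direction = classify_direction(C, err$p_value),
         method = "covariance", se_method = se_method,
         N = series$N, mu = series$mu),
    class = "concentration_result"
  )
}

#' @export
print.concentration_result <- function(x, ...) {
  cat(sprintf("Concentration index: %.4f%s (se %.4f, p %.3g) -> %s [N=%d, mu=%.4f]\n",
              x$C, x$stars, x$se, x$p_value, x$direction, x$N, x$mu))
  invisible(x)
}

#' Classify the direction of socioeconomic concentration
#'
#' A negative index indicates concentration of the health variable among the
#' poorer ("pro-poor"), a positive index among the richer ("pro-rich").  When
#' the index is not significant at the loosest star threshold (p >= 0.1) the
#' distribution is classified "equal".
#'
#' @param C concentration index.
#' @param p_value its two-sided p-value.
#' @return one of `"pro-poor"`, `"pro-rich"`, `"equal"`.
#' @export
classify_direction <- function(C, p_value) {
  if (is.na(p_value) || p_value >= 0.1 || C == 0) return("equal")
  if (C < 0) "pro-poor" else "pro-rich"
}

#' Significance stars
#'
#' Standard ladder: `***` for p < 0.01, `**` for p < 0.05, `*` for p < 0.1,
#' empty otherwise.
#'
#' @param p_value p-value in \[0, 1\].
#' @return star string.
#' @export
significance_stars <- function(p_value) {
  stopifnot(p_value >= 0, p_value <= 1)
  if (p_value < 0.01) "***"
  else if (p_value < 0.05) "**"
  else if (p_value < 0.1) "*"
  else ""
}
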