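#' Weighted prevalence of a binary indicator
#'
#' Design-weighted proportion: `sum(w * value) / sum(w)`, reported both as a
#' fraction and as a percentage.
#'
#' @param values binary 0/1 indicator values.
#' @param weights positive design weights.
#' @param label stratum label used in error messages.
#' @return list with `fraction`, `percent`, `n` (records) and `sum_w`.
#' @export
weighted_prevalence <- function(values, weights = rep(1, length(values)),
                                label = "subset") {
  keep <- !is.na(values)
  values <- values[keep]; weights <- weights[keep]
  if (length(values) == 0L) {
    stop(sprintf("undefined prevalence: no records in stratum '%s'", label))
  }
  if (any(weights <= 0)) stop("weights must be positive")
  frac <- sum(weights * values) / sum(weights)
  list(fraction = frac, percent = 100 * frac,
       n = length(values), sum_w = sum(weights))
}

#' Risk ratio between two strata of a binary indicator
#'
#' Ratio of design-weighted prevalences, numerator group listed first.  The
#' 95% interval and two-sided p-value use the Katz log-normal method with
#' effective sample sizes `(sum w)^2 / sum(w^2)` (design-effect-naive; survey
#' clustering is not modeled).  When a zero count blocks the log-RR variance
#' a 0.5 continuity correction is applied to the counts and flagged; a zero
#' denominator prevalence yields an infinite-RR sentinel with a warning.
#'
#' @param records data frame of individual records with the indicator,
#'   weights and the stratifying column.
#' @param stratifier column name to stratify on (e.g. `"quintile"`,
#'   `"residence"`, `"education"`).
#' @param group_a numerator group label.
#' @param group_b denominator group label.
#' @param value_col column holding the 0/1 indicator (default `"value"`).
#' @param weight_col column holding design weights (default `"weight"`).
#' @return object of class `risk_ratio_result`: `group_a`, `group_b`,
#'   `prevalence_a`, `prevalence_b`, `rr`, `ci95`, `p_value`, `n_a`, `n_b`,
#'   `corrected`.
#' @export
risk_ratio <- function(records, stratifier, group_a, group_b,
                       value_col = "value", weight_col = "weight") {
  sub <- records[!is.na(records[[value_col]]), , drop = FALSE]
  a <- sub[sub[[stratifier]] == group_a, , drop = FALSE]
  b <- sub[sub[[stratifier]] == group_b, , drop = FALSE]
  if (nrow(a) == 0L) stop(sprintf("empty group '%s' for stratifier '%s'", group_a, stratifier))
  if (nrow(b) == 0L) stop(sprintf("empty group '%s' for stratifier '%s'", group_b, stratifier))
  pa <- weighted_prevalence(a[[value_col]], a[[weight_col]], label = as.character(group_a))
  pb <- weighted_prevalence(b[[value_col]], b[[weight_col]], label = as.character(group_b))
  # effective sample sizes under unequal weights
  na_eff <- pa$sum_w^2 / sum(a[[weight_col]]^2)
  nb_eff <- pb$sum_w^2 / sum(b[[weight_col]]^2)

  if (pb$fraction == 0) {
    warning(sprintf("zero denominator prevalence in group '%s'; risk ratio is infinite", group_b))
    return(structure(list(group_a = group_a, group_b = group_b,
                          prevalence_a = pa$fraction, prevalence_b = 0,
                          rr = Inf, ci95 = c(NA_real_, NA_real_),
                          p_value = NA_real_, n_a = pa$n, n_b = pb$n,
                          corrected = FALSE),
                     class = "risk_ratio_result"))
  }

  xa <- pa$fraction * na_eff; xb <- pb$fraction * nb_eff
  corrected <- FALSE
  if (xa == 0 || xb == 0 || xa == na_eff || xb == nb_eff) {
    # continuity correction only when a boundary count blocks the variance
    xa <- xa + 0.5; xb <- xb + 0.5
    na_eff <- na_eff + 1; nb_eff <- nb_eff + 1
    corrected <- TRUE
  }
  p_a <- xa / na_eff; p_b <- xb / nb_eff
  rr <- if (corrected) p_a / p_b else pa$fraction / pb$fraction
  se_log <- sqrt((1 - p_a) / (na_eff * p_a) + (1 - p_b) / (nb_eff * p_b))
  z <- log(rr) / se_log
  structure(
    list(group_a = group_a, group_b = group_b,
         prevalence_a = pa$fraction, prevalence_b = pb$fraction,
         rr = rr,
         ci95 = exp(log(rr) + c(-1, 1) * stats::qnorm(0.975) * se_log),
         p_value = 2 * stats::pnorm(-abs(z)),
         n_a = pa$n, n_b = pb$n, corrected = corrected),
    class = "risk_ratio_result"
  )
}

#' @export
print.risk_ratio_result <- function(x, ...) {
  cat(sprintf("RR (%s : %s) = %.3f [%.3f, %.3f], p = %.3g (prev %.3f vs %.3f)\n",
              x$group_a, x$group_b, x$rr, x$ci95[1], x$ci95[2],
              x$p_value, x$prevalence_a, x$prevalence_b))
  invisible(x)
}

#' Assemble the full equity table for a survey
#'
#' One row per indicator: design-weighted average prevalence; the weighted
#' covariance-form concentration index with standard error, p-value, stars
#' and direction; the richest-vs-poorest risk ratios (quintile 5 : quintile 1
#' and decile 10 : decile 1 — only the top and bottom groups enter); and the
#' urban : rural and higher : lower education risk ratios with p-values.
#' Rows carry the indicator class so outcome and coverage blocks can be
#' printed separately.  An indicator with zero prevalence gets its
#' concentration-index cells marked undefined (NA) and the pipeline
#' continues.
#'
#' @param survey a `synthetic_survey` (or any list with `households` and
#'   `individuals` tables in the fixture schema).
#' @param wealth_index optional precomputed [build_wealth_index()]; built
#'   from `survey$households` when omitted.
#' @param indicators indicator column names; default: all columns of the
#'   individual table beyond the identifier/weight/stratifier columns.
#' @param indicator_classes optional named vector mapping indicator name to
#'   `"outcome"`/`"coverage"`; taken from `survey$truth` when available.
#' @param se_method concentration-index SE method, `"analytic"` or
#'   `"bootstrap"`.
#' @param B bootstrap replicates when `se_method = "bootstrap"`.
#' @param seed bootstrap seed.
#' @param rank_convention fractional-rank convention.
#' @return data frame of class `equity_table`, one row per indicator, with a
#'   `note` attribute recording that p-values are design-naive.
#' @export
build_equity_table <- function(survey, wealth_index = NULL, indicators = NULL,
                               indicator_classes = NULL,
                               se_method = "analytic", B = 1000, seed = NULL,
                               rank_convention = "endpoint") {
  ind_tab <- survey$individuals
  meta_cols <- c("unit_id", "household_id", "weight", "residence", "education")
  if (is.null(indicators)) indicators <- setdiff(names(ind_tab), meta_cols)
  if (length(indicators) == 0L) stop("no indicator columns found")
  if (is.null(indicator_classes) && !is.null(survey$truth)) {
    tr <- survey$truth$indicators
    indicator_classes <- stats::setNames(tr$class, tr$name)
  }
  if (is.null(wealth_index)) {
    wealth_index <- build_wealth_index(survey$households,
                                       rank_convention = rank_convention)
  }
  idx <- wealth_index$index
  pos <- match(ind_tab$household_id, idx$household_id)
  if (anyNA(pos)) stop("individual references a household absent from the wealth index")
  ind_tab$quintile <- idx$quintile[pos]
  ind_tab$decile <- idx$decile[pos]

  rows <- lapply(indicators, function(nm) {
    rec <- ind_tab[!is.na(ind_tab[[nm]]), , drop = FALSE]
    prev <- weighted_prevalence(rec[[nm]], rec$weight, label = nm)
    cls <- if (!is.null(indicator_classes) && nm %in% names(indicator_classes))
      indicator_classes[[nm]] else NA_character_

    if (prev$fraction == 0) {
      conc <- list(C = NA_real_, se = NA_real_, p_value = NA_real_,
                   stars = "", direction = "undefined")
    } else {
      series <- indicator_series(rec, wealth_index, nm,
                                 rank_convention = rank_convention)
      conc <- concentration_result(series, se_method = se_method, B = B,
                                   seed = seed)
    }

    rr_cell <- function(strat, a, b) {
      res <- tryCatch(
        risk_ratio(rec, strat, a, b, value_col = nm),
        error = function(e) NULL, warning = function(w) NULL
      )
      if (is.null(res)) list(rr = NA_real_, p = NA_real_, stars = "")
      else list(rr = res$rr, p = res$p_value,
                stars = if (is.na(res$p_value)) "" else significance_stars(res$p_value))
    }
    q <- rr_cell("quintile", 5L, 1L)
    d <- rr_cell("decile", 10L, 1L)
    u <- rr_cell("residence", "urban", "rural")
    e <- rr_cell("education", "higher", "lower")

    data.frame(
      indicator = nm, class = cls,
      prevalence_pct = prev$percent,
      ci = conc$C, ci_se = conc$se, ci_p = conc$p_value,
      ci_stars = conc$stars, ci_direction = conc$direction,
      rr_q5_q1 = q$rr, rr_q5_q1_p = q$p, rr_q5_q1_stars = q$stars,
      rr_d10_d1 = d$rr, rr_d10_d1_p = d$p, rr_d10_d1_stars = d$stars,
      rr_urban_rural = u$rr, rr_urban_rural_p = u$p, rr_urban_rural_stars = u$stars,
      rr_higher_lower = e$rr, rr_higher_lower_p = e$p, rr_higher_lower_stars = e$stars,
      n = prev$n,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  # outcome block first, then coverage, mirroring the standard table layout
  if (!all(is.na(out$class))) {
    out <- out[order(match(out$class, c("outcome", "coverage"))), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "note") <- "p-values are design-naive (no clustering adjustment); RR intervals use the Katz log-normal method"
  class(out) <- c("equity_table", "data.frame")
  out
}

#' @export
print.equity_table <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  show <- data.frame(
    indicator = df$indicator,
    class = df$class,
    `prev%` = round(df$prevalence_pct, 2),
    CI = paste0(formatC(df$ci, digits = digits, format = "f"), df$ci_stars),
    `RR Q5:Q1` = paste0(formatC(df$rr_q5_q1, digits = digits, format = "f"), df$rr_q5_q1_stars),
    `RR D10:D1` = paste0(formatC(df$rr_d10_d1, digits = digits, format = "f"), df$rr_d10_d1_stars),
    `RR urb:rur` = paste0(formatC(df$rr_urban_rural, digits = digits, format = "f"), df$rr_urban_rural_stars),
    `RR hi:lo ed` = paste0(formatC(df$rr_higher_lower, digits = digits, format = "f"), df$rr_higher_lower_stars),
    check.names = FALSE
  )
  print(show, row.names = FALSE)
  cat("note:", attr(x, "note"), "\n")
  invisible(x)
}
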