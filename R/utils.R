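#' Derive a deterministic substream seed for one simulation stage
#'
#' A single global seed governs all draws; each stage (wealth, strata,
#' assets, education, each indicator, each calibration replicate) draws from
#' its own substream whose seed is a deterministic function of the global
#' seed, a stage label and an index.  Adding an indicator therefore never
#' perturbs draws made by earlier stages.
#'
#' @param seed global integer seed.
#' @param stage character stage label.
#' @param index integer substream index within the stage (e.g. indicator
#'   number), default 0.
#' @return integer seed in \[1, 2^31 - 2\].
#' @keywords internal
stage_seed <- function(seed, stage, index = 0L) {
  m <- 2147483647
  h <- (abs(as.double(seed)) %% m) * 48271 +
    (sum(utf8ToInt(stage)) %% m) * 1299721 +
    (abs(as.double(index)) %% m) * 7919
  s <- as.integer(h %% (m - 1)) + 1L
  s
}

# format numeric columns for CSV at full double precision
.fmt_num <- function(x) {
  if (is.numeric(x) && !is.integer(x)) {
    formatC(x, digits = 17, format = "g")
  } else x
}
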