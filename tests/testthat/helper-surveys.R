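# shared fixtures for the test suite: small configs with known structure

# single indicator driven only by wealth (no residence/education effects)
wealth_only_indicator <- function(name = "ind", p0 = 0.2, beta = 0,
                                  class = "outcome") {
  data.frame(name = name, class = class, alpha = stats::qlogis(p0),
             beta = beta, residence_effect = 0, education_effect = 0,
             stringsAsFactors = FALSE)
}

# one self-weighting stratum: all design weights equal
single_stratum <- function() {
  data.frame(stratum = "all", residence = "rural", share = 1,
             sampling_fraction = 1, stringsAsFactors = FALSE)
}

small_config <- function(n = 500, seed = 1, beta = 0, p0 = 0.2, ...) {
  sim_config(n_households = n, n_assets = 6,
             indicators_spec = wealth_only_indicator(p0 = p0, beta = beta),
             seed = seed, ...)
}

# random nonnegative health series with positive mean
random_h <- function(n, binary = TRUE) {
  if (binary) {
    h <- rbinom(n, 1, runif(1, 0.1, 0.9))
    if (sum(h) == 0) h[sample.int(n, 1)] <- 1
  } else {
    h <- rexp(n, rate = runif(1, 0.5, 2))
  }
  h
}
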