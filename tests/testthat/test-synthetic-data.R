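test_that("invalid configurations are rejected naming the offender", {
  bad_share <- data.frame(stratum = c("a", "b"), residence = c("urban", "rural"),
                          share = c(0.5, 0.4), sampling_fraction = c(1, 1))
  expect_error(sim_config(strata_spec = bad_share), "shares sum to")
  bad_frac <- data.frame(stratum = c("a", "b"), residence = c("urban", "rural"),
                         share = c(0.5, 0.5), sampling_fraction = c(1, 0))
  expect_error(sim_config(strata_spec = bad_frac), "stratum 'b'")
  expect_error(sim_config(n_households = 0), "n_households")
})

test_that("a single self-weighting stratum gives equal design weights", {
  cfg <- small_config(n = 200, seed = 2, strata_spec = single_stratum())
  sv <- generate_survey(cfg)
  expect_equal(sv$households$weight, rep(1, 200))
})

test_that("design weights equal share/fraction up to one normalization", {
  cfg <- sim_config(n_households = 2000, seed = 4)
  sv <- generate_survey(cfg)
  ss <- cfg$strata_spec
  raw <- ss$share / ss$sampling_fraction
  per_stratum <- tapply(sv$households$weight, sv$households$stratum, unique)
  ratio <- unlist(per_stratum)[ss$stratum] / raw
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-12)
  expect_equal(mean(sv$households$weight), 1, tolerance = 1e-12)
})

test_that("generation is deterministic and stable under added indicators", {
  cfg <- small_config(n = 300, seed = 17)
  s1 <- generate_survey(cfg)
  s2 <- generate_survey(cfg)
  expect_identical(s1$households, s2$households)
  expect_identical(s1$individuals, s2$individuals)

  # adding a second indicator leaves all earlier draws untouched
  cfg2 <- cfg
  cfg2$indicators_spec <- rbind(cfg$indicators_spec,
                                wealth_only_indicator("extra", p0 = 0.3))
  s3 <- generate_survey(cfg2)
  expect_identical(s3$households, s1$households)
  expect_identical(s3$individuals$ind, s1$individuals$ind)
})

test_that("weighted prevalence converges to the stratum mixture", {
  # residence effect makes urban prevalence differ; the weighted estimate
  # must recover the population-share mixture despite oversampling
  ind <- data.frame(name = "y", class = "outcome", alpha = qlogis(0.15),
                    beta = 0, residence_effect = 0.8, education_effect = 0)
  cfg <- sim_config(n_households = 10000, indicators_spec = ind,
                    education_model = list(intercept = -1, wealth = 0, urban = 0),
                    seed = 23)
  sv <- generate_survey(cfg)
  est <- weighted_prevalence(sv$individuals$y, sv$individuals$weight)$fraction
  p_urban <- mean(plogis(qlogis(0.15) + 0.8))
  p_rural <- plogis(qlogis(0.15))
  shares <- cfg$strata_spec$share
  truth <- sum(shares * ifelse(cfg$strata_spec$residence == "urban", p_urban, p_rural))
  se <- sqrt(truth * (1 - truth) / 10000)
  expect_lt(abs(est - truth), 3 * se)
})

test_that("the wealth effect drives the estimated index sign", {
  for (beta in c(-0.8, 0, 0.8)) {
    cfg <- small_config(n = 10000, seed = 29, beta = beta)
    ci <- estimate_survey_ci(generate_survey(cfg))
    mc_se <- 0.012  # binomial-scale MC error at n = 10,000, p = 0.2
    if (beta == 0) expect_lt(abs(ci), 3 * mc_se)
    else expect_equal(sign(ci), sign(beta))
  }
})

test_that("calibration finds a beta that reproduces the target index", {
  cfg <- sim_config(n_households = 4000, n_assets = 8,
                    indicators_spec = wealth_only_indicator(p0 = 0.25),
                    seed = 37)
  expect_equal(calibrate_effect(0, cfg)$beta, 0)  # symmetry of the logit link

  cal <- calibrate_effect(0.2, cfg, R = 6, tol = 0.015)
  expect_gt(cal$beta, 0)  # sign of beta matches sign of the target
  expect_lt(abs(cal$achieved - 0.2), 0.015)
  expect_equal(cal$R, 6)

  expect_error(calibrate_effect(0.95, cfg), "below 0.9")
  expect_error(calibrate_effect(0.4, cfg, beta_bracket = c(-0.01, 0.01)),
               "does not bracket")
})

test_that("calibration to a pro-poor target is recovered by fresh simulation", {
  # target magnitude of the order seen in published equity tables (-0.133)
  cfg <- sim_config(n_households = 4000, n_assets = 8,
                    indicators_spec = wealth_only_indicator(p0 = 0.25),
                    seed = 41)
  cal <- calibrate_effect(-0.133, cfg, R = 8)
  cfg2 <- cfg
  cfg2$indicators_spec$beta[1] <- cal$beta
  fresh <- vapply(1:30, function(r) {
    cfg2$seed <- 900000 + r
    estimate_survey_ci(generate_survey(cfg2))
  }, numeric(1))
  expect_gt(mean(fresh), -0.143)
  expect_lt(mean(fresh), -0.123)
})

test_that("fixtures round-trip exactly and validate referential integrity", {
  cfg <- sim_config(n_households = 100, n_assets = 4,
                    indicators_spec = rbind(wealth_only_indicator("a", p0 = 0.3),
                                            wealth_only_indicator("b", p0 = 0.5)),
                    records_per_household = 2, seed = 43)
  sv <- generate_survey(cfg)
  dir <- withr::local_tempdir()
  write_fixture(sv, dir)
  back <- read_fixture(dir)
  expect_equal(back$households, sv$households)
  expect_equal(back$individuals, sv$individuals)
  expect_equal(nrow(back$households), 100)
  expect_equal(nrow(back$individuals), 100 * 2)
  expect_equal(back$truth$wealth$wealth, sv$truth$wealth$wealth, tolerance = 1e-12)

  # an individual referencing a missing household is a parse error with row number
  ind <- utils::read.csv(file.path(dir, "individuals.csv"))
  ind$household_id[5] <- 99999
  utils::write.csv(ind, file.path(dir, "individuals.csv"), row.names = FALSE)
  expect_error(read_fixture(dir), "row 5")
})
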