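test_that("asset standardization uses the population convention", {
  std <- standardize_assets(matrix(c(0, 1), ncol = 1))
  expect_equal(drop(std$x), c(-1, 1))  # sd with denominator N

  m <- matrix(c(0, 1, 1, 0,
                1, 0, 1, 0,
                0, 0, 1, 1), nrow = 4)
  std2 <- standardize_assets(m)
  expect_equal(unname(colMeans(std2$x)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(sqrt(colMeans(std2$x^2))), rep(1, 3), tolerance = 1e-12)
})

test_that("constant asset columns are dropped with a warning", {
  m <- cbind(a = c(0, 1, 0), b = c(1, 1, 1))
  expect_warning(std <- standardize_assets(m), "constant")
  expect_equal(std$retained, "a")
  expect_equal(std$dropped, "b")
  expect_error(standardize_assets(cbind(c(1, 1), c(0, 0))), "degenerate")
})

test_that("first component recovers simple correlation structure", {
  # two perfectly correlated assets: loadings (1,1)/sqrt(2), share 1
  x <- c(0, 0, 1, 1, 0, 1)
  std <- standardize_assets(cbind(x, x))
  pc <- first_component(std)
  expect_equal(unname(pc$loadings), rep(1 / sqrt(2), 2), tolerance = 1e-12)
  expect_equal(pc$explained_share, 1, tolerance = 1e-12)

  # two independent assets: isotropic, explained share 1/2
  set.seed(5)
  a <- rbinom(4000, 1, 0.5); b <- rbinom(4000, 1, 0.5)
  pc2 <- first_component(standardize_assets(cbind(a, b)))
  expect_equal(pc2$explained_share, 0.5, tolerance = 0.05)
})

test_that("one-factor assets yield all-positive loadings matching power iteration", {
  cfg <- small_config(n = 1500, seed = 9)
  sv <- generate_survey(cfg)
  std <- standardize_assets(sv$households[, grep("^asset_", names(sv$households))])
  pc <- first_component(std)
  expect_true(all(pc$loadings > 0))

  # independent oracle: power iteration on the sample correlation matrix
  R <- crossprod(std$x) / nrow(std$x)
  v <- rep(1, ncol(R))
  for (i in 1:500) v <- drop(R %*% v) / sqrt(sum((R %*% v)^2))
  if (sum(v * pc$loadings) < 0) v <- -v
  expect_equal(unname(pc$loadings), unname(v), tolerance = 1e-8)
})

test_that("scores are monotone in dominated profiles and ties are deterministic", {
  hh <- data.frame(household_id = 1:4, weight = 1,
                   asset_1 = c(1, 0, 1, 1), asset_2 = c(1, 0, 0, 0),
                   asset_3 = c(1, 0, 1, 1))
  std <- standardize_assets(hh[, 3:5])
  pc <- first_component(std)
  idx <- score_households(hh, pc$loadings, std)
  sc <- idx$score[match(1:4, idx$household_id)]
  expect_gt(sc[1], sc[2])          # owns everything vs owns nothing
  expect_equal(sc[3], sc[4])       # identical profiles tie on score
  r3 <- idx$rank[idx$household_id == 3]
  r4 <- idx$rank[idx$household_id == 4]
  expect_equal(r4, r3 + 1L)        # tie broken by ascending household_id
  # scores standardized over the sample
  expect_equal(mean(idx$score), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(idx$score^2)), 1, tolerance = 1e-12)
})

test_that("scores are invariant to asset column order", {
  cfg <- small_config(n = 300, seed = 21)
  hh <- generate_survey(cfg)$households
  wi1 <- build_wealth_index(hh)
  asset_cols <- grep("^asset_", names(hh), value = TRUE)
  hh2 <- hh[, c(setdiff(names(hh), asset_cols), rev(asset_cols))]
  wi2 <- build_wealth_index(hh2)
  expect_equal(wi1$index$score, wi2$index$score, tolerance = 1e-10)
})

test_that("weighted quantile groups follow the cumulative-weight walk", {
  idx <- data.frame(household_id = 1:10, score = 1:10, weight = rep(1, 10))
  expect_equal(assign_quantiles(idx, 5L), rep(1:5, each = 2))
  expect_equal(assign_quantiles(idx, 10L), 1:10)
  expect_error(assign_quantiles(idx, 4L), "k must be 5")
  expect_equal(assign_quantiles(idx, 4L, allow_any_k = TRUE),
               c(1, 1, 1, 2, 2, 3, 3, 3, 4, 4))

  # heavy household spanning several cut fractions sits in the group holding
  # its weight midpoint; group weights within one household weight of W/k
  idx2 <- data.frame(household_id = 1:5, score = 1:5, weight = c(1, 1, 1, 1, 6))
  g <- assign_quantiles(idx2, 5L)
  expect_equal(g, c(1, 1, 2, 2, 4))  # midpoint of heavy unit at 7/10 -> group 4
  gw <- tapply(idx2$weight, g, sum)
  expect_true(all(abs(gw - 10 / 5) <= 6))
})

test_that("quintile labels match the weighted-midpoint formula and nest deciles", {
  cfg <- sim_config(n_households = 800, seed = 13)
  wi <- build_wealth_index(generate_survey(cfg)$households)
  idx <- wi$index
  mid <- (cumsum(idx$weight) - idx$weight / 2) / sum(idx$weight)
  expect_equal(idx$quintile, pmin(pmax(ceiling(5 * mid), 1), 5))
  expect_true(all(idx$decile %in% c(2 * idx$quintile - 1, 2 * idx$quintile)))
  expect_true(all(diff(idx$quintile) >= 0))  # nondecreasing in score order
})

test_that("wealth index recovers latent wealth on a synthetic survey", {
  cfg <- sim_config(n_households = 1000, seed = 31)
  sv <- generate_survey(cfg)
  wi <- build_wealth_index(sv$households)
  rho <- cor(wi$index$score[order(wi$index$household_id)],
             sv$truth$wealth$wealth, method = "spearman")
  expect_gt(rho, 0.8)
})
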