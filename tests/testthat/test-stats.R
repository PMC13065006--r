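mk_series <- function(pct, work, id = "P1") {
  n <- length(pct)
  structure(data.frame(player_id = id, cycle = seq_len(n),
                       peak_velocity = pct * 0.06,
                       peak_velocity_pct = pct,
                       cum_tot = work, cum_ext = work, cum_int = work / 3,
                       cum_pelvis = work * 1.4, cum_bb = work * 3,
                       cum_tot_neg = -work, cum_ext_neg = -work),
            class = c("player_series", "data.frame"))
}

test_that("per-player correlation matches the covariance formula and flags degeneracy", {
  s <- mk_series(pct = c(100, 95, 90, 85), work = c(300, 600, 900, 1200))
  pc <- player_correlation(s, "tot")
  expect_equal(pc$r, -1)
  expect_identical(pc$n, 4L)

  expect_error(player_correlation(mk_series(rep(90, 4), c(1, 2, 3, 4))),
               "zero variance")

  set.seed(71)
  x <- rnorm(12); y <- rnorm(12)
  s2 <- mk_series(pct = 80 + 5 * y, work = 1000 + 100 * x)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(player_correlation(s2, "tot")$r, oracle, tolerance = 1e-12)
})

test_that("pooled correlation: single-group identity and homogeneous shrinkage", {
  one <- pooled_correlation(-0.9, 10)
  expect_equal(one$r_pooled, -0.9, tolerance = 1e-9)
  expect_equal(one$ci_low, tanh(atanh(-0.9) - 1.96 / sqrt(7)), tolerance = 1e-3)
  expect_equal(one$ci_high, tanh(atanh(-0.9) + 1.96 / sqrt(7)), tolerance = 1e-3)

  five <- pooled_correlation(rep(-0.9, 5), rep(8, 5))
  expect_equal(five$r_pooled, -0.9, tolerance = 1e-12)
  expect_equal(five$tau2, 0)
  expect_true(five$ci_low <= five$r_pooled && five$r_pooled <= five$ci_high)

  expect_error(pooled_correlation(c(-0.9, -0.8), c(10, 3)), "n <= 3")
})

test_that("pooled correlation equals an independent DerSimonian-Laird meta-analysis", {
  library(metafor)
  set.seed(72)
  for (rep in 1:5) {
    k <- sample(5:12, 1)
    r <- tanh(rnorm(k, -1.2, 0.4))
    n <- sample(5:15, k, replace = TRUE)
    got <- pooled_correlation(r, n)
    fit <- metafor::rma(yi = atanh(r), vi = 1 / (n - 3), method = "DL")
    expect_equal(got$r_pooled, tanh(as.numeric(fit$beta)), tolerance = 1e-8)
    expect_equal(got$tau2, fit$tau2, tolerance = 1e-8)
    expect_equal(got$ci_low, tanh(fit$ci.lb), tolerance = 1e-6)
    expect_equal(got$ci_high, tanh(fit$ci.ub), tolerance = 1e-6)
  }
})

test_that("pooled r stays inside the per-player range and its CI shrinks with n", {
  set.seed(73)
  r <- c(-0.95, -0.9, -0.85, -0.8)
  # equal variances, tau2 forced 0 by homogeneity of weights: pooled within range
  got <- pooled_correlation(r, rep(10, 4))
  expect_gte(got$r_pooled, min(r))
  expect_lte(got$r_pooled, max(r))
  # invariant to relabelling
  perm <- pooled_correlation(r[c(3, 1, 4, 2)], rep(10, 4))
  expect_equal(perm$r_pooled, got$r_pooled, tolerance = 1e-12)

  # homogeneous correlations keep tau2 at 0, so the CI narrows with n
  widths <- vapply(c(6, 10, 20, 50), function(n) {
    p <- pooled_correlation(rep(-0.88, 4), rep(n, 4))
    expect_equal(p$tau2, 0)
    p$ci_high - p$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("magnitude labels use strict thresholds at 0.5/0.7/0.9", {
  expect_identical(magnitude_label(-0.93), "extremely large")
  expect_identical(magnitude_label(-0.75), "very large")
  expect_identical(magnitude_label(0.6), "large")
  expect_identical(magnitude_label(0.5), "trivial-to-moderate")  # boundary excluded
  expect_identical(magnitude_label(0.7), "large")
  expect_identical(magnitude_label(-0.9), "very large")
  expect_error(magnitude_label(1.2), "exceed")
})

test_that("repeated-measures Bland-Altman handles exact and offset agreement", {
  ref <- c(100, 120, 110, 95, 105, 130)
  subj <- c("a", "a", "a", "b", "b", "b")
  perfect <- rm_bland_altman(ref, ref, subj)
  expect_equal(perfect$bias, 0)
  expect_equal(perfect$loa_halfwidth, 0)

  off <- rm_bland_altman(ref, ref + 100, subj)
  expect_equal(off$bias, 100)
  expect_equal(off$loa_halfwidth, 0)
  expect_equal(off$loa_halfwidth,
               1.96 * sqrt(off$sd_within^2 + off$sd_between^2),
               tolerance = 1e-9)

  expect_error(rm_bland_altman(ref, ref, rep("a", 6)), "at least 2 subjects")

  # equal trial counts: bias is the grand mean of per-subject mean differences
  set.seed(74)
  d <- rnorm(12)
  subj2 <- rep(letters[1:4], each = 3)
  got <- rm_bland_altman(rep(0, 12), d, subj2)
  expect_equal(got$bias, mean(tapply(d, subj2, mean)), tolerance = 1e-12)
})

test_that("minimal detectable correlation solves the Fisher-z power equation", {
  r15 <- min_detectable_r(15, 0.05, 0.8)
  expect_equal(r15, tanh((qnorm(0.975) + qnorm(0.8)) / sqrt(12)),
               tolerance = 1e-12)
  expect_equal(round(r15, 3), 0.669)

  # defining equation holds
  expect_equal(atanh(r15) * sqrt(12), qnorm(0.975) + qnorm(0.8),
               tolerance = 1e-12)

  # power 0.5: z_power = 0
  r50 <- min_detectable_r(20, 0.05, 0.5)
  expect_equal(atanh(r50) * sqrt(17), qnorm(0.975), tolerance = 1e-12)

  # monotone decrease towards zero with growing n
  rs <- vapply(c(10, 30, 100, 1000, 10000), min_detectable_r, numeric(1))
  expect_true(all(diff(rs) < 0))
  expect_lt(rs[5], 0.03)

  expect_error(min_detectable_r(3), "n >= 4")
  expect_error(min_detectable_r(15, alpha = 1.5), "alpha")
})
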