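test_that("rank weights follow the stated rules and are nonincreasing", {
  expect_equal(rank_weights(weight_scheme("linear"), 4), c(1, 3/4, 2/4, 1/4))
  wl <- rank_weights(weight_scheme("logistic"), 1000)
  expect_gt(min(wl[1:300]), 0.95)   # ranks well below center * n
  expect_lt(max(wl[701:1000]), 0.05)
  for (k in c("adaptive", "linear", "logistic", "uniform")) {
    w <- rank_weights(weight_scheme(k), 11)
    expect_true(all(diff(w) <= 0), info = k)
    expect_true(all(w >= 0 & w <= 1), info = k)
    expect_gt(w[1], 0)
  }
  expect_error(rank_weights(weight_scheme("linear"), 2), "at least 3")
})

test_that("LTS initializer recovers exact lines and resists a gross outlier", {
  set.seed(10)
  U <- rnorm(20)
  V <- 2 * U + 1
  f <- lts_initial_fit(U, V, seed = 3)
  expect_equal(f$beta1, 2, tolerance = 1e-10)
  expect_equal(f$beta0, 1, tolerance = 1e-10)
  expect_equal(max(abs(f$residuals)), 0, tolerance = 1e-10)

  # clean linear data plus one gross outlier: closer to truth than OLS
  V2 <- 2 * U + 1 + rnorm(20, sd = 0.1)
  V2[5] <- 100
  ols <- stats::lm.fit(cbind(1, U), V2)$coefficients[2]
  flts <- lts_initial_fit(U, V2, seed = 3)
  expect_lt(abs(flts$beta1 - 2), abs(ols - 2))

  expect_identical(lts_initial_fit(U, V2, seed = 9),
                   lts_initial_fit(U, V2, seed = 9))
  expect_error(lts_initial_fit(rep(1, 10), rnorm(10)), "constant")
})

test_that("LWS with uniform weights coincides with ordinary least squares", {
  for (i in 1:5) {
    s <- rbvn(40, 0.4, seed = i)
    f <- lws_fit(s$U, s$V, weight_scheme("uniform"), seed = i)
    ols <- stats::lm.fit(cbind(1, s$U), s$V)$coefficients
    expect_equal(f$beta0, unname(ols[1]), tolerance = 1e-10)
    expect_equal(f$beta1, unname(ols[2]), tolerance = 1e-10)
  }
})

test_that("LWS residuals satisfy the exact residual identity", {
  s <- rbvn(60, 0.5, seed = 2)
  f <- lws_fit(s$U, s$V, weight_scheme("linear"), seed = 2)
  expect_identical(f$residuals, s$V - f$beta0 - f$beta1 * s$U)
  expect_equal(length(f$weights), 60L)
})

test_that("adaptive LWS tracks OLS on clean data (efficiency, scaled-down run)", {
  # 40 replications instead of 200 to keep the default suite fast; the
  # slope difference is held to 3 Monte-Carlo standard errors
  diffs <- vapply(1:40, function(i) {
    s <- rbvn(200, 0.5, seed = 100 + i)
    f <- lws_fit(s$U, s$V, weight_scheme("adaptive"), seed = i)
    ols <- stats::lm.fit(cbind(1, s$U), s$V)$coefficients[2]
    f$beta1 - unname(ols)
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(length(diffs)) + 1e-8)
  expect_lt(stats::sd(diffs), 0.05)
})

test_that("adaptive weights trim inflated residuals but not clean ones", {
  set.seed(11)
  r2 <- rnorm(200)^2
  frac_trimmed <- vapply(1:50, function(i) {
    set.seed(300 + i)
    mean(adaptive_weights(rnorm(200)^2) == 0)
  }, numeric(1))
  expect_gte(mean(frac_trimmed <= 0.05), 0.9)

  r2_bad <- r2
  set.seed(12)
  r2_bad[1:20] <- rnorm(20, mean = 100, sd = 5)^2   # 10% gross outliers
  w <- adaptive_weights(r2_bad)
  expect_true(all(w[1:20] == 0))
  expect_true(all(adaptive_weights(rep(2, 50)) == 1))
  expect_true(all(adaptive_weights(rep(0, 50)) == 1))
})

test_that("r_lws hits the exact-fit and classical limits", {
  set.seed(5)
  U <- rnorm(30)
  expect_equal(r_lws(U, 2 * U + 1, weight_scheme("adaptive"))$value, 1)
  expect_equal(r_lws(U, -U, weight_scheme("linear"))$value, -1)
  for (i in 1:5) {
    s <- rbvn(50, 0.3, seed = 40 + i)
    expect_equal(r_lws(s$U, s$V, weight_scheme("uniform"), seed = i)$value,
                 stats::cor(s$U, s$V), tolerance = 1e-10)
  }
})

test_that("r_lws is affine invariant and sign equivariant", {
  s <- rbvn(80, 0.6, seed = 7)
  base <- r_lws(s$U, s$V, weight_scheme("adaptive"), seed = 3)$value
  shifted <- r_lws(3 * s$U + 5, 0.5 * s$V - 2,
                   weight_scheme("adaptive"), seed = 3)$value
  expect_equal(shifted, base, tolerance = 1e-8)
  flipped <- r_lws(s$U, -s$V, weight_scheme("adaptive"), seed = 3)$value
  expect_equal(flipped, -base, tolerance = 1e-8)
})

test_that("r_lws rejects degenerate inputs", {
  expect_error(r_lws(rnorm(10), rep(1, 10), weight_scheme("uniform")),
               "zero weighted variance")
})

test_that("breakdown bound follows the finite-sample formula", {
  expect_equal(breakdown_bound(48, 1), 22 / 48)
  expect_equal(breakdown_bound(4, 1), 0)
  expect_equal(breakdown_bound(100, 0.25), 0.25)
  expect_error(breakdown_bound(2), "exceed 2")
})

test_that("contaminated samples stay near truth while Pearson breaks (scaled-down)", {
  # 20 replications of the 15%-outlier design; the full 100-replication
  # version runs in the acceptance suite
  vals <- vapply(1:20, function(i) {
    s <- rbvn(200, 0.6, seed = 500 + i)
    s$U[1:30] <- 100; s$V[1:30] <- -100
    c(r_lws(s$U, s$V, weight_scheme("adaptive"), seed = i)$value,
      stats::cor(s$U, s$V))
  }, numeric(2))
  expect_lt(stats::median(abs(vals[1, ] - 0.6)), 0.1)
  expect_gt(stats::median(abs(vals[2, ] - 0.6)), 0.3)
})
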