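# naive nested-loop implementation of the analytic intensity, kept
# deliberately close to the defining sums (the independent oracle)
lambda_star_loops <- function(M) {
  n <- nrow(M); m <- ncol(M)
  Z <- matrix(0, n, m)
  for (j in seq_len(m)) Z[, j] <- (M[, j] - mean(M[, j])) / stats::sd(M[, j])
  num <- 0; den <- 0
  for (i in 2:m) for (j in 1:(i - 1)) {
    w <- numeric(n)
    for (k in seq_len(n)) w[k] <- Z[k, i] * Z[k, j]
    s_ij <- n / (n - 1) * mean(w)
    v_ij <- n / (n - 1)^3 * sum((w - mean(w))^2)
    num <- num + v_ij
    den <- den + s_ij^2
  }
  if (den <= 0) 1 else max(0, min(1, num / den))
}

test_that("sample_correlation handles exact and degenerate cases", {
  set.seed(1)
  x <- rnorm(20)
  M <- cbind(a = x, b = x, c = -x)
  R <- sample_correlation(M)
  expect_equal(R["a", "b"], 1)
  expect_equal(R["a", "c"], -1)
  expect_error(sample_correlation(cbind(x, rep(2, 20))), "constant")
  set.seed(2)
  N <- matrix(rnorm(3000), 1000, 3)
  expect_lt(max(abs(sample_correlation(N)[upper.tri(diag(3))])), 0.1)
})

test_that("vectorized analytic intensity equals the nested-loop oracle", {
  set.seed(42)
  for (dims in list(c(10, 5), c(30, 20))) {
    M <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    expect_equal(as.numeric(lambda_star(M)), lambda_star_loops(M),
                 tolerance = 1e-10)
  }
})

test_that("intensity shrinks hard for pure noise, barely for strong signal", {
  # scaled-down: 30 replications of each regime
  lam_noise <- vapply(1:30, function(i) {
    set.seed(600 + i)
    as.numeric(lambda_star(matrix(rnorm(30 * 20), 30, 20)))
  }, numeric(1))
  expect_gte(mean(lam_noise > 0.5), 0.95)

  lam_sig <- vapply(1:30, function(i) {
    set.seed(700 + i)
    base <- rnorm(1000)
    M <- cbind(base, base + rnorm(1000, sd = 0.05),
               base + rnorm(1000, sd = 0.05), base + rnorm(1000, sd = 0.05))
    as.numeric(lambda_star(M))
  }, numeric(1))
  expect_true(all(lam_sig < 0.1))
})

test_that("shrink performs the exact convex combination", {
  R <- matrix(c(1, 0.8, 0.8, 1), 2)
  expect_equal(shrink(R, 1), diag(2))
  expect_equal(shrink(R, 0), R)
  expect_equal(shrink(R, 0.25)[1, 2], 0.6)
  expect_error(shrink(R, 1.2), "in \\[0, 1\\]")
  expect_error(shrink(matrix(c(1, 2, 3, 1), 2), 0.5), "symmetric")
})

test_that("regularized multiple correlation reduces to known closed forms", {
  set.seed(9)
  u <- rnorm(100)
  z <- 0.6 * u + sqrt(0.64) * rnorm(100)
  r2 <- stats::cor(z, u)^2
  expect_equal(reg_multiple_corr(z, cbind(u), lam = 0)$value, r2,
               tolerance = 1e-10)
  expect_equal(reg_multiple_corr(z, cbind(u), lam = 1)$value, 0)

  # orthogonal predictors at lam = 0: sum of squared simple correlations
  set.seed(10)
  A <- matrix(rnorm(400), 200, 2)
  A <- sweep(A, 2, colMeans(A))
  A[, 2] <- A[, 2] - A[, 1] * sum(A[, 1] * A[, 2]) / sum(A[, 1]^2)
  expect_equal(stats::cor(A[, 1], A[, 2]), 0, tolerance = 1e-12)
  z2 <- rnorm(200)
  got <- reg_multiple_corr(z2, A, lam = 0)$value
  want <- stats::cor(z2, A[, 1])^2 + stats::cor(z2, A[, 2])^2
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("eigendecomposition inversion agrees with a direct solve", {
  set.seed(11)
  M <- matrix(rnorm(20 * 5), 20, 5)
  z <- rnorm(20)
  res <- reg_multiple_corr(z, M)
  lam <- res$lambda_used
  R <- sample_correlation(cbind(M, z))
  R_TT_star <- shrink(R, lam)[1:5, 1:5]
  R_ZT_star <- (1 - lam) * R[1:5, 6]
  direct <- drop(crossprod(R_ZT_star, solve(R_TT_star, R_ZT_star)))
  expect_equal(res$value, direct, tolerance = 1e-8)
})

test_that("eigenvalue identity holds and keeps the matrix invertible for n << s", {
  for (i in 1:10) {
    set.seed(800 + i)
    n <- sample(6:12, 1); s <- sample(c(4, 15, 25), 1)  # includes n < s
    M <- matrix(rnorm(n * s), n, s)
    lam <- as.numeric(lambda_star(M))
    theta <- eigen(sample_correlation(M), symmetric = TRUE,
                   only.values = TRUE)$values
    ev <- eigen(shrink(sample_correlation(M), lam), symmetric = TRUE,
                only.values = TRUE)$values
    expect_equal(ev, (1 - lam) * theta + lam, tolerance = 1e-10)
    expect_true(all(ev >= lam - 1e-12))
  }
})

test_that("the regularized multiple correlation stays within [0, 1]", {
  for (i in 1:10) {
    set.seed(900 + i)
    n <- sample(5:15, 1); s <- sample(c(2, 8, 20), 1)
    v <- reg_multiple_corr(rnorm(n), matrix(rnorm(n * s), n, s))$value
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("shrinkage reduces Frobenius risk under an identity truth (scaled-down)", {
  # 30 replications; the 100-replication version runs in the acceptance suite
  wins <- vapply(1:30, function(i) {
    set.seed(1000 + i)
    M <- matrix(rnorm(20 * 50), 20, 50)
    sr <- shrink_correlation(M)
    I50 <- diag(50)
    sum((sr$R_star - I50)^2) < sum((sr$R_tilde - I50)^2)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("off-diagonal monotone shrinkage is exact", {
  set.seed(13)
  sr <- shrink_correlation(matrix(rnorm(15 * 6), 15, 6))
  off <- upper.tri(sr$R_tilde)
  expect_equal(sr$R_star[off], (1 - sr$lambda_star) * sr$R_tilde[off])
  expect_equal(diag(sr$R_star), rep(1, 6))
})
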