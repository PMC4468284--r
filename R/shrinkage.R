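#' Sample correlation matrix with degeneracy checks
#'
#' Thin wrapper around [stats::cor] that rejects constant columns by
#' name instead of silently returning NaN entries.
#'
#' @param columns numeric matrix, n rows (observations) by m columns.
#' @return the m x m empirical correlation matrix.
#' @export
sample_correlation <- function(columns) {
  columns <- as.matrix(columns)
  if (nrow(columns) < 3L) stop("at least 3 observations are required")
  sds <- apply(columns, 2L, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(columns)
    bad <- which(sds == 0)[1L]
    stop("degenerate variable: column ",
         if (is.null(nm)) bad else paste0("'", nm[bad], "'"), " is constant")
  }
  stats::cor(columns)
}

# columns standardized to zero mean, unit (n-1) variance; zero-variance
# columns map to all zeros so they correlate 0 with everything
standardize_columns <- function(M) {
  mu <- colMeans(M)
  Z <- sweep(M, 2L, mu, "-")
  sds <- sqrt(colSums(Z * Z) / (nrow(M) - 1L))
  sds[sds == 0] <- Inf
  sweep(Z, 2L, sds, "/")
}

#' Analytic shrinkage intensity toward the identity
#'
#' Distribution-free intensity lambda* minimizing the asymptotic mean
#' squared error of the convex combination
#' (1 - lambda) R-tilde + lambda I of the sample correlation matrix and
#' the identity. With standardized columns z and pairwise products
#' w_kij = z_ki z_kj, the pairwise correlations are
#' S_ij = n/(n-1) mean_k(w_kij), their variance estimates
#' var-hat(S_ij) = n/(n-1)^3 sum_k (w_kij - w-bar_ij)^2, and
#' \deqn{\lambda^* = \frac{\sum_{i<j} \widehat{var}(S_{ij})}
#'                        {\sum_{i<j} S_{ij}^2},}
#' clamped to [0, 1] (an all-diagonal target: a zero denominator returns
#' full shrinkage 1).
#'
#' @param columns numeric matrix with at least 4 rows and 2 columns.
#' @return the intensity, a number in [0, 1], with attributes
#'   \code{numerator} and \code{denominator} carrying the two sums.
#' @export
lambda_star <- function(columns) {
  M <- as.matrix(columns)
  n <- nrow(M)
  if (n < 4L) stop("at least 4 observations are required")
  if (ncol(M) < 2L) stop("at least 2 columns are required")
  sds <- apply(M, 2L, stats::sd)
  if (any(sds == 0))
    stop("degenerate variable: column ", which(sds == 0)[1L], " is constant")
  Z <- standardize_columns(M)
  W_bar <- crossprod(Z) / n                     # mean_k w_kij
  S <- W_bar * (n / (n - 1L))                   # pairwise correlations
  SS_w <- crossprod(Z * Z)                      # sum_k w_kij^2
  V_hat <- (n / (n - 1L)^3) * (SS_w - n * W_bar^2)
  off <- upper.tri(S)
  num <- sum(V_hat[off])
  den <- sum(S[off]^2)
  lam <- if (den <= 0) 1 else max(0, min(1, num / den))
  structure(lam, numerator = num, denominator = den)
}

#' Shrink a correlation matrix toward the identity
#'
#' @param R_tilde symmetric correlation matrix with unit diagonal.
#' @param lam shrinkage intensity in [0, 1].
#' @return (1 - lam) R_tilde + lam I; its eigenvalues are
#'   (1 - lam) theta_i + lam for eigenvalues theta_i of \code{R_tilde}.
#' @export
shrink <- function(R_tilde, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0 || lam > 1)
    stop("lam must be a single number in [0, 1]")
  R_tilde <- as.matrix(R_tilde)
  if (nrow(R_tilde) != ncol(R_tilde) ||
      max(abs(R_tilde - t(R_tilde))) > 1e-8 ||
      max(abs(diag(R_tilde) - 1)) > 1e-8)
    stop("R_tilde must be symmetric with unit diagonal")
  (1 - lam) * R_tilde + lam * diag(nrow(R_tilde))
}

#' Regularized correlation matrix of a set of columns
#'
#' Convenience combination of [sample_correlation], [lambda_star] and
#' [shrink]; every entry of the result depends on all columns jointly
#' through the analytic intensity.
#'
#' @param columns numeric matrix, n x m.
#' @param lam \code{"analytic"} (default) or a fixed number in [0, 1].
#' @return a list with \code{R_tilde}, \code{lambda_star}, \code{R_star},
#'   \code{numerator}, \code{denominator}, of class
#'   \code{"shrinkage_result"}.
#' @export
shrink_correlation <- function(columns, lam = "analytic") {
  R_tilde <- sample_correlation(columns)
  if (identical(lam, "analytic")) {
    ls <- lambda_star(columns)
    lamv <- as.numeric(ls)
    num <- attr(ls, "numerator"); den <- attr(ls, "denominator")
  } else {
    lamv <- lam; num <- NA_real_; den <- NA_real_
  }
  structure(list(R_tilde = R_tilde, lambda_star = lamv,
                 R_star = shrink(R_tilde, lamv),
                 numerator = num, denominator = den),
            class = "shrinkage_result")
}

#' Regularized coefficient of multiple correlation
#'
#' Squared-scale association between a single column Z and a set of
#' columns T_1..T_s, computed from the jointly regularized correlation
#' matrix of (T, Z): with R* the shrunken matrix, R*_ZT its last column
#' (cross block) and R*_TT its leading s x s block,
#' \deqn{\tilde r^*(Z, T) = R^{*T}_{ZT} (R^*_{TT})^{-1} R^*_{ZT}.}
#' The inverse goes through the eigendecomposition of the empirical
#' correlation matrix of T: if R-tilde_TT = Q diag(theta) Q', then
#' (R*_TT)^{-1} = Q diag(1/((1-lambda) theta_i + lambda)) Q', which is
#' well defined for any lambda > 0 even when n is smaller than s.
#'
#' Because the intensity is computed on the joint (T, Z) matrix, the
#' value depends on all columns, not only on the pair it names: unstable
#' columns borrow strength from stable ones, giving a denoised version of
#' the classical squared multiple correlation.
#'
#' @param Z numeric vector of length n (the candidate column).
#' @param T_set numeric matrix n x s (the already-selected columns).
#' @param lam \code{"analytic"} (default) or a fixed number in [0, 1].
#' @return an object of class \code{"multiple_corr_result"}: \code{value}
#'   in [0, 1], \code{lambda_used}, \code{eigenvalues_theta},
#'   \code{R_ZT} (shrunken cross-correlations) and \code{mode}.
#' @export
reg_multiple_corr <- function(Z, T_set, lam = "analytic") {
  T_set <- as.matrix(T_set)
  n <- length(Z)
  if (nrow(T_set) != n) stop("Z and T_set must have the same number of rows")
  if (n < 4L) stop("at least 4 observations are required")
  s <- ncol(T_set)
  if (s < 1L) stop("T_set must contain at least one column")
  joint <- cbind(T_set, Z)
  sr <- shrink_correlation(joint, lam)
  lamv <- sr$lambda_star
  R_tilde_TT <- sr$R_tilde[seq_len(s), seq_len(s), drop = FALSE]
  R_ZT_star <- (1 - lamv) * sr$R_tilde[seq_len(s), s + 1L]
  eg <- eigen(R_tilde_TT, symmetric = TRUE)
  theta <- eg$values
  d <- (1 - lamv) * theta + lamv
  if (any(d <= 0))
    stop("regularized matrix is singular (lambda = 0 with rank-deficient T)")
  proj <- crossprod(eg$vectors, R_ZT_star)
  value <- sum(proj^2 / d)
  value <- max(0, min(1, value))
  structure(list(value = value, lambda_used = lamv,
                 eigenvalues_theta = theta, R_ZT = R_ZT_star,
                 mode = if (identical(lam, "analytic")) "analytic-lambda"
                        else "fixed-lambda"),
            class = "multiple_corr_result")
}
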