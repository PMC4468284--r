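#' Weight scheme for least weighted squares
#'
#' The LWS estimator minimizes a weighted sum of ordered squared
#' residuals, the weights decreasing in residual rank. Three decreasing
#' schemes are supported, plus a uniform scheme under which LWS reduces
#' exactly to ordinary least squares:
#' \describe{
#'   \item{\code{"adaptive"}}{data-dependent 0/1 trimming: the
#'     contamination fraction is estimated by comparing empirical
#'     quantiles of scaled squared residuals with their chi-squared(1)
#'     counterparts; only the estimated outlying tail is dropped, so on
#'     clean data the estimator keeps (essentially) all observations and
#'     attains full least-squares efficiency.}
#'   \item{\code{"linear"}}{linearly decreasing rank weights
#'     w_i = (n - i + 1)/n.}
#'   \item{\code{"logistic"}}{w(t) = 1/(1 + exp(s (t - c))) evaluated at
#'     t = (i - 1/2)/n: close to 1 for the best-fitting half of the
#'     ranks, close to 0 for the worst.}
#'   \item{\code{"uniform"}}{all weights 1 (ordinary least squares).}
#' }
#'
#' @param kind one of \code{"adaptive"}, \code{"linear"},
#'   \code{"logistic"}, \code{"uniform"}.
#' @param logistic_steepness steepness s of the logistic scheme.
#' @param logistic_center center c in (0,1) of the logistic scheme.
#' @param adaptive_margin multiplier on the theoretical quantile curve
#'   above which the empirical curve flags an observation as outlying.
#' @return an object of class \code{"weight_scheme"}.
#' @export
weight_scheme <- function(kind = c("adaptive", "linear", "logistic", "uniform"),
                          logistic_steepness = 20, logistic_center = 0.5,
                          adaptive_margin = 2.5) {
  kind <- match.arg(kind)
  stopifnot(logistic_steepness > 0, logistic_center > 0, logistic_center < 1,
            adaptive_margin > 0)
  structure(list(kind = kind,
                 logistic_steepness = logistic_steepness,
                 logistic_center = logistic_center,
                 adaptive_margin = adaptive_margin),
            class = "weight_scheme")
}

#' Rank weights of a weight scheme
#'
#' Returns the nonincreasing weight sequence w_1 >= ... >= w_n >= 0
#' attached to residual ranks; weights are later assigned to observations
#' by ascending squared residual. The adaptive scheme has no fixed rank
#' weights (they depend on the residuals themselves); for it this
#' function returns the uniform sequence used as its starting point.
#'
#' @param scheme a [weight_scheme].
#' @param n number of observations, at least 3.
#' @return numeric vector of n weights in [0, 1].
#' @export
rank_weights <- function(scheme, n) {
  if (!inherits(scheme, "weight_scheme")) stop("scheme must be a weight_scheme")
  if (n < 3L) stop("at least 3 observations are required")
  switch(scheme$kind,
    linear = (n - seq_len(n) + 1) / n,
    logistic = {
      t <- (seq_len(n) - 0.5) / n
      1 / (1 + exp(scheme$logistic_steepness * (t - scheme$logistic_center)))
    },
    adaptive = rep(1, n),
    uniform = rep(1, n))
}

#' Adaptive 0/1 weights from squared residuals
#'
#' Quantile-based data-dependent trimming. Squared residuals are scaled
#' by a high-breakdown variance estimate (the mean of the h smallest
#' squared residuals with its normal-model consistency factor) and their
#' order statistics compared with chi-squared(1) quantiles; a contiguous
#' upper tail whose empirical quantile curve exceeds \code{margin} times
#' the theoretical curve on the absolute-residual scale (the classical
#' 2.5-sigma convention) is declared outlying and receives weight 0, all
#' other observations weight 1. The estimated outlying fraction never
#' exceeds (n - h)/n with h = floor((n+3)/2).
#'
#' @param squared_residuals nonnegative numeric vector from a current fit.
#' @param margin exceedance multiplier, default 2.5.
#' @return 0/1 weight vector aligned to the input observations.
#' @export
adaptive_weights <- function(squared_residuals, margin = 2.5) {
  r2 <- squared_residuals
  n <- length(r2)
  if (n < 3L) stop("at least 3 observations are required")
  if (max(r2) <= 0) return(rep(1, n))
  h <- lws_h(n)
  # high-breakdown scale: mean of the h smallest squared residuals with
  # the normal-model consistency factor E[z^2 | z^2 <= chi2_{h/n}] (the
  # raw trimmed mean is deflated because the preceding fit concentrates
  # on exactly those observations)
  alpha <- h / n
  cons <- stats::pchisq(stats::qchisq(alpha, df = 1), df = 3) / alpha
  s2 <- mean(sort(r2)[seq_len(h)]) / cons
  if (s2 <= 0) {
    # a majority of exactly-zero residuals (possible for a discrete
    # response, a.s. impossible for continuous data): the normal
    # quantile comparison is undefined, so nothing is trimmed
    return(rep(1, n))
  }
  ord <- order(r2, seq_len(n))
  t_sorted <- r2[ord] / s2
  q_theo <- stats::qchisq((seq_len(n) - 0.5) / n, df = 1)
  # the margin acts on the absolute-residual scale (the classical
  # "2.5 sigma" convention), hence margin^2 on squared residuals
  flagged <- t_sorted > margin^2 * q_theo
  # contiguous outlying tail, never deeper than the n - h worst ranks
  m <- 0L
  for (i in n:(h + 1L)) {
    if (flagged[i]) m <- m + 1L else break
  }
  w <- rep(1, n)
  if (m > 0L) w[ord[seq.int(n - m + 1L, n)]] <- 0
  w
}

lws_h <- function(n) (n + 3L) %/% 2L

# closed-form (weighted) simple linear regression; returns NULL when the
# weighted design is degenerate
fit_wls <- function(U, V, w = NULL) {
  if (is.null(w)) w <- rep(1, length(U))
  sw <- sum(w)
  if (sw <= 0) return(NULL)
  mu <- sum(w * U) / sw
  mv <- sum(w * V) / sw
  du <- U - mu
  sxx <- sum(w * du * du)
  if (sxx <= 0) return(NULL)
  b1 <- sum(w * du * (V - mv)) / sxx
  b0 <- mv - b1 * mu
  list(beta0 = b0, beta1 = b1, wmean_U = mu, wmean_V = mv)
}

new_lws_fit <- function(fit, U, V, weights, n_steps, seed, converged = TRUE) {
  res <- V - fit$beta0 - fit$beta1 * U
  structure(list(beta0 = fit$beta0, beta1 = fit$beta1,
                 weights = weights, residuals = res,
                 weighted_mean_U = fit$wmean_U,
                 weighted_mean_V = fit$wmean_V,
                 n_concentration_steps = n_steps,
                 converged = converged, seed = seed),
            class = "lws_fit")
}

#' Fast least trimmed squares initializer
#'
#' High-breakdown initial estimator for the LWS regression of V on U:
#' minimizes the sum of the h = floor((n+3)/2) smallest squared residuals
#' (the maximal-breakdown trimming constant for a two-parameter model)
#' by the standard fast-LTS recipe: random two-point elemental fits, a
#' fixed number of concentration steps on each, then full refinement of
#' the best candidates until the active h-subset stabilizes.
#'
#' @param U,V numeric vectors of equal length n >= 3.
#' @param n_subsets number of random two-point starts.
#' @param n_csteps concentration steps applied to every start.
#' @param n_best number of best starts refined to convergence.
#' @param seed integer seed; the fit is deterministic given it.
#' @return an object of class \code{"lws_fit"} (weights are the 0/1
#'   indicators of the final h-subset).
#' @export
lts_initial_fit <- function(U, V, n_subsets = 500L, n_csteps = 2L,
                            n_best = 10L, seed = 1L) {
  n <- length(U)
  stopifnot(length(V) == n, n >= 3L, n_subsets >= 1L)
  if (max(U) == min(U)) stop("degenerate input: U is constant")
  h <- lws_h(n)

  cstep <- function(b0, b1, k) {
    for (it in seq_len(k)) {
      r2 <- (V - b0 - b1 * U)^2
      keep <- order(r2, seq_len(n))[seq_len(h)]
      f <- fit_wls(U[keep], V[keep])
      if (is.null(f)) break
      b0 <- f$beta0; b1 <- f$beta1
    }
    r2 <- (V - b0 - b1 * U)^2
    list(b0 = b0, b1 = b1, obj = sum(sort(r2)[seq_len(h)]))
  }

  if (n * (n - 1) / 2 <= 4 * n_subsets) {
    # small samples: enumerate every elemental pair (deterministic and
    # strictly better than subsampling)
    pairs <- utils::combn(n, 2L)
    i1 <- pairs[1L, ]; i2 <- pairs[2L, ]
  } else {
    cands <- with_seed(seed, {
      list(i1 = sample.int(n, n_subsets, replace = TRUE),
           i2 = sample.int(n, n_subsets, replace = TRUE))
    })
    i1 <- cands$i1; i2 <- cands$i2
  }
  ok <- i1 != i2 & U[i1] != U[i2]
  i1 <- i1[ok]; i2 <- i2[ok]
  if (length(i1) == 0L) {
    # fall back to a deterministic sweep of index pairs
    pair <- which(outer(U, U, "!="), arr.ind = TRUE)
    if (nrow(pair) == 0L) stop("degenerate input: no two-point subset determines a line")
    i1 <- pair[1L, 1L]; i2 <- pair[1L, 2L]
  }
  b1s <- (V[i2] - V[i1]) / (U[i2] - U[i1])
  b0s <- V[i1] - b1s * U[i1]
  m <- length(i1)

  # concentration steps for all elemental starts at once: threshold each
  # residual column at its h-th smallest value and refit on the retained
  # subset by closed-form least squares
  col_id <- rep.int(seq_len(m), rep.int(n, m))
  col_sorted <- function(R2)
    matrix(R2[order(col_id, R2, method = "radix")], n, m)
  for (step in seq_len(n_csteps)) {
    R2 <- (matrix(V, n, m) - rep(b0s, each = n) - U %o% b1s)^2
    thr <- col_sorted(R2)[h, ]
    W <- R2 <= rep(thr, each = n)
    sw <- colSums(W)
    su <- colSums(U * W); sv <- colSums(V * W)
    suu <- colSums(U * U * W); suv <- colSums(U * V * W)
    sxx <- suu - su^2 / sw
    ok2 <- is.finite(sxx) & sxx > 0
    b1n <- (suv - su * sv / sw) / sxx
    b0n <- sv / sw - b1n * su / sw
    b1s <- ifelse(ok2, b1n, b1s)
    b0s <- ifelse(ok2, b0n, b0s)
  }
  R2 <- (matrix(V, n, m) - rep(b0s, each = n) - U %o% b1s)^2
  objs <- colSums(col_sorted(R2)[seq_len(h), , drop = FALSE])
  objs[!is.finite(objs)] <- Inf
  keep <- order(objs)[seq_len(min(n_best, m))]
  best <- NULL
  for (s in keep) {
    f <- cstep(b0s[s], b1s[s], 0L)
    for (it in seq_len(30L)) {   # c-steps never increase the objective
      f2 <- cstep(f$b0, f$b1, 1L)
      if (f2$obj >= f$obj) break
      f <- f2
    }
    if (is.null(best) || f$obj < best$obj) best <- f
  }
  r2 <- (V - best$b0 - best$b1 * U)^2
  keep_h <- order(r2, seq_len(n))[seq_len(h)]
  w <- numeric(n); w[keep_h] <- 1
  f <- fit_wls(U, V, w)
  if (is.null(f)) f <- list(beta0 = best$b0, beta1 = best$b1,
                            wmean_U = mean(U[keep_h]), wmean_V = mean(V[keep_h]))
  new_lws_fit(list(beta0 = best$b0, beta1 = best$b1,
                   wmean_U = f$wmean_U, wmean_V = f$wmean_V),
              U, V, w, n_csteps, seed)
}

#' Least weighted squares regression
#'
#' Robust simple linear regression V = beta0 + beta1 U + e minimizing the
#' weighted sum of ordered squared residuals, weights nonincreasing in
#' residual rank. Starting from the fast-LTS fit, the algorithm
#' alternates (i) ranking observations by squared residual (ties broken
#' by observation index), (ii) assigning the scheme's rank weights (or
#' recomputing the adaptive weights) to observations, and (iii) refitting
#' by weighted least squares, until the observation-to-rank assignment is
#' a fixed point or an iteration cap is hit, in which case the iterate
#' with the smallest LWS objective is returned and flagged.
#'
#' @param U,V numeric vectors of equal length n >= 3; V is the response.
#' @param scheme a [weight_scheme].
#' @param seed integer seed (consumed by the LTS initializer).
#' @param max_iter iteration cap.
#' @param n_subsets,n_csteps passed to [lts_initial_fit].
#' @return an object of class \code{"lws_fit"}: coefficients, final
#'   per-observation weights, residuals, weighted means of U and V, and a
#'   convergence flag.
#' @export
lws_fit <- function(U, V, scheme = weight_scheme("adaptive"), seed = 1L,
                    max_iter = 100L, n_subsets = 500L, n_csteps = 2L) {
  n <- length(U)
  stopifnot(length(V) == n, n >= 3L)
  init <- lts_initial_fit(U, V, n_subsets = n_subsets, n_csteps = n_csteps,
                          seed = seed)
  b0 <- init$beta0; b1 <- init$beta1
  wr <- rank_weights(scheme, n)
  prev_ord <- NULL; prev_ord2 <- NULL
  best <- NULL; best_obj <- Inf
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    r2 <- (V - b0 - b1 * U)^2
    ord <- order(r2, seq_len(n))
    if (scheme$kind == "adaptive") {
      w <- adaptive_weights(r2, scheme$adaptive_margin)
    } else {
      w <- numeric(n); w[ord] <- wr
    }
    obj <- sum(w * r2)
    f <- fit_wls(U, V, w)
    if (is.null(f)) stop("degenerate input: zero weighted variance of U")
    if (obj < best_obj) {
      best_obj <- obj
      best <- list(fit = f, w = w)
    }
    if (!is.null(prev_ord) && identical(ord, prev_ord)) { converged <- TRUE; break }
    # a 2-cycle of rank assignments cannot improve further: stop and keep
    # the best-objective iterate, flagged as unconverged
    if (!is.null(prev_ord2) && identical(ord, prev_ord2)) break
    prev_ord2 <- prev_ord
    prev_ord <- ord
    b0 <- f$beta0; b1 <- f$beta1
  }
  new_lws_fit(best$fit, U, V, best$w, iters, seed, converged = converged)
}

#' @export
print.lws_fit <- function(x, ...) {
  cat(sprintf("lws_fit: beta0 = %.6g, beta1 = %.6g, %d/%d positive weights%s\n",
              x$beta0, x$beta1, sum(x$weights > 0), length(x$weights),
              if (isTRUE(x$converged)) "" else " (not converged)"))
  invisible(x)
}

#' Robust correlation coefficient based on LWS regression
#'
#' Measures linear association between two data vectors through the LWS
#' regression of V on U: the slope is rescaled by the ratio of weighted
#' standard deviations computed with the final LWS weights,
#' \deqn{r = b_1 \sqrt{\sum \tilde w_i (U_i - \bar U_w)^2} /
#'           \sqrt{\sum \tilde w_i (V_i - \bar V_w)^2},}
#' clipped to [-1, 1]. With uniform weights this is exactly the Pearson
#' correlation coefficient; with decreasing weights it inherits the high
#' breakdown point and (for adaptive weights) the full normal-model
#' efficiency of the LWS estimator. V is the regression response; within
#' relevance screening the continuous variable plays that role (it is
#' regressed on the binary labels, so gross measurement errors appear as
#' response outliers and are trimmed).
#'
#' @inheritParams lws_fit
#' @return an object of class \code{"correlation_estimate"} with elements
#'   \code{value}, \code{scheme}, \code{n}, and \code{fit}.
#' @export
r_lws <- function(U, V, scheme = weight_scheme("adaptive"), seed = 1L, ...) {
  fit <- lws_fit(U, V, scheme = scheme, seed = seed, ...)
  w <- fit$weights
  su2 <- sum(w * (U - fit$weighted_mean_U)^2)
  sv2 <- sum(w * (V - fit$weighted_mean_V)^2)
  if (su2 <= 0 || sv2 <= 0)
    stop("undefined correlation: zero weighted variance of U or V")
  val <- fit$beta1 * sqrt(su2) / sqrt(sv2)
  val <- max(-1, min(1, val))
  structure(list(value = val, scheme = fit_scheme_name(scheme), n = length(U),
                 fit = fit),
            class = "correlation_estimate")
}

fit_scheme_name <- function(scheme) scheme$kind

#' @export
print.correlation_estimate <- function(x, ...) {
  cat(sprintf("r_lws (%s weights, n = %d): %.6f\n", x$scheme, x$n, x$value))
  invisible(x)
}

#' Lower bound on the finite-sample breakdown point of the adaptive LWS
#' correlation
#'
#' The robust correlation coefficient inherits the breakdown point of the
#' LWS slope: at least min(eps0, (floor((n+1)/2) - 2)/n), where eps0 is
#' the breakdown point of the initial estimator.
#'
#' @param n number of observations, n > 2.
#' @param eps0 breakdown point of the initializer, in [0, 1].
#' @return the lower bound, a number in [0, 1/2].
#' @export
breakdown_bound <- function(n, eps0 = 1) {
  if (n <= 2) stop("n must exceed 2")
  stopifnot(eps0 >= 0, eps0 <= 1)
  min(eps0, (((n + 1) %/% 2) - 2) / n)
}
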