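#' Specification of the two-group synthetic benchmark generator
#'
#' Emulates the structure of a two-group expression study with n much
#' smaller than p: a small set of informative variables whose class means
#' differ by \code{effect} within-class standard deviations, and
#' correlated blocks planted among the remaining noise variables to give
#' the redundancy penalty something to act on. Defaults mirror the
#' benchmark design: 24 + 24 samples and 10 informative variables at
#' effect 1.5 SD among p = 500 (a desk-scale stand-in for a whole-genome
#' panel).
#'
#' @param n1,n2 class sizes, at least 2 each.
#' @param p total number of variables.
#' @param p_inf number of informative variables (the leading columns).
#' @param effect between-class mean shift in within-class SD units.
#' @param block_rho equicorrelation inside noise blocks, |rho| < 1.
#' @param block_size number of variables per noise block.
#' @param seed integer seed.
#' @return an object of class \code{"generator_spec"}.
#' @export
generator_spec <- function(n1 = 24L, n2 = 24L, p = 500L, p_inf = 10L,
                           effect = 1.5, block_rho = 0.3, block_size = 10L,
                           seed = 1L) {
  stopifnot(n1 >= 2L, n2 >= 2L, p >= 1L, p_inf >= 0L, p_inf <= p,
            abs(block_rho) < 1, block_size >= 1L)
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2), p = as.integer(p),
                 p_inf = as.integer(p_inf), effect = effect,
                 block_rho = block_rho, block_size = as.integer(block_size),
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a planted two-group data matrix
#'
#' Class-conditional Gaussian data with unit within-class variance. The
#' first \code{p_inf} columns are mutually independent informative
#' variables (mean 0 in group 1, \code{effect} in group 2); the remaining
#' columns are pure noise arranged in consecutive equicorrelated blocks
#' of \code{block_size} variables sharing pairwise correlation
#' \code{block_rho}. The ground-truth informative indices are recorded in
#' the \code{informative} attribute of the result.
#'
#' @param spec a [generator_spec].
#' @return a [data_matrix] with labels 1 (first n1 rows) and 2.
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n1 + spec$n2
  X <- with_seed(spec$seed, {
    M <- matrix(stats::rnorm(n * spec$p), n, spec$p)
    p_noise <- spec$p - spec$p_inf
    if (p_noise > 0L && spec$block_rho != 0) {
      blocks <- split(seq_len(p_noise) + spec$p_inf,
                      (seq_len(p_noise) - 1L) %/% spec$block_size)
      for (b in blocks) {
        shared <- stats::rnorm(n)
        M[, b] <- sqrt(spec$block_rho) * shared +
          sqrt(1 - spec$block_rho) * M[, b]
      }
    }
    M
  })
  if (spec$p_inf > 0L)
    X[seq.int(spec$n1 + 1L, n), seq_len(spec$p_inf)] <-
      X[seq.int(spec$n1 + 1L, n), seq_len(spec$p_inf), drop = FALSE] + spec$effect
  data_matrix(X, rep(1:2, c(spec$n1, spec$n2)),
              informative = seq_len(spec$p_inf))
}

#' Additive noise model
#'
#' Three distributional models for cell-wise additive contamination:
#' \describe{
#'   \item{\code{"gauss"}}{Normal(0, gauss_var), default variance 0.1.}
#'   \item{\code{"contam_normal"}}{the scale mixture
#'     Delta N(0, var_main) + (1 - Delta) N(0, var_tail), defaults
#'     Delta = 0.85, variances 0.01 and 1 — occasional gross errors on a
#'     quiet background.}
#'   \item{\code{"cauchy"}}{Cauchy with density c / (pi (x^2 + c^2)),
#'     default scale c = 0.002: tiny interquartile range (2c) but
#'     arbitrarily heavy tails.}
#' }
#'
#' @param kind one of \code{"gauss"}, \code{"contam_normal"},
#'   \code{"cauchy"}.
#' @param gauss_var variance of the Gaussian model.
#' @param contam_delta mixing weight Delta in [0, 1].
#' @param contam_var_main,contam_var_tail variances of the mixture
#'   components.
#' @param cauchy_c Cauchy scale c > 0.
#' @return an object of class \code{"noise_model"}.
#' @export
noise_model <- function(kind = c("gauss", "contam_normal", "cauchy"),
                        gauss_var = 0.1, contam_delta = 0.85,
                        contam_var_main = 0.01, contam_var_tail = 1,
                        cauchy_c = 0.002) {
  kind <- match.arg(kind)
  stopifnot(gauss_var > 0, contam_delta >= 0, contam_delta <= 1,
            contam_var_main > 0, contam_var_tail > 0, cauchy_c > 0)
  structure(list(kind = kind, gauss_var = gauss_var,
                 contam_delta = contam_delta,
                 contam_var_main = contam_var_main,
                 contam_var_tail = contam_var_tail, cauchy_c = cauchy_c),
            class = "noise_model")
}

# draw m iid noise values from a noise_model (RNG state of the caller)
draw_noise <- function(noise, m) {
  switch(noise$kind,
    gauss = stats::rnorm(m, sd = sqrt(noise$gauss_var)),
    contam_normal = {
      tail <- stats::runif(m) > noise$contam_delta
      sd <- ifelse(tail, sqrt(noise$contam_var_tail),
                   sqrt(noise$contam_var_main))
      stats::rnorm(m, sd = sd)
    },
    cauchy = stats::rcauchy(m, scale = noise$cauchy_c))
}

#' Contaminate a data matrix with cell-wise additive noise
#'
#' Adds an independent draw from the noise model to every cell of the
#' data matrix, independently of variable and observation; labels and
#' metadata are untouched.
#'
#' @param data a [data_matrix].
#' @param noise a [noise_model].
#' @param seed integer seed.
#' @return a [data_matrix] with \code{X + E}.
#' @export
contaminate <- function(data, noise, seed = 1L) {
  stopifnot(inherits(data, "data_matrix"), inherits(noise, "noise_model"))
  E <- with_seed(seed, draw_noise(noise, length(data$X)))
  out <- data
  out$X <- data$X + matrix(E, nrow(data$X), ncol(data$X))
  out
}
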