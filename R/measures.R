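#' Relevance and redundancy measure specification
#'
#' A single interface over the catalogue of association measures used by
#' the forward search. Relevance measures score the association between
#' the binary label vector and one continuous variable; redundancy
#' measures score the similarity between continuous variables.
#'
#' Relevance names: \code{mutual_information}, \code{pearson_abs},
#' \code{spearman_abs}, \code{lws_adaptive_abs}, \code{lws_linear_abs},
#' \code{lws_logistic_abs}. Redundancy names: \code{mutual_information},
#' \code{pearson_abs}, \code{spearman_abs}, \code{ks_pvalue} (two-sample
#' Kolmogorov-Smirnov p-value; large = similar distributions = redundant),
#' \code{sign_pvalue} (exact sign test on paired differences), and
#' \code{reg_multiple} (the regularized multiple correlation, a set-level
#' measure delegated to [reg_multiple_corr]).
#'
#' @param role \code{"relevance"} or \code{"redundancy"}.
#' @param name measure name, see Details.
#' @param bins number of equal-frequency bins for mutual information.
#' @param scheme a [weight_scheme]; built automatically for the
#'   \code{lws_*} names.
#' @return an object of class \code{"measure_spec"}.
#' @export
measure_spec <- function(role = c("relevance", "redundancy"), name,
                         bins = 3L, scheme = NULL) {
  role <- match.arg(role)
  rel_names <- c("mutual_information", "pearson_abs", "spearman_abs",
                 "lws_adaptive_abs", "lws_linear_abs", "lws_logistic_abs")
  red_names <- c("mutual_information", "pearson_abs", "spearman_abs",
                 "ks_pvalue", "sign_pvalue", "reg_multiple")
  valid <- if (role == "relevance") rel_names else red_names
  if (!name %in% valid)
    stop("'", name, "' is not a valid ", role, " measure; choose one of: ",
         paste(valid, collapse = ", "))
  if (is.null(scheme) && startsWith(name, "lws_"))
    scheme <- weight_scheme(sub("_abs$", "", sub("^lws_", "", name)))
  structure(list(role = role, name = name, bins = as.integer(bins),
                 scheme = scheme),
            class = "measure_spec")
}

# equal-frequency discretization into at most `bins` bins
discretize_ef <- function(x, bins) {
  qs <- unique(stats::quantile(x, probs = seq_len(bins - 1L) / bins,
                               type = 1L, names = FALSE))
  findInterval(x, qs, left.open = TRUE) + 1L
}

# mutual information (nats) of a contingency table of two discrete codes
mi_nats <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pi_ <- rowSums(p); pj <- colSums(p)
  e <- outer(pi_, pj)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / e[nz]))
}

#' Relevance of one variable for the binary labels
#'
#' @param Y integer label vector with values in \{1, 2\}.
#' @param Xk numeric vector, one variable across samples.
#' @param measure a relevance [measure_spec].
#' @param seed integer seed (consumed by the LWS measures).
#' @return a nonnegative number; a constant variable scores 0 with a
#'   warning (it carries no class information).
#' @export
relevance_one <- function(Y, Xk, measure, seed = 1L) {
  if (measure$role != "relevance") stop("measure role must be 'relevance'")
  if (length(Y) != length(Xk)) stop("Y and Xk must have the same length")
  if (max(Xk) == min(Xk)) {
    warning("constant variable has zero relevance")
    return(0)
  }
  yv <- as.numeric(Y)
  switch(measure$name,
    pearson_abs = abs(stats::cor(Xk, yv)),
    spearman_abs = abs(stats::cor(Xk, yv, method = "spearman")),
    mutual_information = mi_nats(discretize_ef(Xk, measure$bins), Y),
    # the variable is regressed on the labels (two-sample location model),
    # so gross cells in Xk are response outliers that the rank weights trim
    abs(r_lws(yv, Xk, scheme = measure$scheme, seed = seed)$value))
}

#' Mean relevance of a set of variables
#'
#' Arithmetic mean of [relevance_one] over the members of the set.
#'
#' @param Y label vector.
#' @param S integer vector of column indices, nonempty.
#' @param X data matrix (samples in rows).
#' @param measure a relevance [measure_spec].
#' @param seed integer seed.
#' @return a nonnegative number.
#' @export
relevance_set <- function(Y, S, X, measure, seed = 1L) {
  if (length(S) == 0L) stop("S must be nonempty")
  vals <- vapply(S, function(j)
    relevance_one(Y, X[, j], measure, seed = child_seed(seed, j)), numeric(1L))
  mean(vals)
}

#' Pairwise redundancy between two variables
#'
#' @param Xk,Xl numeric vectors of equal length.
#' @param measure a redundancy [measure_spec] other than
#'   \code{reg_multiple} (which is set-level, not pairwise).
#' @return a nonnegative number; the p-value measures lie in [0, 1] and
#'   are oriented so that large values mean redundant.
#' @export
redundancy_pairwise <- function(Xk, Xl, measure) {
  if (measure$role != "redundancy") stop("measure role must be 'redundancy'")
  if (measure$name == "reg_multiple")
    stop("reg_multiple is a set-level measure; use redundancy_set with a candidate")
  if (length(Xk) != length(Xl)) stop("Xk and Xl must have the same length")
  switch(measure$name,
    pearson_abs = abs(stats::cor(Xk, Xl)),
    spearman_abs = abs(stats::cor(Xk, Xl, method = "spearman")),
    mutual_information = mi_nats(discretize_ef(Xk, measure$bins),
                                 discretize_ef(Xl, measure$bins)),
    ks_pvalue = suppressWarnings(stats::ks.test(Xk, Xl)$p.value),
    sign_pvalue = {
      d <- Xk - Xl
      d <- d[d != 0]
      if (length(d) == 0L) 1
      else stats::binom.test(sum(d > 0), length(d))$p.value
    })
}

#' Redundancy of a set of variables
#'
#' For the classical pairwise measures this is the double mean over all
#' ordered pairs (k, l) of the set, diagonal included — so the redundancy
#' of a singleton is the measure's self-similarity (1 for the
#' correlation-type and p-value measures). For \code{reg_multiple} the
#' set-level regularized multiple correlation between the candidate and
#' the set is returned.
#'
#' @param S integer vector of column indices, nonempty.
#' @param X data matrix (samples in rows).
#' @param measure a redundancy [measure_spec].
#' @param candidate column index of the candidate variable, required for
#'   \code{reg_multiple}.
#' @return a nonnegative number.
#' @export
redundancy_set <- function(S, X, measure, candidate = NULL) {
  if (length(S) == 0L) stop("S must be nonempty")
  if (measure$name == "reg_multiple") {
    if (is.null(candidate))
      stop("reg_multiple redundancy requires a candidate column")
    return(reg_multiple_corr(X[, candidate], X[, S, drop = FALSE])$value)
  }
  s <- length(S)
  total <- 0
  for (a in seq_len(s)) {
    total <- total + redundancy_pairwise(X[, S[a]], X[, S[a]], measure)
    if (a < s) for (b in seq.int(a + 1L, s)) {
      total <- total + 2 * redundancy_pairwise(X[, S[a]], X[, S[b]], measure)
    }
  }
  total / s^2
}
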