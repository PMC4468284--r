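#' Configuration of the forward variable-selection search
#'
#' @param m target number of selected variables, at least 1.
#' @param gamma nonnegative trade-off weight on redundancy in the
#'   criterion relevance - gamma * redundancy; values above 1 are allowed
#'   since relevance and redundancy need not share a scale.
#' @param relevance a relevance [measure_spec]; default the adaptive LWS
#'   robust correlation (the MRRMRR choice).
#' @param redundancy a redundancy [measure_spec]; default the regularized
#'   multiple correlation.
#' @param redundancy_mode for \code{reg_multiple} redundancy:
#'   \code{"multiple"} (default) uses the set-level regularized multiple
#'   correlation of the candidate against the selected set;
#'   \code{"pairwise_mean"} averages the shrunken pairwise correlations
#'   (1 - lambda*) |r-tilde(X_k, Z)| taken from the jointly regularized
#'   matrix.
#' @param seed integer seed governing every randomized step.
#' @return an object of class \code{"selection_config"}.
#' @export
selection_config <- function(m, gamma = 0,
                             relevance = measure_spec("relevance", "lws_adaptive_abs"),
                             redundancy = measure_spec("redundancy", "reg_multiple"),
                             redundancy_mode = c("multiple", "pairwise_mean"),
                             seed = 1L) {
  redundancy_mode <- match.arg(redundancy_mode)
  stopifnot(m >= 1L, gamma >= 0,
            inherits(relevance, "measure_spec"),
            inherits(redundancy, "measure_spec"))
  structure(list(m = as.integer(m), gamma = gamma, relevance = relevance,
                 redundancy = redundancy, redundancy_mode = redundancy_mode,
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Relevance of every column
#'
#' Computes [relevance_one] for all p columns, each under a child seed
#' derived from the column index, so the result does not depend on
#' evaluation order. This is the dominant cost of a robust selection run
#' (one LWS regression per column) and is cached across gamma values by
#' [gamma_search].
#'
#' @param data a [data_matrix].
#' @param measure a relevance [measure_spec].
#' @param seed integer seed.
#' @return numeric vector of p relevance values.
#' @export
relevance_all <- function(data, measure, seed = 1L) {
  vapply(seq_len(ncol(data$X)), function(j)
    relevance_one(data$Y, data$X[, j], measure, seed = child_seed(seed, j)),
    numeric(1L))
}

#' Most relevant single variable
#'
#' @param data a [data_matrix].
#' @param relevance a relevance [measure_spec].
#' @param seed integer seed.
#' @return the column index of the maximal relevance; ties go to the
#'   smallest index.
#' @export
first_variable <- function(data, relevance, seed = 1L) {
  which.max(relevance_all(data, relevance, seed))
}

#' Score of a candidate variable against the current set
#'
#' The forward-search criterion relevance(Z) - gamma * redundancy(Z, S).
#' The redundancy term depends on the configured measure: the set-level
#' regularized multiple correlation, the mean shrunken pairwise
#' correlation, or the mean classical pairwise redundancy over the
#' selected set.
#'
#' @param Z column index of the candidate, not in \code{S}.
#' @param S integer vector of already-selected column indices, nonempty.
#' @param data a [data_matrix].
#' @param config a [selection_config].
#' @return the scalar criterion value.
#' @export
step_score <- function(Z, S, data, config) {
  if (Z %in% S) stop("candidate is already selected")
  if (length(S) == 0L) stop("S must be nonempty")
  rel <- relevance_one(data$Y, data$X[, Z], config$relevance,
                       seed = child_seed(config$seed, Z))
  rel - config$gamma * redundancy_term(Z, S, data$X, config)
}

redundancy_term <- function(Z, S, X, config) {
  if (config$redundancy$name == "reg_multiple") {
    if (config$redundancy_mode == "multiple") {
      reg_multiple_corr(X[, Z], X[, S, drop = FALSE])$value
    } else {
      joint <- cbind(X[, S, drop = FALSE], X[, Z])
      sr <- shrink_correlation(joint)
      s <- length(S)
      mean((1 - sr$lambda_star) * abs(sr$R_tilde[seq_len(s), s + 1L]))
    }
  } else {
    mean(vapply(S, function(k)
      redundancy_pairwise(X[, k], X[, Z], config$redundancy), numeric(1L)))
  }
}

#' Greedy forward minimum-redundancy maximum-relevance selection
#'
#' Starts from the single most relevant variable and repeatedly adds the
#' unselected variable maximizing relevance - gamma * redundancy against
#' the current set, until m variables are selected. Ties go to the
#' smallest column index; the whole trace is deterministic given the
#' configuration seed.
#'
#' @param data a [data_matrix].
#' @param config a [selection_config] with \code{m <= p}.
#' @param relevance_values optional precomputed [relevance_all] vector
#'   (used by [gamma_search] to share the robust-relevance scan across
#'   gamma values).
#' @return an object of class \code{"selection_result"}: \code{selected}
#'   (indices in selection order), a \code{steps} data frame with the
#'   winning relevance, redundancy, score and shrinkage intensity per
#'   step, \code{config} and \code{variable_names}.
#' @export
mrmr_forward <- function(data, config, relevance_values = NULL) {
  X <- data$X
  p <- ncol(X)
  if (config$m > p) stop("m (", config$m, ") exceeds the number of variables (", p, ")")
  if (is.null(relevance_values))
    relevance_values <- relevance_all(data, config$relevance, config$seed)
  selected <- integer(0L)
  steps <- data.frame(index = integer(0L), relevance = numeric(0L),
                      redundancy = numeric(0L), score = numeric(0L),
                      lambda = numeric(0L))
  reg <- config$redundancy$name == "reg_multiple"
  Zstd <- if (reg) standardize_columns(X)
  Zsq <- if (reg) Zstd * Zstd
  red_rows <- NULL   # classical measures: pairwise redundancy rows, selected x p

  for (t in seq_len(config$m)) {
    if (t == 1L) {
      j <- which.max(relevance_values)
      selected <- j
      steps[1L, ] <- list(j, relevance_values[j], NA_real_,
                          relevance_values[j], NA_real_)
      if (!reg) red_rows <- matrix(NA_real_, 0L, p)
      next
    }
    cand <- setdiff(seq_len(p), selected)
    if (reg) {
      rt <- reg_redundancy_all(Zstd, Zsq, selected, cand, config$redundancy_mode)
      red <- rt$red
      lam <- rt$lambda
    } else {
      new_row <- vapply(seq_len(p), function(j)
        if (j %in% selected) NA_real_
        else redundancy_pairwise(X[, selected[length(selected)]], X[, j],
                                 config$redundancy), numeric(1L))
      red_rows <- rbind(red_rows, new_row)
      red <- colMeans(red_rows[, cand, drop = FALSE])
      lam <- rep(NA_real_, length(cand))
    }
    score <- relevance_values[cand] - config$gamma * red
    w <- which.max(score)
    j <- cand[w]
    selected <- c(selected, j)
    steps[t, ] <- list(j, relevance_values[j], red[w], score[w], lam[w])
  }
  structure(list(selected = selected, steps = steps, config = config,
                 variable_names = data$variable_names),
            class = "selection_result")
}

# Vectorized regularized redundancy of every candidate against the
# selected set: for each candidate c the joint correlation matrix of
# (selected, c) is shrunken with its own analytic intensity; the
# "multiple" mode evaluates the quadratic form through the
# eigendecomposition of the selected-set correlation block, the
# "pairwise_mean" mode averages the shrunken cross-correlations.
reg_redundancy_all <- function(Zstd, Zsq, selected, cand, mode) {
  n <- nrow(Zstd)
  s <- length(selected)
  Zs <- Zstd[, selected, drop = FALSE]
  Zc <- Zstd[, cand, drop = FALSE]
  W_bar_SS <- crossprod(Zs) / n
  S_SS <- W_bar_SS * (n / (n - 1L))
  V_SS <- (n / (n - 1L)^3) * (crossprod(Zsq[, selected, drop = FALSE]) -
                              n * W_bar_SS^2)
  off <- upper.tri(S_SS)
  num0 <- sum(V_SS[off])
  den0 <- sum(S_SS[off]^2)
  # cross terms, one column per candidate
  W_bar_SC <- crossprod(Zs, Zc) / n                         # s x C
  S_SC <- W_bar_SC * (n / (n - 1L))
  V_SC <- (n / (n - 1L)^3) *
    (crossprod(Zsq[, selected, drop = FALSE], Zsq[, cand, drop = FALSE]) -
     n * W_bar_SC^2)
  num <- num0 + colSums(V_SC)
  den <- den0 + colSums(S_SC^2)
  lam <- ifelse(den <= 0, 1, pmin(1, pmax(0, num / den)))
  if (mode == "pairwise_mean") {
    red <- (1 - lam) * colMeans(abs(S_SC))
    return(list(red = red, lambda = lam))
  }
  eg <- eigen(S_SS, symmetric = TRUE)
  theta <- eg$values
  Mq <- crossprod(eg$vectors, S_SC)                          # s x C
  D <- outer(theta, 1 - lam) + rep(lam, each = s)            # (1-lam) theta + lam
  red <- (1 - lam)^2 * colSums(Mq^2 / D)
  red <- pmin(1, pmax(0, red))
  list(red = red, lambda = lam)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d variables (gamma = %g, relevance = %s, redundancy = %s)\n",
              length(x$selected), x$config$gamma, x$config$relevance$name,
              x$config$redundancy$name))
  print(x$steps)
  invisible(x)
}
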