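#' Linear discriminant analysis for two groups
#'
#' Classical pooled-covariance LDA. The pooled within-class covariance is
#' inflated by \code{ridge} times the identity when it is numerically
#' singular (ridge \code{NULL} picks the guard value
#' \code{1e-6 trace/dim} automatically; an explicit \code{ridge = 0}
#' turns the guard off and singularity becomes an error). Priors are
#' equal by default, matching near-balanced designs; set
#' \code{priors = "empirical"} for class-frequency priors.
#'
#' @param X_train numeric matrix of training samples (rows).
#' @param Y_train labels in \{1, 2\}, both present.
#' @param ridge nonnegative ridge added to the pooled covariance when
#'   singular, or \code{NULL} for the automatic guard.
#' @param priors \code{"equal"}, \code{"empirical"}, or a length-2
#'   probability vector.
#' @return an object of class \code{"lda_model"} with \code{class_means},
#'   \code{pooled_covariance}, \code{log_priors}.
#' @export
lda_fit <- function(X_train, Y_train, ridge = NULL, priors = "equal") {
  X_train <- as.matrix(X_train)
  Y_train <- as.integer(Y_train)
  if (!all(sort(unique(Y_train)) == 1:2))
    stop("both classes must be present in the training labels")
  n1 <- sum(Y_train == 1L); n2 <- sum(Y_train == 2L)
  d <- ncol(X_train)
  mu1 <- colMeans(X_train[Y_train == 1L, , drop = FALSE])
  mu2 <- colMeans(X_train[Y_train == 2L, , drop = FALSE])
  cov_of <- function(M) if (nrow(M) > 1L) stats::cov(M) else matrix(0, d, d)
  Sp <- ((n1 - 1L) * cov_of(X_train[Y_train == 1L, , drop = FALSE]) +
         (n2 - 1L) * cov_of(X_train[Y_train == 2L, , drop = FALSE])) /
        (n1 + n2 - 2L)
  singular <- rcond_safe(Sp) < 1e-12
  if (singular) {
    if (is.null(ridge)) ridge <- 1e-6 * sum(diag(Sp)) / d
    if (ridge <= 0)
      stop("pooled covariance is singular; supply a positive ridge")
  }
  if (!is.null(ridge) && ridge > 0) Sp <- Sp + ridge * diag(d)
  if (rcond_safe(Sp) < 1e-14)
    stop("pooled covariance is singular even after ridge inflation")
  pr <- if (identical(priors, "equal")) c(0.5, 0.5)
        else if (identical(priors, "empirical")) c(n1, n2) / (n1 + n2)
        else priors / sum(priors)
  structure(list(class_means = rbind(mu1, mu2), pooled_covariance = Sp,
                 log_priors = log(pr)),
            class = "lda_model")
}

rcond_safe <- function(M) {
  if (any(!is.finite(M))) return(0)
  tryCatch(rcond(M), error = function(e) 0)
}

#' @export
predict.lda_model <- function(object, newdata, ...) {
  newdata <- matrix(as.numeric(newdata), ncol = ncol(object$class_means))
  Sinv <- solve(object$pooled_covariance)
  score <- function(g) {
    mu <- object$class_means[g, ]
    drop(newdata %*% (Sinv %*% mu)) - 0.5 * drop(mu %*% Sinv %*% mu) +
      object$log_priors[g]
  }
  ifelse(score(1L) >= score(2L), 1L, 2L)
}

#' Leave-one-out cross-validated classification after selection
#'
#' Runs the forward selection, then classifies every sample by an LDA
#' rule learned on the remaining n - 1 samples restricted to the selected
#' columns. By default selection is performed once on the full data
#' before the loop (the protocol of selecting a reduced variable set and
#' then cross-validating the classifier on it); this is optimistically
#' biased for error estimation, and \code{nested = TRUE} reruns the
#' selection inside every fold instead.
#'
#' Accuracy is defined as (sensitivity + specificity)/2, with sensitivity
#' the correct-classification rate in group 1 and specificity in group 2.
#'
#' @param data a [data_matrix] with both classes of size at least 2.
#' @param config a [selection_config].
#' @param nested logical; rerun selection inside each fold.
#' @param ridge passed to [lda_fit].
#' @param relevance_values optional cached [relevance_all] vector (only
#'   used when \code{nested = FALSE}).
#' @return a list with \code{sensitivity}, \code{specificity},
#'   \code{accuracy} and \code{selected} (the full-data selection when
#'   \code{nested = FALSE}, otherwise \code{NULL}).
#' @export
loocv <- function(data, config, nested = FALSE, ridge = NULL,
                  relevance_values = NULL) {
  n <- nrow(data$X)
  if (min(tabulate(data$Y, 2L)) < 2L) stop("both classes need at least 2 samples")
  sel <- NULL
  if (!nested) {
    sel <- mrmr_forward(data, config, relevance_values = relevance_values)
    cols <- sel$selected
  }
  pred <- integer(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(data$Y[tr])) < 2L)
      stop("a training fold contains a single class")
    if (nested) {
      fold <- data_matrix(data$X[tr, , drop = FALSE], data$Y[tr])
      cols <- mrmr_forward(fold, config)$selected
    }
    fit <- lda_fit(data$X[tr, cols, drop = FALSE], data$Y[tr], ridge = ridge)
    pred[i] <- predict(fit, data$X[i, cols, drop = FALSE])
  }
  se <- mean(pred[data$Y == 1L] == 1L)
  sp <- mean(pred[data$Y == 2L] == 2L)
  list(sensitivity = se, specificity = sp, accuracy = (se + sp) / 2,
       selected = if (nested) NULL else sel$selected)
}

#' Gamma grid search scored by cross-validated accuracy
#'
#' Repeats selection plus leave-one-out evaluation for each value of the
#' gamma grid and reports the per-gamma sensitivity, specificity and
#' accuracy; the optimal gamma is the accuracy argmax, ties going to the
#' smallest gamma. The relevance scan (the expensive robust-regression
#' pass) is computed once and shared across the grid when
#' \code{nested = FALSE}.
#'
#' @param data a [data_matrix].
#' @param base_config a [selection_config]; its gamma field is ignored.
#' @param gamma_grid nonempty vector of nonnegative gammas; default 0 to
#'   2 in steps of 0.1.
#' @param nested,ridge passed to [loocv].
#' @return an object of class \code{"cv_report"}: \code{per_gamma} data
#'   frame, \code{selected_per_gamma} list, \code{best_gamma},
#'   \code{best_accuracy}.
#' @export
gamma_search <- function(data, base_config, gamma_grid = seq(0, 2, by = 0.1),
                         nested = FALSE, ridge = NULL) {
  if (length(gamma_grid) == 0L) stop("gamma_grid must be nonempty")
  if (any(gamma_grid < 0)) stop("gamma values must be nonnegative")
  gamma_grid <- sort(gamma_grid)
  rel <- if (!nested)
    relevance_all(data, base_config$relevance, base_config$seed)
  rows <- vector("list", length(gamma_grid))
  sel_list <- vector("list", length(gamma_grid))
  for (g in seq_along(gamma_grid)) {
    cfg <- base_config
    cfg$gamma <- gamma_grid[g]
    res <- loocv(data, cfg, nested = nested, ridge = ridge,
                 relevance_values = rel)
    rows[[g]] <- data.frame(gamma = gamma_grid[g],
                            sensitivity = res$sensitivity,
                            specificity = res$specificity,
                            accuracy = res$accuracy)
    sel_list[[g]] <- res$selected
  }
  per_gamma <- do.call(rbind, rows)
  best <- which.max(per_gamma$accuracy)
  structure(list(per_gamma = per_gamma, selected_per_gamma = sel_list,
                 best_gamma = gamma_grid[best],
                 best_accuracy = per_gamma$accuracy[best]),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: best gamma = %g (accuracy %.3f)\n",
              x$best_gamma, x$best_accuracy))
  print(x$per_gamma, row.names = FALSE)
  invisible(x)
}
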