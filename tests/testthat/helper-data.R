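# shared fixture builders; everything is generated in code at test time

# bivariate normal sample with correlation rho
rbvn <- function(n, rho, seed) {
  set.seed(seed)
  u <- rnorm(n)
  v <- rho * u + sqrt(1 - rho^2) * rnorm(n)
  list(U = u, V = v)
}

# small labelled data matrix with informative leading columns
small_data <- function(n = 30, p = 8, p_inf = 2, effect = 2, seed = 1) {
  set.seed(seed)
  y <- rep(1:2, each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[y == 2L, seq_len(p_inf)] <- X[y == 2L, seq_len(p_inf)] + effect
  data_matrix(X, y)
}

# write a small csv with a group column; returns the path
write_group_csv <- function(X, groups, path = tempfile(fileext = ".csv")) {
  df <- data.frame(X, group = groups, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# independent naive greedy: no caching, no vectorization; recomputes
# every relevance and redundancy from the measure functions at each step
naive_greedy <- function(data, config) {
  p <- ncol(data$X)
  rel <- vapply(seq_len(p), function(j)
    relevance_one(data$Y, data$X[, j], config$relevance,
                  seed = mrrmrr:::child_seed(config$seed, j)), numeric(1))
  S <- which.max(rel)
  while (length(S) < config$m) {
    cand <- setdiff(seq_len(p), S)
    sc <- vapply(cand, function(z) {
      red <- if (config$redundancy$name == "reg_multiple") {
        if (config$redundancy_mode == "multiple") {
          reg_multiple_corr(data$X[, z], data$X[, S, drop = FALSE])$value
        } else {
          sr <- shrink_correlation(cbind(data$X[, S, drop = FALSE], data$X[, z]))
          mean((1 - sr$lambda_star) *
                 abs(sr$R_tilde[seq_along(S), length(S) + 1L]))
        }
      } else {
        mean(vapply(S, function(k)
          redundancy_pairwise(data$X[, k], data$X[, z], config$redundancy),
          numeric(1)))
      }
      rel[z] - config$gamma * red
    }, numeric(1))
    S <- c(S, cand[which.max(sc)])
  }
  S
}
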