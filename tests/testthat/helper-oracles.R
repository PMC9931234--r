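# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

# direct-summation Shannon entropy of a count matrix
oracle_entropy <- function(C) {
  p <- as.numeric(C) / sum(C)
  p <- p[p > 0]
  -sum(p * log(p))
}

# min-tie rank by the strict-less-than definition
oracle_rank_min <- function(x) {
  vapply(x, function(v) 1L + sum(x < v), 1L)
}

# OLS by normal equations
oracle_ols <- function(X, y) {
  X1 <- cbind(1, X)
  solve(t(X1) %*% X1, t(X1) %*% y)[, 1]
}

# exhaustive minimum within-cluster-sum-of-squares bipartition
oracle_best_bipartition <- function(x) {
  n <- length(x)
  best <- Inf
  best_lab <- NULL
  wss <- function(v) sum((v - mean(v))^2)
  for (m in 1:(2^(n - 1) - 1)) {
    g <- as.integer(intToBits(m))[1:n]
    if (all(g == g[1])) next
    w <- wss(x[g == 1]) + wss(x[g == 0])
    if (w < best) { best <- w; best_lab <- g }
  }
  list(within_ss = best, labels = best_lab)
}

within_ss <- function(x, lab) {
  sum(tapply(x, lab, function(v) sum((v - mean(v))^2)))
}

# stationary law by brute-force matrix power convergence
oracle_stationary <- function(P, power = 1000L) {
  M <- diag(nrow(P))
  # dampen periodicity with a lazy step so rows converge
  L <- 0.5 * diag(nrow(P)) + 0.5 * P
  for (i in seq_len(power)) M <- M %*% L
  M[1, ]
}

random_counts <- function(k = 4L, max_count = 40L) {
  repeat {
    C <- matrix(sample.int(max_count + 1L, k * k, replace = TRUE) - 1L, k, k)
    if (sum(C) >= 1L) return(C)
  }
}

random_chain <- function(k = 4L) {
  P <- matrix(runif(k * k, 0.05, 1), k, k)
  P / rowSums(P)
}

# a 15-minute series data frame from explicit times/scores
mk_series <- function(t, score = NULL) {
  if (is.null(score)) score <- runif(length(t), 0, 8)
  data.frame(t_minutes = as.integer(t), score = score)
}

# binned state series with full adjacency, directly from a state vector
mk_states <- function(states, gap_after = integer(0)) {
  t <- 30L * (seq_along(states) - 1L)
  for (g in gap_after) t[(g + 1L):length(t)] <- t[(g + 1L):length(t)] + 30L
  df <- data.frame(t_minutes = t, score = states + 0.5, state = as.integer(states))
  df$adjacent_next <- c(diff(df$t_minutes) == 30L, FALSE)
  df
}
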