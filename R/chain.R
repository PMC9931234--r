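#' Specify a discrete illness-state Markov chain
#'
#' A chain is parameterized by the probability mass retained on the diagonal
#' of each row ("stickiness") and a rule for spreading the remaining mass
#' over the off-diagonal entries. Heterogeneous stickiness across states is
#' what produces non-uniform stationary laws, and hence the low end of the
#' transition-entropy spectrum.
#'
#' @param n_states number of discrete states (default 4).
#' @param stickiness scalar or length-`n_states` vector of diagonal
#'   probabilities, each in \[0, 1\].
#' @param spread how off-diagonal mass is distributed: `"uniform"` splits it
#'   equally over the other states; `"decay"` halves the weight with each
#'   additional step of state distance, so transitions to neighbouring
#'   severity levels dominate.
#' @return an object of class `chain_spec`.
#' @export
chain_spec <- function(n_states = 4L, stickiness = 0.9,
                       spread = c("uniform", "decay")) {
  spread <- match.arg(spread)
  n_states <- as.integer(n_states)
  if (length(n_states) != 1L || is.na(n_states) || n_states < 2L)
    stop("n_states must be a single integer >= 2")
  if (!length(stickiness) %in% c(1L, n_states))
    stop("stickiness must have length 1 or n_states")
  if (any(!is.finite(stickiness)) || any(stickiness < 0) || any(stickiness > 1))
    stop("stickiness must lie in [0, 1]")
  structure(
    list(n_states = n_states,
         stickiness = rep_len(as.numeric(stickiness), n_states),
         spread = spread),
    class = "chain_spec")
}

#' Build the row-stochastic transition matrix of a chain spec
#'
#' @param spec a [chain_spec()].
#' @return an `n_states` x `n_states` matrix whose rows sum to 1.
#' @export
make_chain <- function(spec) {
  if (!inherits(spec, "chain_spec")) spec <- do.call(chain_spec, spec)
  n <- spec$n_states
  s <- spec$stickiness
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    P[i, i] <- s[i]
    if (n > 1L) {
      w <- switch(spec$spread,
                  uniform = rep(1, n - 1L),
                  decay   = 2^-(abs(seq_len(n)[-i] - i) - 1))
      P[i, -i] <- (1 - s[i]) * w / sum(w)
    }
  }
  dimnames(P) <- list(from = as.character(0:(n - 1L)),
                      to   = as.character(0:(n - 1L)))
  P
}

.check_stochastic <- function(P, tol = 1e-8) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop("P must be a square matrix")
  if (any(!is.finite(P)) || any(P < -tol))
    stop("P must have finite nonnegative entries")
  if (any(abs(rowSums(P) - 1) > tol))
    stop("rows of P must sum to 1")
  invisible(P)
}

.is_irreducible <- function(P) {
  # boolean reachability: state graph strongly connected
  n <- nrow(P)
  A <- (P > 0) + diag(n)
  R <- A
  for (k in seq_len(ceiling(log2(n)) + 1L)) R <- (R %*% R) > 0
  all(R > 0)
}

#' Stationary distribution of an irreducible finite chain
#'
#' Solves the global balance equations `pi P = pi`, `sum(pi) = 1` by least
#' squares on the augmented linear system. Reducible chains, which need not
#' have a unique stationary law, are rejected.
#'
#' @param P row-stochastic matrix.
#' @return probability vector `pi` with `pi %*% P == pi`.
#' @export
stationary_distribution <- function(P) {
  .check_stochastic(P)
  if (!.is_irreducible(P))
    stop("chain is reducible: no unique stationary distribution")
  n <- nrow(P)
  A <- rbind(t(P) - diag(n), rep(1, n))
  pi <- qr.solve(A, c(rep(0, n), 1))
  pi[pi < 0 & pi > -1e-12] <- 0
  if (any(pi < 0)) stop("stationary solve produced negative mass")
  pi / sum(pi)
}

.xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

#' Shannon entropy of a chain's stationary joint transition law
#'
#' The joint law puts mass `q_ij = pi_i P_ij` on the transition (i, j); its
#' Shannon entropy (natural log, with 0 log 0 := 0) is the population value
#' that the per-admission empirical transition-density entropy estimates.
#'
#' @param P row-stochastic matrix.
#' @param pi optional stationary distribution; computed from `P` when `NULL`.
#'   Supplying `pi` permits degenerate cases (e.g. an absorbing chain
#'   started in its absorbing state) that have no unique stationary law.
#' @return entropy in nats, in \[0, log(n^2)\].
#' @export
true_entropy <- function(P, pi = NULL) {
  .check_stochastic(P)
  if (is.null(pi)) pi <- stationary_distribution(P)
  if (length(pi) != nrow(P) || any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop("pi must be a probability vector matching P")
  q <- pi * P   # recycles pi down columns: q[i, j] = pi[i] * P[i, j]
  -sum(.xlogx(q)) + 0   # + 0 normalizes IEEE negative zero
}

#' Simulate a state path from a transition matrix
#'
#' @param P row-stochastic matrix.
#' @param n_steps number of states to emit.
#' @param start initial state in `0:(nrow(P)-1)`; drawn from the stationary
#'   distribution when `NULL`.
#' @return integer vector of states, length `n_steps`.
#' @export
simulate_states <- function(P, n_steps, start = NULL) {
  .check_stochastic(P)
  n <- nrow(P)
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (is.null(start)) {
    start <- sample.int(n, 1L, prob = stationary_distribution(P)) - 1L
  }
  start <- as.integer(start)
  if (start < 0L || start >= n) stop("start state out of range")
  cum <- t(apply(P, 1, cumsum))
  s <- integer(n_steps)
  s[1L] <- start
  if (n_steps > 1L) {
    u <- runif(n_steps - 1L)
    cur <- start
    for (t in 2:n_steps) {
      cur <- findInterval(u[t - 1L], cum[cur + 1L, ], left.open = TRUE)
      s[t] <- cur
    }
  }
  s
}
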