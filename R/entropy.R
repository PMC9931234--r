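#' Count illness-state transitions for one admission
#'
#' Entry (i, j) counts the adjacent 30-minute pairs that moved from state i
#' to state j. Pairs spanning a gap (no `adjacent_next` flag) contribute
#' nothing.
#'
#' @param states binned series from [bin_scores()] (columns `t_minutes`,
#'   `state`, `adjacent_next`).
#' @param k number of states.
#' @return `k` x `k` integer matrix of class `transition_counts` with
#'   attribute `n_transitions`.
#' @export
count_transitions <- function(states, k = 4L) {
  if (!all(c("state", "adjacent_next") %in% names(states)))
    stop("states must come from bin_scores()")
  s <- states$state
  if (length(s) && (any(s < 0L) || any(s >= k)))
    stop(sprintf("states outside 0..%d", k - 1L))
  C <- matrix(0L, k, k,
              dimnames = list(from = as.character(0:(k - 1L)),
                              to   = as.character(0:(k - 1L))))
  idx <- which(states$adjacent_next[-length(s)])
  if (length(s) >= 2L && length(idx)) {
    from <- s[idx]
    to <- s[idx + 1L]
    tab <- table(factor(from, levels = 0:(k - 1L)),
                 factor(to, levels = 0:(k - 1L)))
    C[] <- as.integer(tab)
  }
  structure(C, n_transitions = sum(C), class = c("transition_counts", "matrix"))
}

#' @export
print.transition_counts <- function(x, ...) {
  cat("Transition counts (", attr(x, "n_transitions"), " pairs)\n", sep = "")
  print(unclass(x)[,])
  invisible(x)
}

#' Row-normalized Markov transition probability matrix
#'
#' Each visited row (positive count total) is divided by its row total so
#' it sums to one. Rows for initial states never observed are left
#' all-zero and flagged in the `visited` attribute rather than filled in.
#'
#' @param counts a `transition_counts` matrix.
#' @return matrix of class `transition_probs` with attribute `visited`.
#' @export
transition_matrix <- function(counts) {
  N <- attr(counts, "n_transitions")
  if (is.null(N)) N <- sum(counts)
  if (N < 1L) stop("no observed transitions")
  C <- unclass(counts)
  rs <- rowSums(C)
  visited <- rs > 0
  P <- C * 0
  P[visited, ] <- C[visited, , drop = FALSE] / rs[visited]
  structure(P, visited = visited, class = c("transition_probs", "matrix"))
}

#' @export
print.transition_probs <- function(x, digits = 3, ...) {
  cat("Transition probabilities (unvisited rows masked)\n")
  m <- round(unclass(x)[,], digits)
  m[!attr(x, "visited"), ] <- NA
  print(m)
  invisible(x)
}

#' Joint transition-density ("entropy") matrix
#'
#' Divides every cell of the count matrix by the total number of observed
#' transitions, so all cells sum to one: cell (i, j) is the density of
#' observed i-to-j transitions. This joint density, not the row-conditional
#' matrix, is the distribution whose Shannon entropy summarizes an
#' admission.
#'
#' @param counts a `transition_counts` matrix.
#' @return `k` x `k` density matrix (class `entropy_matrix`).
#' @export
entropy_matrix <- function(counts) {
  N <- attr(counts, "n_transitions")
  if (is.null(N)) N <- sum(counts)
  if (N < 1L) stop("no observed transitions")
  structure(unclass(counts) / N, class = c("entropy_matrix", "matrix"))
}

#' Shannon entropy of a transition density
#'
#' `H = -sum(p * log(p))` over the cells of the density matrix, in natural
#' logarithms with the convention 0 log 0 := 0. For a `k`-state chain the
#' value lies in \[0, log(k^2)\]; with k = 4 the maximum is log 16 = 2.77.
#'
#' @param density an [entropy_matrix()] (or any nonnegative array summing
#'   to 1).
#' @param tol tolerance on the sum-to-one check.
#' @return entropy in nats.
#' @export
shannon_entropy <- function(density, tol = 1e-8) {
  d <- as.numeric(density)
  if (any(!is.finite(d)) || any(d < 0))
    stop("density must be nonnegative and finite")
  if (abs(sum(d) - 1) > tol)
    stop("density cells must sum to 1")
  -sum(.xlogx(d)) + 0   # + 0 normalizes IEEE negative zero
}

#' Per-admission summary: entropy, mean score, observation counts
#'
#' The mean illness score is the mean of the retained continuous 30-minute
#' scores (after resampling and adjacency filtering, before binning).
#' Admissions with fewer valid transition pairs than `min_pairs` are
#' flagged `low_data` and should be excluded from clustering.
#'
#' @param states one admission's binned series.
#' @param k number of states.
#' @param min_pairs minimum valid adjacent pairs (default 2).
#' @return one-row data frame: `entropy_nats`, `mean_score`, `n_obs`,
#'   `n_transitions`, `flag`.
#' @export
admission_summary <- function(states, k = 4L, min_pairs = 2L) {
  C <- count_transitions(states, k = k)
  N <- attr(C, "n_transitions")
  H <- if (N >= 1L) shannon_entropy(entropy_matrix(C)) else NA_real_
  data.frame(
    entropy_nats = H,
    mean_score = if (nrow(states)) mean(states$score) else NA_real_,
    n_obs = nrow(states),
    n_transitions = N,
    flag = if (N < min_pairs) "low_data" else "ok")
}

#' Entropy table for a prepared cohort
#'
#' @param prepped result of [prep_cohort()].
#' @param min_pairs minimum valid pairs per admission.
#' @return data frame with one row per admission: `admission_id`,
#'   `entropy_nats`, `mean_score`, `n_obs`, `n_transitions`, `flag`.
#' @export
cohort_entropy <- function(prepped, min_pairs = 2L) {
  k <- prepped$scheme$k
  per <- lapply(split(prepped$states, prepped$states$admission_id),
                admission_summary, k = k, min_pairs = min_pairs)
  out <- cbind(admission_id = names(per), do.call(rbind, per))
  rownames(out) <- NULL
  out
}
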