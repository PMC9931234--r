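#' Define a score-to-state binning scheme
#'
#' States are half-open intervals `[low, high)` delimited by `k - 1`
#' ascending interior edges; the last interval is unbounded above. The
#' default fixed scheme uses edges (1, 2, 3): state 0 holds scores in
#' \[0, 1), state 1 in \[1, 2), state 2 in \[2, 3), and state 3 scores of 3
#' or higher.
#'
#' @param edges strictly increasing interior cut points.
#' @param kind `"fixed"` or `"equiprobable"` (the latter usually built by
#'   [equiprobable_edges()]).
#' @return object of class `binning_scheme`.
#' @export
binning_scheme <- function(edges = c(1, 2, 3), kind = c("fixed", "equiprobable")) {
  kind <- match.arg(kind)
  edges <- as.numeric(edges)
  if (length(edges) < 1L || any(!is.finite(edges)) || is.unsorted(edges, strictly = TRUE))
    stop("edges must be strictly increasing and finite")
  structure(list(edges = edges, k = length(edges) + 1L, kind = kind),
            class = "binning_scheme")
}

.check_series <- function(df, grid = 15L) {
  if (!all(c("t_minutes", "score") %in% names(df)))
    stop("series needs columns t_minutes and score")
  if (nrow(df) > 1L && is.unsorted(df$t_minutes, strictly = TRUE))
    stop("t_minutes must be strictly increasing")
  if (nrow(df) > 0L && any(df$t_minutes %% grid != 0))
    stop(sprintf("t_minutes must be multiples of the %d-minute grid", grid))
  invisible(df)
}

#' Thin a 15-minute series to the 30-minute analysis grid
#'
#' Keeps observations whose offset from the admission's first observation
#' is a multiple of 30 minutes. Anchoring at the first observation (rather
#' than at clock time 0) means a series starting at t = 15 keeps
#' t = 15, 45, 75, ...
#'
#' @param series data frame with `t_minutes`, `score` (and optionally
#'   `admission_id`).
#' @return the thinned series.
#' @export
resample_30min <- function(series) {
  .check_series(series)
  if (nrow(series) == 0L) {
    warning("empty series")
    return(series)
  }
  keep <- (series$t_minutes - series$t_minutes[1L]) %% 30L == 0L
  out <- series[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop observations with no 30-minute neighbour
#'
#' An observation is retained iff another observation sits exactly 30
#' minutes (within `tol` minutes) before or after it; only such adjacent
#' pairs can contribute transitions. The number of removals is attached as
#' attribute `n_removed`.
#'
#' @param series a 30-minute-grid series.
#' @param tol tolerance in minutes for the 30-minute spacing (default 0;
#'   real monitor data may need +/-1).
#' @return filtered series with attribute `n_removed`.
#' @export
remove_nonadjacent <- function(series, tol = 0) {
  .check_series(series)
  n <- nrow(series)
  if (n == 0L) {
    attr(series, "n_removed") <- 0L
    return(series)
  }
  t <- series$t_minutes
  gap_prev <- c(Inf, diff(t))
  gap_next <- c(diff(t), Inf)
  keep <- abs(gap_prev - 30) <= tol | abs(gap_next - 30) <= tol
  out <- series[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Bin continuous risk scores into discrete illness states
#'
#' Each score maps to the index of the half-open interval containing it, so
#' interval boundaries map upward (a score of exactly 2 falls in state 2
#' under the fixed scheme). Negative scores are an error; scores above 8
#' are clipped to 8 with a warning.
#'
#' @param series score series (any grid).
#' @param scheme a [binning_scheme()].
#' @return the series with an integer `state` column added and an
#'   `adjacent_next` flag marking rows whose successor is exactly 30
#'   minutes later (the valid transition pairs).
#' @export
bin_scores <- function(series, scheme = binning_scheme()) {
  if (!inherits(scheme, "binning_scheme")) stop("scheme must be a binning_scheme")
  .check_series(series)
  x <- series$score
  if (any(!is.finite(x))) stop("scores must be finite")
  if (any(x < 0)) stop("negative risk scores are not valid")
  if (any(x > 8)) {
    warning(sprintf("%d score(s) above 8 clipped", sum(x > 8)))
    x <- pmin(x, 8)
    series$score <- x
  }
  series$state <- findInterval(x, scheme$edges)
  series$adjacent_next <- c(diff(series$t_minutes) == 30L, FALSE)
  series
}

#' Equiprobable state edges from pooled scores
#'
#' Places the `k - 1` interior edges at the 1/k, 2/k, ... empirical
#' quantiles of the pooled analysis-ready scores (linear-interpolation
#' quantile definition, R type 7), so each state holds an equal share of
#' observations up to ties.
#'
#' @param pooled_scores all admissions' retained 30-minute scores.
#' @param k number of states (default 4).
#' @return a `binning_scheme` of kind `"equiprobable"`.
#' @export
equiprobable_edges <- function(pooled_scores, k = 4L) {
  x <- as.numeric(pooled_scores)
  x <- x[is.finite(x)]
  if (length(x) < k) stop("need at least k pooled scores")
  if (length(unique(x)) < k)
    stop("fewer than k distinct score values: equiprobable bins degenerate")
  e <- unname(quantile(x, probs = seq_len(k - 1L) / k, type = 7))
  if (is.unsorted(e, strictly = TRUE))
    stop("tied quantiles: equiprobable bins degenerate")
  binning_scheme(edges = e, kind = "equiprobable")
}

#' Prepare one admission's series for transition counting
#'
#' Runs the full prep chain: 30-minute resampling, adjacency filtering,
#' then binning.
#'
#' @param series raw 15-minute score series.
#' @param scheme a [binning_scheme()].
#' @param tol adjacency tolerance in minutes.
#' @return list with `states` (binned series), `n_raw`,
#'   `n_after_resample`, `n_removed_nonadjacent`.
#' @export
prep_series <- function(series, scheme = binning_scheme(), tol = 0) {
  n_raw <- nrow(series)
  r <- resample_30min(series)
  f <- remove_nonadjacent(r, tol = tol)
  list(states = bin_scores(f, scheme),
       n_raw = n_raw,
       n_after_resample = nrow(r),
       n_removed_nonadjacent = attr(f, "n_removed"))
}

#' Prepare a whole cohort, optionally deriving equiprobable edges
#'
#' When `binning = "equiprobable"` and no edges are supplied, edges are
#' computed from the pooled post-filter 30-minute scores of the entire
#' cohort (the analysis-ready observations), then applied per admission.
#'
#' @param scores long-format cohort table (`admission_id`, `t_minutes`,
#'   `score`).
#' @param binning `"fixed"` or `"equiprobable"`, or a ready
#'   [binning_scheme()].
#' @param k number of states when deriving equiprobable edges.
#' @param tol adjacency tolerance in minutes.
#' @return list with `states` (stacked binned series), `report`
#'   (per-admission removal counts), and `scheme`.
#' @export
prep_cohort <- function(scores, binning = "fixed", k = 4L, tol = 0) {
  if (!"admission_id" %in% names(scores))
    stop("cohort scores need an admission_id column")
  split_scores <- split(scores, scores$admission_id)
  filtered <- lapply(split_scores, function(s) {
    s <- s[order(s$t_minutes), , drop = FALSE]
    remove_nonadjacent(resample_30min(s), tol = tol)
  })

  if (inherits(binning, "binning_scheme")) {
    scheme <- binning
  } else if (identical(binning, "fixed")) {
    scheme <- binning_scheme()
  } else if (identical(binning, "equiprobable")) {
    pooled <- unlist(lapply(filtered, `[[`, "score"), use.names = FALSE)
    scheme <- equiprobable_edges(pooled, k = k)
  } else stop("binning must be 'fixed', 'equiprobable', or a binning_scheme")

  states <- lapply(filtered, bin_scores, scheme = scheme)
  report <- data.frame(
    admission_id = names(split_scores),
    n_raw = vapply(split_scores, nrow, 0L),
    n_after_resample = vapply(split_scores, function(s)
      nrow(resample_30min(s[order(s$t_minutes), ])), 0L),
    n_removed_nonadjacent = vapply(filtered, function(f)
      attr(f, "n_removed"), 0L),
    row.names = NULL)
  out_states <- do.call(rbind, states)
  rownames(out_states) <- NULL
  list(states = out_states, report = report, scheme = scheme)
}
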