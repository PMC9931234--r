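#' Minimum-tie ranks
#'
#' Ascending ranks where every member of a tie group receives the lowest
#' rank of the group: rank(x) = 1 + (number of values strictly less than
#' x). With 137 survivors (0) and 27 deaths (1), survivors rank 1 and
#' deaths rank 138.
#'
#' @param values finite numeric vector.
#' @param ascending rank smallest value 1 (default); `FALSE` reverses.
#' @return integer ranks in `1..length(values)`.
#' @export
rank_min_ties <- function(values, ascending = TRUE) {
  if (length(values) == 0L) stop("cannot rank an empty vector")
  if (any(!is.finite(values))) stop("values must be finite")
  x <- if (ascending) values else -values
  as.integer(rank(x, ties.method = "min"))
}

#' Three-component negative-outcome composite
#'
#' Sums the min-tie ranks of in-hospital mortality, ventilator days, and
#' hospital length of stay across the cohort. All three are ranked
#' ascending so that surviving, never-ventilated, shortest-stay admissions
#' receive the lowest possible composite of 3; larger values are worse.
#' Admissions missing any component are excluded with a warning.
#'
#' @param outcomes data frame with columns `admission_id`, `died` (0/1),
#'   `vent_days`, `hospital_los_days`.
#' @return data frame: `admission_id`, `rank_mortality`, `rank_vent`,
#'   `rank_los`, `composite`.
#' @export
composite_score <- function(outcomes) {
  need <- c("admission_id", "died", "vent_days", "hospital_los_days")
  miss <- setdiff(need, names(outcomes))
  if (length(miss)) stop("outcomes missing columns: ", paste(miss, collapse = ", "))
  ok <- complete.cases(outcomes[, need])
  if (any(!ok)) {
    warning(sprintf("%d admission(s) with missing components excluded", sum(!ok)))
    outcomes <- outcomes[ok, , drop = FALSE]
  }
  if (!all(outcomes$died %in% c(0, 1))) stop("died must be coded 0/1")
  if (any(outcomes$vent_days < 0) || any(outcomes$hospital_los_days < 0))
    stop("durations must be nonnegative")
  out <- data.frame(
    admission_id = outcomes$admission_id,
    rank_mortality = rank_min_ties(outcomes$died),
    rank_vent = rank_min_ties(outcomes$vent_days),
    rank_los = rank_min_ties(outcomes$hospital_los_days))
  out$composite <- out$rank_mortality + out$rank_vent + out$rank_los
  out
}
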