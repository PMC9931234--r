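#' Configuration for a synthetic admission cohort
#'
#' Defaults describe a cohort that mirrors the published setting: 164
#' admissions, ~16.5% in-hospital mortality, ICU stays log-normal around a
#' median of 13.9 days, risk scores emitted every 15 minutes, and a 0.3%
#' rate of isolated (nonconsecutive) observations. Outcome severity is
#' positively linked to each admission's true transition entropy through
#' `mortality_link` (logit slope) and `outcome_link` (log-scale slope on the
#' stay/ventilation distributions); setting both to 0 makes outcomes
#' independent of entropy.
#'
#' @param n_admissions number of admissions to simulate (>= 2).
#' @param mortality_intercept logit-scale intercept of the death
#'   probability; the default `qlogis(0.165)` yields ~16.5% mortality when
#'   `mortality_link = 0` or when entropy sits at `entropy_center`.
#' @param mortality_link logit-scale slope of death probability on centered
#'   true entropy.
#' @param outcome_link log-scale slope of stay and ventilation durations on
#'   centered true entropy.
#' @param entropy_center entropy value (nats) treated as the cohort centre
#'   when applying the links; defaults to 1.5, the middle of the generated
#'   spectrum.
#' @param stay_meanlog,stay_sdlog log-normal parameters of ICU length of
#'   stay in days (median `exp(stay_meanlog)` = 13.9 d by default).
#' @param gap_rate fraction of 30-minute observations rendered isolated by
#'   removing their grid neighbours, in \[0, 0.5).
#' @param chain_pool ranges for per-admission chain draws: a list with
#'   `home_stickiness` and `other_stickiness`, each a length-2 range. Every
#'   admission gets one high-stickiness "home" severity state; the draw
#'   ranges put the cohort's true entropies at mean ~1.5 (SD ~0.4),
#'   spanning roughly 0.5--2.0 nats.
#' @param seed integer seed controlling every random draw in
#'   [generate_cohort()].
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_admissions = 164L,
                          mortality_intercept = qlogis(0.165),
                          mortality_link = 1.3,
                          outcome_link = 0.8,
                          entropy_center = 1.5,
                          stay_meanlog = log(13.9),
                          stay_sdlog = 1.2,
                          gap_rate = 0.003,
                          chain_pool = list(home_stickiness = c(0.85, 0.9995),
                                            other_stickiness = c(0.65, 0.98)),
                          seed = 1L) {
  n_admissions <- as.integer(n_admissions)
  if (is.na(n_admissions) || n_admissions < 2L)
    stop("n_admissions must be >= 2")
  if (!is.finite(mortality_link) || !is.finite(outcome_link))
    stop("link coefficients must be finite")
  if (gap_rate < 0 || gap_rate >= 0.5)
    stop("gap_rate must lie in [0, 0.5)")
  structure(
    list(n_admissions = n_admissions,
         mortality_intercept = mortality_intercept,
         mortality_link = mortality_link,
         outcome_link = outcome_link,
         entropy_center = entropy_center,
         stay_meanlog = stay_meanlog,
         stay_sdlog = stay_sdlog,
         gap_rate = gap_rate,
         chain_pool = chain_pool,
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' Emit a raw 15-minute risk-score series from a state chain
#'
#' Simulates a 30-minute illness-state path and emits two 15-minute score
#' observations per state, each drawn uniformly from the state's score bin:
#' state s maps to \[s, s+1) for s < 3 and to \[3, 8\] for the top state.
#' Re-binning the emitted scores with the fixed scheme therefore recovers
#' the simulated path exactly. Gaps are injected by deleting the on-grid
#' observation of the two 30-minute slots flanking a target slot, leaving
#' that slot isolated (no neighbour at +/-30 min) after resampling.
#'
#' @param P row-stochastic transition matrix over states `0:(k-1)` with
#'   `k <= 8` so that every state has a score bin inside \[0, 8\].
#' @param duration_days length of the simulated stay (>= 1); 48 thirty-
#'   minute states per day.
#' @param gap_rate target fraction of 30-minute observations to isolate.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (as [generate_cohort()] does).
#' @param start optional initial state.
#' @return data frame with columns `t_minutes` (multiples of 15, from 0)
#'   and `score`, plus attributes `states` (the simulated path) and
#'   `isolated_slots`.
#' @export
simulate_admission <- function(P, duration_days, gap_rate = 0, seed = NULL,
                               start = NULL) {
  if (duration_days < 1) stop("duration_days must be >= 1 day")
  if (gap_rate < 0 || gap_rate >= 0.5) stop("gap_rate must lie in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(P)
  n30 <- as.integer(round(duration_days * 48))
  states <- simulate_states(P, n30, start = start)

  lo <- states
  hi <- ifelse(states == k - 1L, 8, states + 1)  # top bin truncated at 8
  score1 <- runif(n30, lo, hi)
  score2 <- runif(n30, lo, hi)
  df <- data.frame(
    t_minutes = as.integer(rep(30L * (seq_len(n30) - 1L), each = 2L) +
                             c(0L, 15L)),
    score = as.vector(rbind(score1, score2)))

  iso <- integer(0)
  m <- round(gap_rate * n30)
  if (m > 0) {
    # slots whose two flanking on-grid points get deleted; spacing >= 5
    # keeps removals from cascading into additional isolated slots
    cand <- sample(seq.int(2L, n30 - 3L))
    for (j in cand) {
      if (length(iso) >= m) break
      if (all(abs(iso - j) >= 5L)) iso <- c(iso, j)
    }
    drop_t <- c(30L * (iso - 1L), 30L * (iso + 1L))
    df <- df[!df$t_minutes %in% drop_t, , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "states") <- states
  attr(df, "isolated_slots") <- sort(iso)
  df
}

#' Simulate an outcomes table linked to true transition entropies
#'
#' Mortality follows a logistic model in centred entropy; ICU stay is
#' log-normal with a log-linear entropy effect; hospital stay adds a
#' log-normal post-ICU tail; ventilator days are a random fraction of the
#' ICU stay (zero for a subset of admissions), so `vent_days <=
#' icu_los_days <= hospital_los_days` always holds. Age and sex are drawn
#' to match the published cohort's descriptive distributions and carry no
#' entropy link.
#'
#' @param true_entropies numeric vector of per-admission entropies (nats).
#' @param config a [cohort_config()]; its seed is NOT applied here (the
#'   caller controls the RNG stream).
#' @return data frame with columns `admission_id`, `age_years`, `sex`,
#'   `died`, `vent_days`, `hospital_los_days`, `icu_los_days`.
#' @export
simulate_outcomes <- function(true_entropies, config = cohort_config()) {
  H <- as.numeric(true_entropies)
  if (any(!is.finite(H))) stop("true_entropies must be finite")
  n <- length(H)
  z <- H - config$entropy_center

  died <- rbinom(n, 1L, plogis(config$mortality_intercept +
                                 config$mortality_link * z))
  icu <- pmin(pmax(1, rlnorm(n, config$stay_meanlog + config$outcome_link * z,
                             config$stay_sdlog)), 180)
  hosp <- icu + rlnorm(n, log(10) + 0.5 * config$outcome_link * z, 1.0)
  vented <- rbinom(n, 1L, plogis(qlogis(0.85) + 0.6 * config$mortality_link *
                                   z / max(abs(config$mortality_link), 1)))
  frac <- plogis(rnorm(n, qlogis(0.35), 1.0))
  vent <- vented * icu * frac

  age <- pmin(rlnorm(n, log(1.7), 1.6), 17.9)
  sex <- ifelse(runif(n) < 0.51, "M", "F")

  data.frame(admission_id = sprintf("adm%03d", seq_len(n)),
             age_years = round(age, 2),
             sex = sex,
             died = died,
             vent_days = round(vent, 1),
             hospital_los_days = round(hosp, 1),
             icu_los_days = round(icu, 1))
}

#' Generate a complete synthetic cohort
#'
#' Draws one illness-state chain per admission (a high-stickiness "home"
#' state plus moderately sticky others), computes its exact stationary
#' transition entropy, simulates the 15-minute score series for an ICU stay
#' whose length matches the outcomes table, and simulates outcomes linked
#' to the true entropies. Fully deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param dir optional directory; when given, `scores.csv`, `outcomes.csv`
#'   and `truth.csv` are written there with a `#`-comment provenance header
#'   recording the seed.
#' @return (invisibly when writing) a list with data frames `scores`
#'   (admission_id, t_minutes, score), `outcomes`, and `truth`
#'   (admission_id, chain parameters, duration, true entropy).
#' @export
generate_cohort <- function(config = cohort_config(), dir = NULL) {
  set.seed(config$seed)
  n <- config$n_admissions
  pool <- config$chain_pool
  ids <- sprintf("adm%03d", seq_len(n))

  truth <- vector("list", n)
  scores <- vector("list", n)
  entropies <- numeric(n)

  # outcomes first so the ICU stay in the table drives the series length
  chains <- vector("list", n)
  for (i in seq_len(n)) {
    home <- sample.int(4L, 1L)
    u <- runif(1, pool$home_stickiness[1], pool$home_stickiness[2])
    v <- runif(3, pool$other_stickiness[1], pool$other_stickiness[2])
    s <- numeric(4)
    s[home] <- u
    s[-home] <- v
    chains[[i]] <- list(stickiness = s, home = home)
    entropies[i] <- true_entropy(make_chain(chain_spec(4L, s)))
  }
  outcomes <- simulate_outcomes(entropies, config)
  outcomes$admission_id <- ids

  for (i in seq_len(n)) {
    dur <- max(1, outcomes$icu_los_days[i])
    adm <- simulate_admission(make_chain(chain_spec(4L, chains[[i]]$stickiness)),
                              duration_days = dur,
                              gap_rate = config$gap_rate)
    adm <- cbind(admission_id = ids[i], adm)
    scores[[i]] <- adm
    s <- chains[[i]]$stickiness
    truth[[i]] <- data.frame(
      admission_id = ids[i],
      home_state = chains[[i]]$home - 1L,
      stick_0 = s[1], stick_1 = s[2], stick_2 = s[3], stick_3 = s[4],
      duration_days = dur,
      true_entropy = entropies[i])
  }

  out <- list(scores = do.call(rbind, scores),
              outcomes = outcomes,
              truth = do.call(rbind, truth))
  rownames(out$scores) <- NULL
  rownames(out$truth) <- NULL

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_cohort_csv(out$scores, file.path(dir, "scores.csv"),
                     seed = config$seed, stage = "simulate")
    write_cohort_csv(out$outcomes, file.path(dir, "outcomes.csv"),
                     seed = config$seed, stage = "simulate")
    write_cohort_csv(out$truth, file.path(dir, "truth.csv"),
                     seed = config$seed, stage = "simulate")
    return(invisible(out))
  }
  out
}

#' Write a cohort CSV with a provenance comment header
#'
#' @param df data frame to write.
#' @param path output file.
#' @param seed,stage recorded in the `#` header line.
#' @keywords internal
write_cohort_csv <- function(df, path, seed = NA, stage = "illdyn") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# illdyn stage=%s seed=%s", stage, seed), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort CSV written by this package
#' @param path file path.
#' @keywords internal
read_cohort_csv <- function(path) {
  read.csv(path, comment.char = "#")
}
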