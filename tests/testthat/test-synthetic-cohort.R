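test_that("make_chain produces the forced matrices and validates input", {
  expect_equal(make_chain(chain_spec(2L, stickiness = 1)), diag(2),
               ignore_attr = TRUE)
  expect_equal(make_chain(chain_spec(4L, stickiness = 0.25)),
               matrix(0.25, 4, 4), ignore_attr = TRUE)
  expect_equal(make_chain(chain_spec(2L, stickiness = 0.9)),
               matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_error(chain_spec(4L, stickiness = 1.2), "\\[0, 1\\]")
  expect_error(chain_spec(4L, stickiness = -0.1), "\\[0, 1\\]")
  # rows always sum to 1, both spreads, scalar and vector stickiness
  set.seed(42)
  for (spread in c("uniform", "decay")) {
    for (r in 1:20) {
      P <- make_chain(chain_spec(sample(2:6, 1), runif(1), spread))
      expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_true(all(P >= 0))
    }
  }
  s <- c(0.5, 0.8, 0.2, 0.9)
  expect_equal(diag(make_chain(chain_spec(4L, s))), s, ignore_attr = TRUE)
})

test_that("stationary_distribution solves the balance equations", {
  expect_equal(stationary_distribution(matrix(c(.9, .1, .1, .9), 2, byrow = TRUE)),
               c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(stationary_distribution(matrix(0.25, 4, 4)), rep(0.25, 4),
               tolerance = 1e-12)
  # hand-solved 2x2 balance: pi = (1/3, 2/3)
  P <- matrix(c(0.5, 0.5, 0.25, 0.75), 2, byrow = TRUE)
  expect_equal(stationary_distribution(P), c(1, 2) / 3, tolerance = 1e-12)
  expect_error(stationary_distribution(diag(2)), "reducible")
  expect_error(stationary_distribution(matrix(c(1, 0, 0.5, 0.5), 2, byrow = TRUE)),
               "reducible")
})

test_that("stationary_distribution agrees with brute-force power iteration", {
  set.seed(42)
  for (r in 1:50) {
    P <- random_chain(4L)
    expect_equal(stationary_distribution(P), oracle_stationary(P),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("true_entropy matches hand-computed joint-law values", {
  expect_equal(true_entropy(matrix(0.25, 4, 4)), log(16), tolerance = 1e-12)
  expect_equal(sprintf("%.2f", true_entropy(matrix(0.25, 4, 4))), "2.77")
  # degenerate absorbing case via explicit pi
  expect_equal(true_entropy(diag(2), pi = c(1, 0)), 0)
  # four joint cells evaluated by hand
  P <- matrix(c(.9, .1, .1, .9), 2, byrow = TRUE)
  expect_equal(true_entropy(P),
               -(2 * 0.45 * log(0.45) + 2 * 0.05 * log(0.05)),
               tolerance = 1e-12)
  # bound holds over random chains
  set.seed(42)
  for (r in 1:30) {
    k <- sample(2:5, 1)
    H <- true_entropy(random_chain(k))
    expect_gte(H, 0)
    expect_lte(H, log(k^2) + 1e-12)
  }
})

test_that("simulate_admission emits a recoverable 15-minute score series", {
  P <- make_chain(chain_spec(4L, 0.9))
  adm <- simulate_admission(P, duration_days = 14, gap_rate = 0, seed = 42)
  expect_equal(nrow(adm), 2 * 672)
  expect_true(all(adm$score >= 0 & adm$score <= 8))
  expect_equal(adm$t_minutes, 15L * (seq_len(nrow(adm)) - 1L))

  # prep recovers exactly the simulated state sequence (round trip)
  pr <- prep_series(adm)
  expect_equal(nrow(pr$states), 672)
  expect_equal(pr$states$state, attr(adm, "states"))
  expect_equal(pr$n_removed_nonadjacent, 0L)

  # frozen chain never moves: all scores stay in the start state's bin
  frozen <- simulate_admission(diag(4), duration_days = 2, seed = 1, start = 2L)
  expect_true(all(frozen$score >= 2 & frozen$score < 3))

  expect_error(simulate_admission(P, duration_days = 0.5), ">= 1 day")
})

test_that("gap injection isolates roughly the requested fraction", {
  P <- make_chain(chain_spec(4L, 0.8))
  adm <- simulate_admission(P, duration_days = 14, gap_rate = 0.05, seed = 42)
  iso <- attr(adm, "isolated_slots")
  expect_equal(length(iso), round(0.05 * 672))
  expect_true(all(diff(iso) >= 5))
  # the isolated observations are exactly what the adjacency filter drops
  pr <- prep_series(adm)
  expect_equal(pr$n_removed_nonadjacent, length(iso))
  # and the surviving pairs still re-bin to the simulated states
  surviving <- attr(adm, "states")[pr$states$t_minutes / 30 + 1]
  expect_equal(pr$states$state, surviving)
})

test_that("simulate_outcomes honours the entropy links", {
  set.seed(42)
  H <- runif(1e4, 0.5, 2.3)

  null_cfg <- cohort_config(n_admissions = 100, mortality_link = 0,
                            outcome_link = 0)
  out0 <- simulate_outcomes(H, null_cfg)
  expect_lt(abs(cor(H, out0$hospital_los_days)), 0.05)
  expect_lt(abs(cor(H, out0$vent_days)), 0.05)
  # intercept alone reproduces the target mortality rate (binomial SE at
  # n = 1e4 is ~0.004, so a +/-0.02 absolute band is conservative)
  expect_lt(abs(mean(out0$died) - 0.165), 0.02)

  big_cfg <- cohort_config(n_admissions = 100, mortality_link = 3,
                           outcome_link = 2)
  out1 <- simulate_outcomes(H, big_cfg)
  comp <- composite_score(out1)
  expect_gt(cor(H, comp$composite), 0.5)

  # ordering constraint holds in both worlds
  for (o in list(out0, out1)) {
    expect_true(all(o$vent_days <= o$icu_los_days + 1e-9))
    expect_true(all(o$icu_los_days <= o$hospital_los_days + 1e-9))
    expect_true(all(o$icu_los_days >= 1))
  }
  expect_error(simulate_outcomes(c(1, NA)), "finite")
})

test_that("generate_cohort is deterministic and internally consistent", {
  cfg <- cohort_config(n_admissions = 12, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  generate_cohort(cfg, dir = d1)
  generate_cohort(cfg, dir = d2)
  for (f in c("scores.csv", "outcomes.csv", "truth.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }

  ids <- sprintf("adm%03d", 1:12)
  expect_setequal(unique(a$scores$admission_id), ids)
  expect_setequal(a$outcomes$admission_id, ids)
  expect_setequal(a$truth$admission_id, ids)

  # stored chain parameters regenerate the stored true entropy
  for (i in c(1, 5, 12)) {
    s <- unlist(a$truth[i, c("stick_0", "stick_1", "stick_2", "stick_3")])
    expect_equal(true_entropy(make_chain(chain_spec(4L, unname(s)))),
                 a$truth$true_entropy[i], tolerance = 1e-12)
  }
})

test_that("cohort-level gap rate lands near the configured 0.3%", {
  coh <- generate_cohort(cohort_config(n_admissions = 40, seed = 3))
  pr <- prep_cohort(coh$scores)
  rate <- sum(pr$report$n_removed_nonadjacent) / sum(pr$report$n_after_resample)
  expect_gt(rate, 0.001)
  expect_lt(rate, 0.006)
})
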