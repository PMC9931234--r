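test_that("ward_cluster handles the forced small cases", {
  x <- c(0.1, 0.12, 1.9, 1.95)
  tree <- ward_cluster(x)
  lab <- cut_k(tree, 2)
  expect_equal(lab[1], lab[2])
  expect_equal(lab[3], lab[4])
  expect_true(lab[1] != lab[3])
  # matches the exhaustive minimum within-SS bipartition
  expect_equal(within_ss(x, lab), oracle_best_bipartition(x)$within_ss,
               tolerance = 1e-12)

  t2 <- ward_cluster(c(1.5, 1.5, 3))
  expect_equal(min(t2$height), 0)

  expect_equal(length(unique(cut_k(tree, 4))), 4L)  # n singletons
  expect_equal(length(unique(cut_k(tree, 1))), 1L)
  expect_error(cut_k(tree, 5), "1..n")
  expect_error(ward_cluster(c(1, NA)), "finite")
  expect_error(ward_cluster(1.5), "at least 2")
  # heights nondecreasing along merges
  set.seed(42)
  h <- ward_cluster(runif(30))$height
  expect_true(all(diff(h) >= -1e-12))
})

test_that("greedy Ward matches the exhaustive bipartition on separated data", {
  set.seed(42)
  n_agree <- 0
  reps <- 300
  for (r in 1:reps) {
    n <- sample(4:8, 1)
    # inputs genuinely containing two components; a forced 2-cut of
    # unimodal data is the documented greedy-suboptimality exception
    repeat { g <- rbinom(n, 1, 0.5); if (length(unique(g)) == 2L) break }
    x <- rnorm(n, ifelse(g == 1, 1.8, 1.1), 0.10)
    lab <- cut_k(ward_cluster(x), 2)
    w <- within_ss(x, lab)
    wb <- oracle_best_bipartition(x)$within_ss
    expect_gte(w, wb - 1e-12)   # greedy can never beat the optimum
    if (abs(w - wb) < 1e-10) n_agree <- n_agree + 1
  }
  expect_gte(n_agree / reps, 0.99)
})

test_that("finer cuts refine coarser ones", {
  set.seed(42)
  for (r in 1:20) {
    x <- runif(sample(10:60, 1), 0, 2.8)
    tree <- ward_cluster(x)
    for (k in c(2, 3)) {
      coarse <- cut_k(tree, k)
      fine <- cut_k(tree, 2 * k)
      # each fine cluster lies wholly inside one coarse cluster
      expect_true(all(tapply(coarse, fine, function(v) length(unique(v))) == 1L))
    }
  }
})

test_that("order_phenotypes sorts clusters by descending mean entropy", {
  H <- c(1.1, 1.15, 1.12, 1.8, 1.85)
  lab <- c(1, 1, 1, 2, 2)
  ph <- order_phenotypes(lab, H)
  expect_equal(ph, c(2L, 2L, 2L, 1L, 1L))

  # tie on means: larger cluster becomes phenotype 1
  Ht <- c(1, 1, 1, 1, 1)
  labt <- c(1, 1, 2, 2, 2)
  expect_equal(order_phenotypes(labt, Ht), c(2L, 2L, 1L, 1L, 1L))

  set.seed(42)
  x <- runif(40, 0, 2.8)
  tree <- ward_cluster(x)
  ph4 <- order_phenotypes(cut_k(tree, 4), x)
  mu <- tapply(x, ph4, mean)
  expect_true(all(diff(mu) < 0))  # strictly descending 1..4
})

test_that("k = 2 clustering recovers a two-component entropy mixture", {
  set.seed(42)
  agree <- replicate(30, {
    n <- 160
    g <- rbinom(n, 1, 0.5)
    x <- rnorm(n, ifelse(g == 1, 1.8, 1.1), 0.15)
    ph <- order_phenotypes(cut_k(ward_cluster(x), 2), x)
    truth <- ifelse(g == 1, 1L, 2L)   # component 1.8 = phenotype 1
    mean(ph == truth)
  })
  expect_gte(mean(agree), 0.95)
})

test_that("assign_phenotypes excludes low-data admissions and labels the rest", {
  coh <- generate_cohort(cohort_config(n_admissions = 20, seed = 8))
  et <- cohort_entropy(prep_cohort(coh$scores))
  et$flag[3] <- "low_data"   # force an exclusion
  ph <- assign_phenotypes(et, ks = c(2, 4))
  expect_equal(ph$excluded, et$admission_id[3])
  expect_equal(nrow(ph$labels), 19L)
  expect_true(all(c("phenotype_k2", "phenotype_k4") %in% names(ph$labels)))
  # refinement across the stored cuts
  expect_true(all(tapply(ph$labels$phenotype_k2, ph$labels$phenotype_k4,
                         function(v) length(unique(v))) == 1L))
})

test_that("compare_groups picks tests as documented", {
  # duplicated data: identical group compositions, chi-squared 0 and p = 1
  d <- data.frame(sex = rep(c("M", "F", "M", "M"), 2),
                  died = rep(c(0, 1, 0, 0), 2),
                  age_years = rep(c(1, 2, 3, 4), 2) + rep(c(0, .001), each = 4),
                  composite = rep(c(10, 20, 30, 40), 2) + rep(c(0, .001), each = 4))
  g <- rep(1:2, each = 4)
  gc <- compare_groups(d, g, categorical = c("sex", "died"),
                       continuous = c("age_years", "composite"))
  chisq_rows <- gc$table[gc$table$test == "chi-squared", ]
  expect_equal(chisq_rows$statistic, c(0, 0), tolerance = 1e-12)
  expect_equal(chisq_rows$p_value, c(1, 1), tolerance = 1e-12)
  expect_equal(gc$alpha_adjusted, 0.025)

  # ANOVA degrees of freedom: 4 groups of 164 admissions -> (3, 160);
  # exactly normal within-group data so the parametric route is taken
  d2 <- data.frame(y = qnorm(ppoints(164)))
  g2 <- rep(1:4, 41)   # round-robin over the ordered quantiles
  gc2 <- compare_groups(d2, g2, categorical = character(0), continuous = "y")
  expect_equal(gc2$table$test, "anova")
  expect_equal(gc2$table$df, "3, 160")
  expect_equal(gc2$alpha_adjusted, 0.05)

  expect_error(compare_groups(d2, rep(1, 164), continuous = "y"), "2 groups")
})

test_that("Kruskal-Wallis route keeps its nominal type-I error", {
  set.seed(42)
  reps <- 1000
  g <- rep(1:2, each = 20)
  res <- replicate(reps, {
    d <- data.frame(x = rexp(40))  # skewed null: identical distributions
    tab <- compare_groups(d, g, categorical = character(0),
                          continuous = "x")$table
    c(kw = tab$test == "kruskal-wallis", p = tab$p_value)
  })
  # skewed data should essentially always fail the normality gate
  expect_gt(mean(res["kw", ]), 0.95)
  p <- res["p", res["kw", ] == 1]
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("Tukey post hoc is attached for ANOVA-significant variables", {
  g <- rep(1:4, 41)
  d <- data.frame(y = qnorm(ppoints(164)) + c(0, 0, 0, 3)[g])
  gc <- compare_groups(d, g, categorical = character(0), continuous = "y")
  expect_equal(gc$table$test, "anova")
  expect_lt(gc$table$p_value, gc$alpha_adjusted)
  expect_true("y" %in% names(gc$tukey))
  expect_s3_class(gc$tukey$y, "TukeyHSD")
})
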