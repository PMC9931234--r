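#' Agglomerative Ward clustering of per-admission entropies
#'
#' Euclidean distances between scalar entropy values, merged under Ward's
#' minimum-variance criterion. The default `"ward.D2"` dialect applies the
#' Ward criterion to squared Euclidean increments (the textbook Ward
#' method); the legacy `"ward.D"` dialect, which some software historically
#' labelled "Ward", is exposed because published analyses rarely state
#' which was used.
#'
#' @param entropies numeric vector, optionally named by admission id.
#' @param method `"ward.D2"` (default) or `"ward.D"`.
#' @return an [stats::hclust] tree.
#' @export
ward_cluster <- function(entropies, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  if (length(entropies) < 2L) stop("need at least 2 admissions to cluster")
  if (any(!is.finite(entropies))) stop("entropies must be finite")
  x <- as.numeric(entropies)
  names(x) <- names(entropies)
  # "ward.D2" on Euclidean distances is the textbook Ward criterion;
  # "ward.D" on unsquared distances is the legacy dialect some software
  # shipped under the plain name "Ward".
  hclust(dist(x), method = method)
}

#' Cut a dendrogram into exactly k clusters
#'
#' @param tree an `hclust` tree.
#' @param k number of clusters, `1 <= k <= n`.
#' @return integer cluster labels (arbitrary order; see
#'   [order_phenotypes()]).
#' @export
cut_k <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1L || k > n) stop("k must lie in 1..n")
  lab <- cutree(tree, k = k)
  if (length(unique(lab)) != k)
    stop(sprintf("tied merge heights prevent a cut into exactly %d clusters (got %d)",
                 k, length(unique(lab))))
  lab
}

#' Relabel clusters by descending mean entropy
#'
#' Phenotype 1 is the cluster with the highest mean entropy. Equal means
#' are broken by putting the larger cluster first.
#'
#' @param labels integer cluster labels.
#' @param entropies entropy values aligned with `labels`.
#' @return integer phenotype labels, 1 = highest mean entropy.
#' @export
order_phenotypes <- function(labels, entropies) {
  if (length(labels) != length(entropies)) stop("labels/entropies length mismatch")
  mu <- tapply(entropies, labels, mean)
  size <- tapply(entropies, labels, length)
  ord <- order(-mu, -size)
  map <- setNames(seq_along(ord), names(mu)[ord])
  as.integer(map[as.character(labels)])
}

#' Phenotype assignment at several cuts
#'
#' Clusters admissions on entropy, cuts the tree at each requested k, and
#' orders every solution by descending mean entropy. Because all cuts come
#' from one tree, finer solutions refine coarser ones.
#'
#' @param entropy_table output of [cohort_entropy()]; rows flagged
#'   `low_data` are excluded.
#' @param ks cluster counts (default `c(2, 4)`).
#' @param method Ward dialect, see [ward_cluster()].
#' @return list with `tree`, `labels` (data frame `admission_id` +
#'   `phenotype_k<k>` columns), and `excluded` ids.
#' @export
assign_phenotypes <- function(entropy_table, ks = c(2L, 4L),
                              method = "ward.D2") {
  keep <- entropy_table$flag == "ok" & is.finite(entropy_table$entropy_nats)
  excluded <- entropy_table$admission_id[!keep]
  et <- entropy_table[keep, , drop = FALSE]
  H <- setNames(et$entropy_nats, et$admission_id)
  tree <- ward_cluster(H, method = method)
  labels <- data.frame(admission_id = et$admission_id)
  for (k in ks) {
    lab <- order_phenotypes(cut_k(tree, k), H)
    labels[[paste0("phenotype_k", k)]] <- lab
  }
  list(tree = tree, labels = labels, excluded = excluded)
}

# Brown-Forsythe variant of Levene's test: ANOVA on absolute deviations
# from group medians. Robust to nonnormality, which is the case it guards.
.levene_test <- function(x, g) {
  g <- factor(g)
  med <- tapply(x, g, median)
  z <- abs(x - med[g])
  fit <- stats::anova(lm(z ~ g))
  list(statistic = fit[1, "F value"], p_value = fit[1, "Pr(>F)"])
}

.normality_ok <- function(x, g, alpha = 0.05) {
  ps <- vapply(split(x, g), function(v) {
    if (length(v) < 3L || length(unique(v)) == 1L) return(0)  # cannot attest normality
    shapiro.test(v)$p.value
  }, 0)
  lev <- .levene_test(x, g)
  list(ok = all(ps > alpha) && lev$p_value > alpha,
       shapiro_min_p = min(ps), levene_p = lev$p_value)
}

#' Compare cohort characteristics across phenotypes
#'
#' Categorical variables get chi-squared tests; continuous variables get a
#' one-way ANOVA when per-group Shapiro-Wilk and a Brown-Forsythe variance
#' check both pass at alpha = 0.05, otherwise a Kruskal-Wallis test.
#' ANOVA-significant variables additionally receive a Tukey HSD post hoc.
#' The Bonferroni-adjusted significance level is 0.05 divided by the
#' number of continuous comparisons.
#'
#' @param data cohort table, one row per admission.
#' @param labels phenotype labels aligned with `data` rows.
#' @param categorical,continuous character vectors of column names.
#' @param alpha base significance level (default 0.05).
#' @return object of class `group_comparison`: `$table` (variable, test,
#'   statistic, df, p_value, assumption notes), `$summaries` (per-group %
#'   or mean+/-SD), `$tukey`, `$alpha_adjusted`.
#' @export
compare_groups <- function(data, labels,
                           categorical = c("sex", "died"),
                           continuous = c("age_years", "vent_days",
                                          "hospital_los_days", "composite"),
                           alpha = 0.05) {
  g <- factor(labels)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) == 0L)) stop("every group must be nonempty")
  categorical <- intersect(categorical, names(data))
  continuous <- intersect(continuous, names(data))
  alpha_adj <- alpha / max(length(continuous), 1L)

  rows <- list()
  summaries <- list()
  tukey <- list()

  for (v in categorical) {
    x <- factor(data[[v]])
    tab <- table(g, x)
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_counts == 0)) {
      warning(sprintf("zero expected counts for '%s': chi-squared skipped", v))
      rows[[v]] <- data.frame(variable = v, test = "chi-squared (skipped)",
                              statistic = NA, df = NA, p_value = NA,
                              assumptions = "zero expected cell")
    } else {
      ct <- suppressWarnings(chisq.test(tab))
      rows[[v]] <- data.frame(variable = v, test = "chi-squared",
                              statistic = unname(ct$statistic),
                              df = unname(ct$parameter),
                              p_value = ct$p.value, assumptions = "")
    }
    pos_level <- tail(levels(x), 1L)
    summaries[[v]] <- tapply(x == pos_level, g, function(z)
      sprintf("%.1f%%", 100 * mean(z)))
  }

  for (v in continuous) {
    x <- data[[v]]
    chk <- .normality_ok(x, g, alpha = alpha)
    note <- sprintf("shapiro min p=%.3g, levene p=%.3g",
                    chk$shapiro_min_p, chk$levene_p)
    if (chk$ok) {
      fit <- aov(x ~ g)
      an <- stats::anova(fit)
      p <- an[1, "Pr(>F)"]
      rows[[v]] <- data.frame(variable = v, test = "anova",
                              statistic = an[1, "F value"],
                              df = sprintf("%d, %d", an[1, "Df"], an[2, "Df"]),
                              p_value = p, assumptions = note)
      if (is.finite(p) && p < alpha_adj) tukey[[v]] <- TukeyHSD(fit)
    } else {
      kw <- kruskal.test(x, g)
      rows[[v]] <- data.frame(variable = v, test = "kruskal-wallis",
                              statistic = unname(kw$statistic),
                              df = as.character(unname(kw$parameter)),
                              p_value = kw$p.value, assumptions = note)
    }
    summaries[[v]] <- tapply(x, g, function(z)
      sprintf("%.1f±%.1f", mean(z), sd(z)))
  }

  tab <- do.call(rbind, lapply(rows, function(r) {
    r$df <- as.character(r$df)
    r
  }))
  rownames(tab) <- NULL
  structure(list(table = tab,
                 summaries = do.call(rbind, lapply(summaries, as.vector)),
                 tukey = tukey,
                 alpha_adjusted = alpha_adj,
                 group_sizes = table(g)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (n per group:",
      paste(x$group_sizes, collapse = ", "), ")\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("Bonferroni-adjusted alpha: %.4f\n", x$alpha_adjusted))
  invisible(x)
}
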