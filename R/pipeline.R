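#' Pipeline configuration
#'
#' Builds the configuration consumed by [run_pipeline()], either from
#' arguments or from a YAML file with the same field names. Cohort-level
#' generator settings are forwarded to [cohort_config()].
#'
#' @param file optional YAML file; its entries override the defaults and
#'   are themselves overridden by `...`.
#' @param seed master seed recorded in every artifact.
#' @param outdir output directory.
#' @param binning `"fixed"`, `"equiprobable"`, or `"both"` (fixed primary
#'   plus an equiprobable sensitivity column).
#' @param ks cluster counts for phenotyping.
#' @param min_pairs minimum valid transition pairs per admission.
#' @param n_admissions cohort size for the simulate stage.
#' @param gap_rate isolated-observation rate for the simulate stage.
#' @param ... further [cohort_config()] fields.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(file = NULL, seed = 1L, outdir = "illdyn_out",
                            binning = c("both", "fixed", "equiprobable"),
                            ks = c(2L, 4L), min_pairs = 2L,
                            n_admissions = 164L, gap_rate = 0.003, ...) {
  cfg <- list(seed = as.integer(seed), outdir = outdir,
              binning = match.arg(binning), ks = as.integer(ks),
              min_pairs = as.integer(min_pairs),
              n_admissions = as.integer(n_admissions),
              gap_rate = gap_rate, cohort = list(...))
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    known <- intersect(names(y), c("seed", "outdir", "binning", "ks",
                                   "min_pairs", "n_admissions", "gap_rate"))
    for (nm in known) cfg[[nm]] <- y[[nm]]
    cfg$seed <- as.integer(cfg$seed)
    cfg$ks <- as.integer(cfg$ks)
    cfg$n_admissions <- as.integer(cfg$n_admissions)
    if (!is.null(y$cohort)) cfg$cohort <- modifyList(cfg$cohort, y$cohort)
  }
  if (!cfg$binning %in% c("both", "fixed", "equiprobable"))
    stop("binning must be 'fixed', 'equiprobable' or 'both'")
  class(cfg) <- "pipeline_config"
  cfg
}

.cfg_hash <- function(cfg) {
  # hash only analysis-relevant fields so the same analysis run into two
  # directories produces byte-identical artifacts
  cfg <- unclass(cfg)
  cfg$outdir <- NULL
  s <- paste(deparse(cfg), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Descriptive summary of a cohort outcomes table
#'
#' One row per variable in the conventional layout: n (%) for
#' categorical variables, mean+/-SD, median (IQR) and range for continuous
#' ones. Missing optional columns are reported as unavailable rather than
#' failing.
#'
#' @param outcomes cohort outcomes table.
#' @return data frame with columns `characteristic`, `n_pct`,
#'   `mean_sd`, `median_iqr`, `range`.
#' @export
cohort_summary <- function(outcomes) {
  n <- nrow(outcomes)
  cat_row <- function(name, x, level) {
    if (is.null(x) || all(is.na(x)))
      return(data.frame(characteristic = name, n_pct = "unavailable",
                        mean_sd = "", median_iqr = "", range = ""))
    hit <- sum(x == level, na.rm = TRUE)
    data.frame(characteristic = name,
               n_pct = sprintf("%d (%.1f)", hit, 100 * hit / n),
               mean_sd = "", median_iqr = "", range = "")
  }
  num_row <- function(name, x) {
    if (is.null(x) || all(is.na(x)))
      return(data.frame(characteristic = name, n_pct = "",
                        mean_sd = "unavailable", median_iqr = "", range = ""))
    q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
    data.frame(characteristic = name, n_pct = "",
               mean_sd = sprintf("%.1f±%.1f", mean(x, na.rm = TRUE),
                                 sd(x, na.rm = TRUE)),
               median_iqr = sprintf("%.1f (%.1f–%.1f)", q[2], q[1], q[3]),
               range = sprintf("%.1f–%.1f", min(x, na.rm = TRUE),
                               max(x, na.rm = TRUE)))
  }
  out <- rbind(
    cat_row("Male sex", outcomes$sex, "M"),
    cat_row("In-hospital mortality", outcomes$died, 1),
    num_row("Age (years)", outcomes$age_years),
    num_row("Ventilator days", outcomes$vent_days),
    num_row("Hospital stay (days)", outcomes$hospital_los_days),
    num_row("ICU stay (days)", outcomes$icu_los_days))
  if (!is.null(outcomes$composite))
    out <- rbind(out, num_row("Negative outcomes (composite)",
                              outcomes$composite))
  attr(out, "n_admissions") <- n
  out
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

.dump_matrix_json <- function(m, path, extra = list()) {
  payload <- c(list(k = nrow(m), row_major = as.vector(t(unclass(m)))), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
}

#' Run the full analysis pipeline
#'
#' simulate -> prep -> entropy -> composite -> cluster -> associate ->
#' report. Every artifact is a CSV (with a `#` provenance header) or JSON
#' file under `config$outdir`; rerunning with the same config reproduces
#' them byte for byte. With `binning = "both"` an equiprobable-bin entropy
#' column is computed alongside the fixed one and their correlation is
#' reported (the sensitivity analysis).
#'
#' @param config a [pipeline_config()] (or YAML path).
#' @param scores,outcomes optional pre-existing cohort tables; when `NULL`
#'   the simulate stage generates them.
#' @return (invisibly) list with the key tables and fitted models.
#' @export
run_pipeline <- function(config = pipeline_config(), scores = NULL,
                         outcomes = NULL) {
  if (is.character(config)) config <- pipeline_config(file = config)
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  seed <- config$seed
  hash <- .cfg_hash(config)
  wcsv <- function(df, name, stage) {
    write_cohort_csv(df, file.path(outdir, name), seed = seed,
                     stage = sprintf("%s cfg=%s", stage, hash))
  }

  if (is.null(scores) || is.null(outcomes)) {
    sim <- .stage("simulate", {
      cc <- do.call(cohort_config,
                    modifyList(list(n_admissions = config$n_admissions,
                                    gap_rate = config$gap_rate, seed = seed),
                               config$cohort))
      generate_cohort(cc)
    })
    scores <- sim$scores
    outcomes <- sim$outcomes
    wcsv(sim$scores, "scores.csv", "simulate")
    wcsv(sim$outcomes, "outcomes.csv", "simulate")
    wcsv(sim$truth, "truth.csv", "simulate")
  }

  binnings <- switch(config$binning,
                     fixed = "fixed", equiprobable = "equiprobable",
                     both = c("fixed", "equiprobable"))
  prepped <- .stage("prep", lapply(setNames(binnings, binnings), function(b)
    prep_cohort(scores, binning = b)))
  primary <- prepped[[1L]]
  wcsv(primary$report, "prep_report.csv", "prep")
  wcsv(primary$states, "states.csv", "prep")

  ent <- .stage("entropy", lapply(prepped, cohort_entropy,
                                  min_pairs = config$min_pairs))
  entropy_tab <- ent[[1L]]
  if (length(ent) == 2L) {
    entropy_tab$entropy_equiprobable <- ent[[2L]]$entropy_nats[
      match(entropy_tab$admission_id, ent[[2L]]$admission_id)]
  }
  wcsv(entropy_tab, "entropy.csv", "entropy")

  comp <- .stage("composite", composite_score(outcomes))
  wcsv(comp, "composite.csv", "composite")

  phen <- .stage("cluster", assign_phenotypes(entropy_tab, ks = config$ks))
  wcsv(phen$labels, "phenotypes.csv", "cluster")
  jsonlite::write_json(
    list(merge = phen$tree$merge, height = phen$tree$height,
         labels = phen$tree$labels, seed = seed),
    file.path(outdir, "dendrogram.json"), auto_unbox = TRUE, digits = NA)

  merged <- Reduce(function(a, b) merge(a, b, by = "admission_id"),
                   list(entropy_tab, comp[, c("admission_id", "composite")],
                        outcomes, phen$labels))
  comparisons <- .stage("cluster", {
    out <- list()
    for (k in config$ks) {
      col <- paste0("phenotype_k", k)
      gc <- compare_groups(merged, merged[[col]])
      out[[as.character(k)]] <- gc
      wcsv(gc$table, sprintf("comparison_k%d.csv", k), "cluster")
    }
    out
  })

  assoc <- .stage("associate", {
    uni <- fit_univariate(merged$composite, merged$entropy_nats)
    adj <- fit_adjusted(merged$composite, merged$entropy_nats,
                        merged$mean_score)
    curve <- loess_curve(merged$entropy_nats, merged$composite)
    wcsv(as.data.frame(curve), "loess_entropy.csv", "associate")
    jsonlite::write_json(
      list(univariate = list(beta = uni$beta_entropy, ci = c(uni$ci_low, uni$ci_high),
                             p_value = uni$p_value, r_squared = uni$r_squared),
           adjusted = list(beta = adj$beta_entropy, ci = c(adj$ci_low, adj$ci_high),
                           p_value = adj$p_value, r_squared = adj$r_squared,
                           knots = adj$knots),
           seed = seed),
      file.path(outdir, "association.json"), auto_unbox = TRUE, digits = NA)
    list(univariate = uni, adjusted = adj, curve = curve)
  })

  report <- .stage("report", {
    tab1 <- cohort_summary(merge(outcomes, comp[, c("admission_id", "composite")],
                                 by = "admission_id"))
    wcsv(tab1, "table1.csv", "report")
    rep <- list(seed = seed, config_hash = hash,
                n_admissions = length(unique(scores$admission_id)),
                n_raw_observations = nrow(scores),
                n_removed_nonadjacent = sum(primary$report$n_removed_nonadjacent),
                n_excluded_low_data = length(phen$excluded))
    if (length(ent) == 2L) {
      both_ok <- is.finite(entropy_tab$entropy_nats) &
        is.finite(entropy_tab$entropy_equiprobable)
      rep$sensitivity_entropy_correlation <-
        stats::cor(entropy_tab$entropy_nats[both_ok],
                   entropy_tab$entropy_equiprobable[both_ok])
    }
    jsonlite::write_json(rep, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    rep
  })
  message(sprintf("pipeline complete: %d admissions, %d observations removed as nonadjacent, %d excluded for low data",
                  report$n_admissions, report$n_removed_nonadjacent,
                  report$n_excluded_low_data))

  invisible(list(scores = scores, outcomes = outcomes,
                 entropy = entropy_tab, composite = comp,
                 phenotypes = phen, comparisons = comparisons,
                 association = assoc, report = report))
}
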