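---
title: "Quantifying individual illness dynamics with transition entropy"
author: "illdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying individual illness dynamics with transition entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(illdyn)
```

## The model

An ICU admission is observed through a continuous illness-severity score —
a model-derived fold-increase in short-term sepsis risk, bounded in
[0, 8] — sampled every 15 minutes. `illdyn` treats the admission's course
as a stochastic process on k = 4 discrete illness states obtained by
binning the score ([0,1), [1,2), [2,3), [3,∞)), observed on a 30-minute
grid. The working assumptions are:

* **First-order, time-homogeneous movement.** Transition behaviour is
  summarized by a single k×k matrix per admission; within-admission drift
  (e.g. slow recovery) is not modelled.
* **Valid transitions need adjacency.** A transition is counted only
  between observations exactly 30 minutes apart; observations with no
  30-minute neighbour carry no dynamic information and are removed.
* **The summary of interest is the joint transition density**, counts
  divided by the total number of observed transitions, whose Shannon
  entropy H = −Σ q ln q (natural log, 0 ln 0 := 0, 0 ≤ H ≤ ln 16) measures
  the irregularity of deterioration/recovery. Note this is deliberately
  *not* the chain's entropy rate −Σᵢ πᵢ Σⱼ Pᵢⱼ ln Pᵢⱼ: the joint density
  folds in how the admission distributes its time over initial states, so
  an admission parked in one state scores near 0 even if its rare moves
  are erratic.

Downstream, entropies are clustered (Ward, Euclidean distance) into
dynamic phenotypes at k = 2 and k = 4, labelled in descending mean
entropy, and regressed against a negative-outcome composite: the sum of
min-tie ranks (rank = 1 + number strictly smaller) of mortality,
ventilator days and hospital stay, so larger is worse and the floor is 3.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| bin edges | 1, 2, 3 | score (fold-risk) | clinically meaningful severity cut points; equiprobable pooled quartiles available as sensitivity |
| adjacency tolerance | 0 | min | synthetic grids are exact; ±1 accommodates real monitor jitter |
| `min_pairs` | 2 | transitions | admissions with <2 valid pairs carry no usable dynamics and are flagged out of clustering; clinical analyses of this design use whole admissions and state no floor, so this guard is ours |
| Ward dialect | `ward.D2` | — | the criterion that actually minimizes within-cluster variance with Euclidean input; the legacy `ward.D` (unsquared) dialect is exposed because older software shipped it under the plain name "Ward" |
| normality gate | Shapiro–Wilk per group + Brown–Forsythe Levene, α = 0.05 | — | the decision rule "ANOVA when assumptions met, else Kruskal–Wallis" needs concrete tests; these are the standard pair when `car` is unavailable |
| Bonferroni α | 0.05 / m continuous variables | — | 0.017 for 3 comparisons, 0.0125 for 4 |
| loess | span 0.75, degree 1, tricube | — | "moving least squares lines"; no span is canonical, 0.75 is the field default |
| RCS knots | 0.10/0.50/0.90 quantiles of mean score | score | the common 3-knot convention; data-derived knots (e.g. 0.85/1.65/2.95 in the clinical setting this package targets) are reported with results, not chosen by hand |
| CIs | Wald (t), homoskedastic | — | the conventional symmetric-width reporting style for this design |

## What the generator emulates — and what it does not

`generate_cohort()` draws, per admission, a 4-state chain with one
high-stickiness "home" state (diagonal ~ U(0.85, 0.9995)) and moderately
sticky other states (~ U(0.65, 0.98)). These ranges were fixed once,
before any test was written, to reproduce the entropy distribution
reported for the clinical setting being emulated (mean ≈ 1.5, SD ≈ 0.4,
spectrum roughly 0.5–2.0 nats); they have not been revisited. Each 30-minute state
emits two 15-minute scores uniform in its bin (top bin truncated at 8), so
the prep stage's resampling, adjacency filtering and binning are genuinely
exercised and, at `gap_rate = 0`, invert exactly (the round-trip
property). Gaps are isolated single observations: the two on-grid
neighbours of a target slot are deleted, reproducing the "nonconsecutive
observation" phenomenon at a configurable rate (default 0.3%). Outcomes
are linked to *true* (stationary-law) entropy: logistic mortality centred
to 16.5% at entropy 1.5, log-normal ICU/hospital stays with log-linear
entropy effects, ventilator days a random fraction of the ICU stay (so
vent ≤ ICU ≤ hospital always). ICU stay in the outcomes table drives the
simulated series length, keeping the two tables consistent.

Deliberately **not** emulated: within-admission nonstationarity (recovery
drift, treatment effects), circadian structure, measurement error in the
score itself, readmission correlation (each admission is independent), and
any real relationship between age/sex and outcomes. A green test on this
world therefore establishes that the pipeline recovers known transition
structure and known entropy–outcome links — not that the clinical
associations seen in real cohorts replicate.

## Numerical choices

* Entropy uses natural logs with 0 ln 0 := 0; IEEE negative zero is
  normalized away. Densities must sum to 1 within 1e-8.
* Unvisited initial states give **masked all-zero rows** in the transition
  matrix, never imputed uniform rows: the probability is an observed row
  frequency, and an unvisited row has no observations.
* Stationary laws are solved from the augmented balance equations by QR;
  reducible chains are rejected (no unique stationary law). `true_entropy`
  accepts an explicit π for degenerate references such as an absorbing
  chain started in its absorbing state.
* Equiprobable edges use the linear-interpolation quantile (R type 7) at
  positions (n−1)p; ties that collapse adjacent edges are an error, not a
  silent merge.
* 30-minute resampling anchors at each admission's first observation, not
  clock time, since time is indexed from admission start.
* Ranks use `ties.method = "min"`, verified against the strict-less-than
  definition by brute force.
* The RCS nonlinear column is ((x−k₁)₊³ − (x−k₂)₊³(k₃−k₁)/(k₃−k₂) +
  (x−k₃)₊³(k₂−k₁)/(k₃−k₂)) / (k₃−k₁)², zero at and below k₁ and exactly
  linear beyond k₃. A constant adjuster degrades the adjusted model to the
  univariate fit; any other rank deficiency is an error naming the aliased
  columns.
* Phenotype label ties (equal mean entropy) are broken by cluster size,
  larger first.

## Design choices where the design was open

* **Which chain anchors the entropy-consistency check.** The plug-in
  entropy of an empirical transition density converges at a rate governed
  by the chain's mixing time: at 20,000 steps the |Ĥ − H| < 0.02 bound
  holds for ~99% of runs of the default chain (uniform stickiness 0.9) but
  for under half the runs of a chain with a 0.95-sticky home state, whose
  autocorrelated path carries far fewer effective observations. The
  consistency criterion is therefore pinned to the documented default
  chain; users studying very sticky regimes should expect slower
  convergence of per-admission entropy.
* **What "random inputs" means for the Ward oracle.** Greedy agglomeration
  is not guaranteed optimal: against an exhaustive minimum-within-SS
  bipartition (n ≤ 8) it agrees on ~89% of uniform random inputs, but on
  ≥99% of inputs that genuinely contain two separated components — the
  regime in which a 2-cluster cut is a meaningful question. The oracle
  suite uses two-component inputs and separately asserts the
  distribution-free guarantee that the greedy cut's within-SS never beats
  the exhaustive optimum. Forcing k = 2 on unimodal data is the documented
  exception class.
* **Coverage needs a true coefficient.** The rank-sum composite has no
  linear true effect, so the CI-calibration check uses a linear-Gaussian
  response with a known slope (β = 100) over generator-scale entropies;
  it validates the Wald machinery, not the composite's linearity.
* **Equiprobable edges are computed post-filter** (on analysis-ready
  observations), the natural reading of basing bins on observed transition
  states; computing them pre-filter would shift edges by at most the gap
  rate's worth of observations.

## Known limitations

* Entropy ignores transition *direction* and distance: a patient
  oscillating 0↔1 and one oscillating 0↔3 can score identically.
* Per-admission entropy is length-biased at short stays (few pairs →
  downward-biased plug-in entropy); the `min_pairs` guard removes only the
  degenerate extreme.
* Clustering a scalar is one-dimensional segmentation; the dendrogram's
  visual structure should not be over-read.
* The composite treats its three components as exchangeable ranks; death
  contributes at most the same spread as a long stay.
* The group-comparison table runs one test per variable with a Bonferroni
  α for the continuous block, mirroring common practice in this literature rather
  than a modern multiplicity framework.
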