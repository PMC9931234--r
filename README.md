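# illdyn — illness-state transition entropy and dynamic phenotypes

`illdyn` characterizes *how* an intensive-care admission unfolds, not just
how sick the patient is on average. Its input is the kind of time series a
continuous risk-prediction model produces at the bedside: a dimensionless
illness-severity score in [0, 8] every 15 minutes for the length of an ICU
stay, plus an outcomes table (mortality, ventilator days, lengths of stay).
It is written for clinical-data scientists studying illness trajectories in
critically ill cohorts, where the raw clinical series usually cannot be
shared and methods must be validated on synthetic ground truth.

## The statistic

Scores are thinned to a 30-minute grid, observations without a neighbour
exactly 30 minutes away are discarded, and the remainder are binned into
k = 4 discrete illness states (fixed bins [0,1), [1,2), [2,3), [3,∞);
pooled-quartile "equiprobable" bins as a sensitivity analysis). For each
admission the adjacent pairs give a transition count matrix *C*, a
row-stochastic Markov transition matrix, and the joint transition density
*Q* = *C*/N (all 16 cells sum to one). The admission's summary is the
Shannon entropy of that density,

    H = − Σ_ij q_ij ln q_ij ,   0 ≤ H ≤ ln k² = ln 16 ≈ 2.77,

low when the patient sits in one state (stable, for better or worse), high
when transitions wander over many state pairs. Downstream, admissions are
clustered on H with Ward's method into dynamic phenotypes (k = 2 and 4,
labelled in descending mean entropy), and H is regressed on a min-tie
rank-sum composite of negative outcomes (mortality + ventilator days +
hospital stay), with and without a 3-knot restricted-cubic-spline
adjustment for the mean illness score.

Because real cohorts of this kind are not publicly deposited, the package
ships a seeded generator: per-admission 4-state chains with a
high-stickiness "home" state (true entropy computable exactly from the
stationary law), 15-minute score emission that inverts the binning, gap
injection producing isolated observations, and outcome tables whose
severity is monotonically linked to true entropy.

## Worked example

```r
library(illdyn)
cfg <- pipeline_config(seed = 1, outdir = "demo_out",
                       n_admissions = 164, binning = "both")
res <- run_pipeline(cfg)
#> pipeline complete: 164 admissions, 608 observations removed as
#> nonadjacent, 0 excluded for low data

e <- res$entropy$entropy_nats
sprintf("entropy: mean %.2f, sd %.2f", mean(e), sd(e))
#> "entropy: mean 1.48, sd 0.42"

res$association$univariate
#> entropy coefficient: beta = 73.1 (95% CI 37.7 to 108.5), p = 7.02e-05, R2 = 0.09
res$association$adjusted
#> entropy coefficient: beta = 76.6 (95% CI 33.4 to 119.8), p = 0.000599, R2 = 0.09
#> adjusted for mean illness score, RCS knots at 1.69, 2.41, 3.8

round(res$report$sensitivity_entropy_correlation, 3)
#> 0.983
```

Reading the numbers: the synthetic cohort's entropies span the realistic
0–2.2 nats range (the theoretical ceiling is 2.77); each extra nat of
transition entropy adds ~73 points of composite rank burden (scale 3 to
~490 for n = 164), and the association survives adjustment for mean
illness severity — the generator's stated world, recovered by the
pipeline. The 0.98 correlation between fixed-bin and equiprobable-bin
entropy is the built-in robustness check on the binning choice. Artifacts
(`entropy.csv`, `phenotypes.csv`, `comparison_k2.csv`, `association.json`,
`table1.csv`, ...) land in `outdir`, each with a `#` provenance header;
rerunning the same config reproduces them byte for byte.

A stage-by-stage command-line driver is in `inst/cli/illdyn.R`:

```sh
Rscript inst/cli/illdyn.R all --seed 1 --outdir demo_out --binning both
Rscript inst/cli/illdyn.R cluster --outdir demo_out --k 2,4
```

## Scope

The upstream risk model itself (a random-forest sepsis predictor), sepsis
adjudication, and waveform feature extraction are out of scope: `illdyn`
consumes scores, not monitors. See `vignettes/illness-dynamics.Rmd` for
the model, assumptions, tuning parameters, and known limitations.
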