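# fluorosel

Fluorescence-based indirect selection in maize trials: simulated OJIP
transients, the JIP-test, NIPALS PLS prediction, and balanced-ANOVA
quantitative genetics.

`fluorosel` emulates, end to end, an in-season selection study in which
chlorophyll-*a* fluorescence induction curves (OJIP transients) measured
on young plants are used to predict end-of-season grain yield (GY) and
grain moisture (GM) of maize hybrids, and asks the breeder's question:
how efficient is selection on the fluorescence-predicted trait compared
with direct selection on the trait itself?

The package provides five building blocks:

* **synthetic trial generator** — a seeded, fully reproducible 16-hybrid
  x 3-year x 4-replicate balanced trial with 3 measured plants per plot;
  each plant gets a 118-point OJIP transient from a three-exponential
  kinetic model whose genetics enter through a photochemistry latent (on
  log Fm/F0, hence Fv/Fm) and a curve-shape latent (on the kinetic phase
  weights, hence VJ, M0 and PI_ABS), with configurable genetic
  correlations to GY and GM;
* **JIP-test engine** — landmark extraction (F0 at the 50 us marker, the
  J and I steps, the peak and the complementary area) and the 56-entry
  biophysical parameter roster (plus raw F0/Fm in the default 58-entry
  preset), including

  PI_ABS = (RC/ABS) · φPo/(1−φPo) · ψEo/(1−ψEo),  RC/ABS = φPo·VJ/M0;

* **PLS1 (NIPALS)** — from-scratch partial least squares with seeded
  10-fold cross-validation, pooled-RMSEP component selection and
  out-of-fold predictions;
* **quantitative genetics** — balanced ANOVA (Genotype, Year,
  Replication(Year), Block(Year), Genotype:Year, Error), expected-mean-
  square variance components, progeny-mean heritability
  H² = σ²G/(σ²G + σ²GxE/nE + σ²e/(nE·nR)) with jackknife SEs, genetic
  correlations, Fisher's LSD, and the efficiency of indirect selection
  EI = 100·|rG|·hX/hY;
* **pipeline** — one call chaining simulate/ingest → JIP tables →
  cross-validated prediction per trait x predictor set → variance
  components of observed and predicted traits → EI, with CSV/JSON
  artifacts that are byte-identical on rerun.

Central data objects are Bioconductor-style S4 classes; the transient
container `FluorTransientSet` extends `SummarizedExperiment` (assay =
timepoints x plants, `rowData` = time grid, `colData` = genotype / year
/ rep / plant keys).

## Worked example

```r
library(fluorosel)

cfg <- defaultTrialConfig()                     # the emulated study conditions
trial <- simulateTrial(cfg$design, cfg$effects, seed = 5)
trial$transients
#> FluorTransientSet with 576 transients x 118 timepoints
#>   time grid: 20 us .. 1 s
#>   genotypes: 16  years: 3  reps: 4

jp  <- jipTable(trial$transients, "plot")       # plot-mean JIP parameters
tbl <- trialTable(trial$agro, jp)               # balanced analysis table
head(tbl[c("genotype", "year", "rep", "block", "gy", "gm", "fvfm", "piabs")])
#>  genotype year rep block     gy     gm  fvfm piabs
#>       H01 2017   1     1  9.227 27.311 0.799 1.288
#>       H02 2017   1     1  8.121 23.478 0.806 0.875
#>       H03 2017   1     1 11.942 23.177 0.800 1.251
#>       H04 2017   1     1 12.661 23.429 0.802 1.199
#>       H05 2017   1     2 16.415 21.566 0.806 0.858
#>       H06 2017   1     2 10.736 21.945 0.802 1.513

vc <- estimateVarianceComponents(tbl, "gm")
vc
#> VarianceComponents [gm]: s2G=1.566 s2E=30.32 s2GxE=2.161 s2e=0.9553 (nE=3, nR=4)
#>   progeny-mean H2 = 0.662 +/- 0.106

geneticCovariance(tbl, "piabs", "gm")
#> Genetic covariance piabs ~ gm: CovG = 0.04916, rG = 0.234 +/- 0.330

report <- runPipeline(list(seed_sim = 5, seed_cv = 2))
print(report)
#> Fluorescence-based selection report
#>   192 plots, traits: gy, gm
#>   gy_parameters      LVs= 3  RMSEP=2.352  R2cv=0.0%  H2=0.50  rG=-0.17  EI=14.0%
#>   gy_transients      LVs= 1  RMSEP=2.353  R2cv=2.4%  H2=0.79  rG=0.11  EI=11.5%
#>   gm_parameters      LVs= 6  RMSEP=4.814  R2cv=7.1%  H2=0.06  rG=2.37  EI=70.4%
#>   gm_transients      LVs= 4  RMSEP=4.934  R2cv=2.3%  H2=0.23  rG=0.17  EI=10.4%
```

(Single-seed heritability and rG estimates from 16 genotypes are noisy
by nature; rG estimates may legitimately exceed 1 and are reported
unclipped with a warning. The generator's realized components match
their targets in expectation — the test suite verifies this over 20
seeds.)

The published variance-component reference table ships with the package
and doubles as a worked heritability example:

```r
ref <- referenceVarianceComponents()
gm <- ref[ref$trait == "gm", ]
heritability(varianceComponents(gm$sigma2_G, gm$sigma2_GxE, gm$sigma2_e,
                                nE = 3, nR = 4))
#> [1] 0.6175595   # rounds to 0.62
```

A thin command-line front end is installed under
`inst/scripts/fluorosel.R` (`simulate`, `jip`, `run` subcommands).

## Notes

A methods vignette (`vignettes/fluorosel-methods.Rmd`) documents the
generator's model and assumptions, the one-time calibration of the
fluorescence latent scales, the 58-versus-56 parameter roster, the
F0-at-50-us convention, and the known internal inconsistencies of the
published reference values (the EI figures are not recoverable from the
printed rG and H² inputs; the Fv/Fm variance-component row contradicts
its printed heritability; the GY row rounds to 0.63, not the printed
0.64) together with how the package handles them.
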