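# metalsource

Quantitative source apportionment of heavy metals in soils, with
ecological-risk screening, implemented as an R package.

Surveys of contaminated farmland typically measure a handful of elements
(here Cu, Zn, Pb, Cd, Cr, Ni) across on the order of a hundred sampling
points, and then need to answer two questions: *how dangerous is the
contamination* and *where does it come from*. `metalsource` covers both:

* **Descriptive screening** — per-element summary statistics,
  coefficient-of-variation classes (weak ≤ 15 % < moderate < 36 % ≤ high),
  screening-value exceedance rates, background ratios, and Pearson
  correlation tables with two-tailed p-values.
* **Hakanson potential ecological risk indices** — the single-element risk
  factor `Eri = Tr · C / S` (toxic-response coefficient × enrichment over
  background) and the comprehensive index `RI = Σ Eri`, with the standard
  class bands for both.
* **Three receptor models** that apportion concentrations among unmeasured
  sources using only the receptor data:
  * **APCS-MLR** — absolute principal component scores (factor scores
    shifted by the score of an artificial zero-concentration sample)
    regressed against raw concentrations; contributions from the
    regression coefficients.
  * **Simplified geometric UNMIX** — min–max scaling, SVD-based source-count
    estimation, maximum-volume-simplex vertex (pure-sample) resolution with
    alternating NNLS refinement, and the `Min Rsq > 0.8` /
    `Min Sig/Noise > 2` validity diagnostics.
  * **PMF** — from-scratch positive matrix factorization `X ≈ G F`
    minimizing `Q = Σ ((X − G F)/U)²` by weighted multiplicative updates,
    with the error-fraction uncertainty model
    `U = sqrt((θ·C)² + MDL²)`, robust vs true Q (Huber-type cutoff at
    |scaled residual| = 4), signal-to-noise species screening,
    factor-number scanning against `Q_expected = nm − k(n+m)`, multi-start
    best-of-N fitting, and iterative outlier-sample removal driven by the
    Q_true/Q_robust gap.
* **A synthetic multi-source generator** with known ground truth
  (4 sources × 6 elements × 101 samples by default, Dirichlet mixing,
  log-normal loads, multiplicative noise, optional injected outliers) and
  recovery scoring, so every stage is testable without field data.
* **Cross-model factor alignment** by exhaustive cosine matching, and a
  one-call pipeline (`run_pipeline()`) driving any subset of stages from a
  single config.

## Worked example

Single-element risk factors at the extremes observed in a Zhejiang
farmland survey, using the built-in reference table (province background
values and Hakanson toxicity coefficients Zn = 1, Cr = 2,
Cu = Ni = Pb = 5, Cd = 30):

```r
library(metalsource)
refs <- zhejiang_reference()
round(single_risk(c(0.11, 0.95), ref_lookup(refs, "Cd", "background"),
                  ref_lookup(refs, "Cd", "toxicity")), 2)
#> [1]  47.14 407.14
risk_index(c(8.60, 3.85, 31.94, 160.01, 2.56, 10.69))
#> [1] 217.65
classify_ri(217.65)
#> [1] moderate
```

Cd alone spans the moderate-to-very-high Eri bands (47.14–407.14), and a
sample with average element risks lands at RI = 217.65 — a moderate
comprehensive risk dominated by Cd.

Source apportionment on a synthetic survey with known truth:

```r
sim  <- simulate_scenario(default_scenario(seed = 7))
U    <- uncertainty(sim$table, refs)
fit  <- pmf_fit(sim$table, U, k = 4, pmf_config(n_runs = 20, seed = 7))
fit
#> PMF solution, k = 4 factors, 101 samples
#> Q_true = 135, Q_robust = 135 (best of 20 runs)
#> Species r2:
#>    Cu    Zn    Pb    Cd    Cr    Ni
#> 0.984 0.969 0.994 0.979 1.000 0.980
#> Factor shares (%):
#>    F1    F2    F3    F4
#> 17.19 32.50 26.89 23.42
rec <- score_recovery(fit$f, pmf_shares(fit), sim$truth)
round(rec$cosine, 3)        # aligned profile similarity per source
#> [1] 0.996 0.999 0.998 0.997
round(rec$share_error, 2)   # share error in percentage points
#> [1] 3.75 1.31 3.18 1.88
```

The fitted factors match the generating source profiles with cosine
similarity ≥ 0.996 and recover each source's overall share within
4 percentage points.

The full pipeline — screening, risk, all three models, and a cross-model
alignment report — runs from one config:

```r
res <- run_pipeline(list(scenario = list(n = 101), seed = 7,
                         pmf = list(k = 4), unmix = list(k = 4),
                         apcs = list(retention = 4)))
res$alignment
```

## Documentation

The methods vignette (`vignettes/source-apportionment.Rmd`) describes the
models, the uncertainty and noise assumptions, every tunable parameter
with its default and rationale, what the synthetic generator does and does
not emulate, and the package's known limitations.
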