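---
title: "Receptor-model source apportionment of soil heavy metals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor-model source apportionment of soil heavy metals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalsource)
```

## The problem

A farmland survey measures m trace-element concentrations (mg/kg) at n
sampling points. Receptor models treat each sample as a non-negative
mixture of a small number of unobserved source profiles — industrial
fallout, agricultural inputs, traffic dust, parent material — and estimate
both the profiles and each source's contribution using only the internal
structure of the receptor data. `metalsource` implements three such models
with deliberately different mathematics, because agreement between
independent models is the main practical check on an apportionment, plus
the Hakanson risk indices used to rank the hazard itself.

## Ecological risk indices

For element i with measured concentration $C_i$, regional background $S_i$
and toxic-response coefficient $T_{r,i}$ (Zn = 1, Cr = 2, Cu = Ni = Pb = 5,
Cd = 30 by convention, loaded from the reference table):

$$E_{r,i} = T_{r,i}\,\frac{C_i}{S_i}, \qquad RI = \sum_i E_{r,i}.$$

Class bands: $E_r$ low < 40 ≤ moderate < 80 ≤ considerable < 160 ≤ high
< 320 ≤ very high; $RI$ low < 150 ≤ moderate < 300 ≤ considerable < 600 ≤
high < 1200 ≤ very high. Published band definitions are inconsistent about
whether 150 belongs to the low or moderate RI class; the package makes
every lower edge inclusive, uniformly, so classification is monotone and
free of gaps.

## APCS-MLR

Concentrations are standardized column-wise with the sample (n−1) standard
deviation, $Z_{ij} = (C_{ij} - \bar C_i)/\sigma_i$. Principal components
of the correlation matrix are retained by the Kaiser rule (eigenvalue
> 1) or a fixed count; loadings are eigenvectors scaled by the square root
of their eigenvalues, varimax-rotated by default. Rotation is a design
choice, not a mathematical necessity: unrotated solutions rarely give the
clean one-or-two-marker-element factors that make sources interpretable,
so the package rotates unless told otherwise (`rotate = "none"`).

Factor scores use the regression method, $B = R^{-1}L$ (with a
pseudo-inverse fallback when elements are perfectly collinear). The
*absolute* score of a sample is its factor score minus the score of an
artificial zero-concentration sample whose standardized coordinates are
$-\bar C_i/\sigma_i$. Working with score differences — rather than
differences of standardized concentrations, which is how the operation is
sometimes printed — keeps the quantity a proper factor score and
reproduces the append-zero-row construction exactly; the test suite checks
this equivalence to 1e-10.

Each element is then regressed (OLS) on all absolute scores:
$C_i = b_{0i} + \sum_p \mathrm{APCS}_p\, b_{pi}$. The mean contribution of
factor p to element i is $b_{pi}\,\overline{\mathrm{APCS}_p}$. Signed
contributions are kept in the output; for percentage tables, negative mean
contributions are floored at zero, the remainder (including the intercept)
is reported as *unidentified*, and rows are renormalized to 100 % — the
common APCS-MLR reporting convention. Overall factor shares average the
per-element percentages with equal element weights; a
concentration-weighted aggregation would emphasize the most abundant
elements and is intentionally not the default, since the survey's elements
span four orders of magnitude.

## Simplified geometric UNMIX

The geometric model needs no preset source count and no uncertainties,
which is exactly what makes it a useful cross-check on PMF. The package's
implementation is an explicitly simplified self-modeling mixture
resolution — the production EPA tool's NUMFACT and edge-finding internals
are unpublished, so a published, testable pure-sample algorithm is
substituted:

1. **Scaling.** Per-element min–max (dispersion) scaling to [0, 1]; the
   extremes are kept so everything maps back to mg/kg.
2. **Source count.** SVD of the column-centred scaled matrix. For
   candidate rank r the noise floor is the mean squared trailing singular
   value beyond r, and k is the *smallest self-consistent rank*: the
   smallest r for which exactly r components exceed twice their own noise
   floor. The self-consistency requirement matters: a naive "count
   components above the floor" scan re-evaluates the floor at rank m−1,
   where it collapses to the single smallest singular value and
   over-detects by one on noisy low-rank data. On exact low-rank input the
   trailing values vanish and the rank is accepted outright; if no rank is
   self-consistent, k = 1 is returned flagged `low_confidence` (a single
   component cannot be resolved as a mixture).
3. **Vertices.** Samples are projected onto the top k−1 principal axes;
   the k samples spanning the maximum-volume simplex are taken as the
   nearest available approximations to pure sources (exhaustive search
   when the candidate count is small, greedy inflation from the farthest
   pair otherwise; volume ties break on the lexicographically smallest
   sample set).
4. **Refinement.** Contributions by per-sample NNLS on the vertex
   profiles, then up to 15 alternating NNLS passes (profiles given
   contributions, contributions given profiles) with a relative
   residual-sum stop at 1e-10. A single refinement pass leaves clearly
   audible vertex noise in the profiles — on the default noisy scenario it
   yields minimum per-element r² anywhere from 0.48 to 0.9, while the
   alternating scheme reaches 0.89–0.97 — so the deeper refinement is the
   default. The active-set NNLS solver occasionally stalls on degenerate
   systems; a bounded L-BFGS-B fallback covers those.

The published validity thresholds are retained: the solution is `valid`
iff the minimum per-element r² exceeds 0.8 *and* the minimum retained
signal-to-noise exceeds 2. Both diagnostics are reimplemented
operationally as described above, since their production definitions are
not public.

## PMF

Positive matrix factorization solves
$X \approx GF$, $G \ge 0$, $F \ge 0$, minimizing
$Q = \sum_{ij} \left( (X - GF)_{ij} / U_{ij} \right)^2$.

**Uncertainty model.** $U_{ij} = \sqrt{(\theta_j C_{ij})^2 + MDL_j^2}$,
with θ the per-element relative standard deviation and MDL the detection
limit. Where the reference table omits them the defaults are θ = 0.10 and
MDL = 5 % of the element mean — typical ICP-OES practice; both are plain
columns of the reference CSV, so survey-specific values drop in without
code changes.

**Optimizer.** Weighted multiplicative updates (weights $1/U^2$), the
standard monotone scheme for weighted non-negative factorization: each
update never increases Q, which the test suite verifies trace-by-trace
across seeds. Each of `n_runs` restarts (default 20) starts from seeded
uniform(0,1] matrices scaled to the column magnitudes; run r uses
`seed + r − 1`, so a fit is reproducible from one integer. Convergence is
declared when the relative Q drop falls below `tol` (1e-8) or `max_iter`
(2000) is reached, in which case the result carries a warning flag rather
than an error — a long-but-unconverged best-of-N run is still information.
A small ε (1e-12) in the update denominators guards against division by
zero; it is far below the data scale and does not measurably perturb Q.

**Reporting scale.** $GD, D^{-1}F$ leaves Q unchanged, so exported
profile rows of F are normalized to unit sum with the scale absorbed into
G. G is then in total-contribution units (mg/kg) and factor shares are
simply `100 · mean(G_k) / Σ mean(G)`, comparable across runs and across
models.

**Robust Q.** $Q_{true}$ sums squared scaled residuals;
$Q_{robust}$ replaces $r^2$ by the Huber-type
$h(r) = r^2$ for $|r| \le \alpha$, $\alpha(2|r| - \alpha)$ beyond, with
α = 4 (the conventional |scaled residual| > 4 outlier band). The two
coincide exactly when no residual passes the cutoff.

**Outlier-sample removal.** Iteratively refit, remove the sample with the
largest sum of squared scaled residuals, and stop once
$(Q_{true} - Q_{robust})/Q_{robust} \le$ `outlier_gap_tol` or
`max_removals` is hit. The default tolerance is 0.005: under well-behaved
Gaussian scaled residuals the expected gap is essentially zero (a |r| > 4
cell is a 6-in-100,000 event), so any gap above half a percent indicates
remaining heavy cells. Whole samples are removed, never single cells, and
removal aborts if n would fall below 3k.

**Factor-number scan.** For each k in range, the best-of-runs
$Q_{true}$, $Q_{robust}$, the ratio to
$Q_{expected} = nm - k(n+m)$ (the residual degrees of freedom; ≈ Q when
the uncertainty model is honest), and the run-to-run Q dispersion. No
automatic choice is made; the k reached by the single largest relative
drop in Q is marked as the elbow, for orientation only.

## Synthetic data generator

`default_scenario()` encodes the study design the package is exercised
on: n = 101 samples, six elements (Cu, Zn, Pb, Cd, Cr, Ni), four sources
with target shares 35/30/21/14 % — industrial (Cu + Ni), agricultural
(Cd + Zn), traffic (Pb with Cu and Zn), natural (≥ 80 % of its mass on
Cr). Contributions are per-sample Dirichlet mixing proportions (α
proportional to the target shares, concentration parameter 4 — dense,
correlated mixtures with occasional near-pure samples, as in real
multi-source soils) times log-normal total loads (median 500 mg/kg,
log-sd 0.4, matching the order of the surveyed element totals). Noise is
multiplicative log-normal, $X = (GF)\,e^{\varepsilon}$,
$\varepsilon \sim N(0, \theta^2)$ with θ = 0.10: positivity is automatic
and θ plays precisely the role of the uncertainty model's relative
standard deviation. Outliers, when requested, multiply 1–3 elements of a
flagged sample by a factor (default ×8), mimicking aberrant sampling
points rather than single bad cells.

What the generator does **not** emulate: spatial autocorrelation, depth
stratification, covariate structure (pH/SOM correlations), detection-limit
censoring, and — important for interpretation — absolute per-element
magnitudes. Profiles live in composition-share space, so synthetic Cd is
orders of magnitude more abundant than survey Cd; risk indices computed on
synthetic tables are therefore structurally correct but numerically
meaningless. Recovery tests passing on this generator show the estimators
work under the stated noise model; they do not certify performance on
data whose misfit is structural rather than stochastic.

`score_recovery()` matches estimated factors to true sources by
exhaustive permutation search over total cosine similarity (k ≤ 6
throughout this domain, so exhaustive beats approximate matching), then
reports per-source cosines and share errors with estimated shares
renormalized over the matched factors.

## Problem sizes and test design

The test suite exercises the estimators at the scale of the study design:
profile/share recovery sweeps run ten generator seeds with 20-restart PMF
fits at n = 101 (about 15 s), the outlier experiments use ten seeds with
ten injected outlier samples each, and oracle checks (naive Q summation,
append-zero-row scores, exhaustive permutation alignment, rank-1
factorization against a generic bounded optimizer) run on instances small
enough to verify by hand. Under these conditions the PMF recovery medians
are cosine ≈ 0.997 and share error ≈ 2.6 points, and APCS-MLR per-element
r² medians all clear 0.8.

## Known limitations

* **Cell-level outliers barely move PMF shares here.** Because
  $U \propto \theta C$, a cell multiplied by 8 sees its weight divided by
  ~64, so the fit largely ignores it: contribution shares before outlier
  removal sit within a point of a clean-data fit, and removal changes them
  within subsampling noise (improving them in about half of seeds, while
  aligned-profile cosines improve in 9 of 10). The outlier damage shows up
  instead in the fit-quality channel — species r² collapses for the
  affected elements — which matches how receptor-model practitioners
  actually diagnose outlier trouble. Claims that outliers distort *shares*
  presuppose misfit that this uncertainty model down-weights.
* The simplified UNMIX requires near-pure samples to exist; heavily mixed
  surveys (no sample dominated by one source) bias its vertex profiles
  toward mixtures, and the validity flag is the guard.
* Multiplicative-update PMF converges to local optima; multi-start
  mitigates but does not eliminate this, and run-to-run Q dispersion in
  the scan table is the practical diagnostic.
* APCS-MLR can produce negative contributions; the flooring-plus-
  renormalization convention is reported transparently (the signed table
  is in the result) but is still a convention.
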