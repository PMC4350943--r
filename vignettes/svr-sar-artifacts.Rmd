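---
title: "Auditing Tanimoto-kernel SVR potency models with SAR scores and activity landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing Tanimoto-kernel SVR potency models with SAR scores and activity landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarsvr)
```

## The question the package answers

Kernelized support vector regression predicts compound potency well *on
average*, and its global statistics (R², mean error) reward exactly that.
But medicinal chemistry cares disproportionately about the tail: highly
potent compounds, which typically sit on **activity cliffs** — pairs of
structural analogs (Tanimoto similarity above a scheme threshold) with large
potency gaps. Because cliff compounds are rare, an ε-insensitive, complexity-
penalized objective can afford to mispredict them and still look excellent.
`sarsvr` operationalizes this audit: score a data set's SAR discontinuity,
fit SVR across a regularization grid, rescore the data set *from the model's
own predictions*, and compare observed against predicted activity
landscapes.

## Scores

For potencies `pot(i)` as pKi (dimensionless, `-log10` of a molar K_i) and
Tanimoto coefficients `Tc(i,j)`:

- **Raw continuity** `cont_raw = 1 - Σ w_ij Tc(i,j) / Σ w_ij` over all pairs
  `i > j`, with `w_ij = pot(i)pot(j) / (1 + |pot(i) - pot(j)|)`. The weight
  is largest for pairs of two potent compounds at similar potency, so
  `cont_raw` is one minus a potency-weighted mean similarity: it is high
  when potency is conserved across structurally diverse compounds. Since
  `Tc ∈ [0,1]`, `cont_raw ∈ [0,1]`. The formula is implemented in this
  "1 − weighted mean" reading; the alternative reading (subtracting the
  ratio term-by-term in a different grouping) would not be bounded and would
  not behave as a continuity measure.
- **Raw discontinuity** `disc_raw`: the mean of `|pot(i) - pot(j)| Tc(i,j)`
  over *qualifying* pairs (`Tc ≥ t`). Cliffs — very similar pairs with
  large gaps — drive it up. When no pair qualifies the score is undefined
  and the package throws a typed error rather than returning 0: a silent
  zero would be indistinguishable from the genuine smoothness that this very
  analysis is designed to detect in model predictions.

The thresholds default to `t = 0.85` for MACCS-style and `t = 0.56` for
ECFP4-style fingerprints, the conventional settings for declaring two
fingerprints structural analogs under each representation; `t` travels on
the data set and can be overridden per call.

Raw scores are only comparable across data sets after standardization
against a **reference panel** of independent data sets: `Φ((raw - m)/s)`
with panel mean `m` and *sample* (n−1) standard deviation `s` (the panel is
a sample of data sets, not a population), and `Φ` the standard normal CDF.
Scoring a panel against its own statistics therefore centers near 0.5 —
a property the test suite checks.

## The SVR protocol

`fit_svr()` solves the ε-SVR dual — maximize
`-1/2 (α-α*)ᵀK(α-α*) - ε Σ(α+α*) + Σ y(α-α*)` subject to
`Σ(α-α*) = 0`, `0 ≤ α, α* ≤ C` — with the Tanimoto kernel, which on binary
fingerprints coincides with the Tanimoto similarity, so one pairwise matrix
serves scoring, regression, and embedding. Defaults and why:

- **ε = 0.1 pKi**, never tuned. Smaller values are below experimental
  detection limits for binding constants; larger values would excuse
  deviations approaching an order of magnitude, which are biologically
  meaningful. The reported error is the matching ε-insensitive absolute
  error `Σ max(0, |y - f(x)| - ε)`, i.e. the realized slack of the
  objective, and its per-compound mean.
- **C grid {1…50, 100, 250, 500, 1000}** (54 values), dense where
  underfitting-to-fit transitions happen and sparse in the overfitting tail.
- **10 trials of 50/50 random splits** (train half `⌊n/2⌋`), drawn once per
  sweep from a seeded stream and **reused for every C**, so C is the only
  factor that varies between grid points and per-trial comparisons are
  paired.
- **Best C** is the argmin of mean test error, ties broken toward the
  smaller C (the less complex model). This deliberately optimistic selection
  (no external validation set) biases *in favour* of the model — the point
  of the analysis is that the cliff artifact survives even favourable
  treatment.

### Numerical choices in the solver

The QP is delegated to `kernlab::ipop` (interior point) on the precomputed
kernel with a `1e-8` ridge on the structurally rank-deficient dual Hessian
and significance target `sigf = 12`. Two hardening measures, both
deterministic: if the scaled KKT system goes numerically singular (iterates
hugging the box boundary on near-duplicate fingerprints), the solve retries
at `sigf` 10 then 8 before raising a typed error; and when
`max(y) - min(y) ≤ 2ε` the exact optimum (zero expansion, intercept at the
target mid-range) is returned directly, since the interior-point KKT system
is singular at that degenerate optimum. The intercept is recovered from the
complementary-slackness interval `[lo, hi]` implied by the dual solution;
within that interval — which collapses to a point whenever a free support
vector exists — `b` is chosen to minimize the ε-insensitive training loss
exactly (a 1D convex piecewise-linear problem over the clipped breakpoints
`g_i ± ε`), with ties broken toward the interval midpoint. Dual coefficients
below `1e-8·max(1, C)` are snapped to zero; the test suite verifies the box
constraint `|α - α*| ≤ C`, the in-tube Karush–Kuhn–Tucker condition at
`1e-6`, agreement with an independent SVR implementation, and the
monotone decrease of training error in C at `1e-6` on a fixed split.

## Rescoring from predictions

For each compound, its predictions are averaged over the trials in which it
fell in the requested context (training or test membership); the handful of
compounds that a finite set of random splits never places in a context fall
back to their observed potency (and are flagged). Substituting these means
for the observed potencies — same similarity matrix, same threshold — and
rescoring yields the *predicted* continuity/discontinuity. Identity
substitution reproduces the observed scores bit for bit, which the tests
assert. Mean predictions are computed at the selected best C;
`discontinuity_profile()` exposes the same quantity across the whole grid.
The package reports normalized scores to users but drives its internal
comparisons with raw scores, so conclusions cannot be artifacts of a
particular panel. Pearson correlation between per-set discontinuity and
mean test error uses the exact t transform with n−2 degrees of freedom for
the two-tailed p-value.

## Landscapes

`embed_mds()` minimizes metric stress on `1 - Tc` by SMACOF stress
majorization. The start configuration is classical (Torgerson) scaling:
measured on 150-compound sets it both cuts the iteration count roughly
eight-fold and reaches lower stress than a random start (which can settle
into poorer local optima); a seeded random start remains as fallback for
degenerate inputs. Convergence is declared at a relative stress change below
`1e-9` (cap 10 000 iterations; exceeding it is an error carrying the stress
trace). A single compound embeds at the origin; coincident fingerprints
embed at (numerically) coincident points.

`interpolate_surface()` uses Shepard inverse-distance weighting with power
2 over all points — parameter-free, exact at compound locations, linear in
the potency vector, and bounded by the observed potency range, so surface
peaks are always real compounds and never interpolation overshoot. Grid
cells that coincide with several compounds take their mean. Degenerate
bounding boxes (zero-width axes) are padded by ±0.5.

`compare_surfaces()` requires both surfaces on the identical grid (the
embedding is computed once from structure, which predictions do not change).
A peak is an 8-neighborhood local maximum above the observed surface mean
plus `peak_offset` (default 1 pKi). A peak counts as **lost** unless the
predicted surface, within `match_radius` (default 2) cells, still reaches
within `peak_drop_tol` (default 1 pKi) of the observed peak height: the
height condition matters, because a flattened remnant of a tall peak can
still clear an absolute threshold while the activity cliff it represented
is gone. All three constants are explicit arguments.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the analysis
assumes: clusters of structural analogs (40 shared core bits + 8 private
bits per compound over a 1024-bit universe, giving within-cluster Tanimoto
≈ 0.7 and near-zero between clusters), cluster baseline potencies uniform
on [5, 10] pKi, smooth within-cluster variation (a linear gradient across
members spanning ± one standard deviation plus Gaussian noise, default sd
0.3 pKi — a realistic assay-scale spread), and a configurable fraction of
cliff compounds boosted by 3 pKi (clamped at the range top + 2), planted
inside clusters so the cliff pairs exceed the qualifying threshold, as
activity cliffs are defined between analogs. All sampling consumes one
seeded stream in documented order, so a configuration reproduces its data
set bit for bit on any platform with R's default generator.

What it does *not* emulate: real chemistry. There are no actual
substructures behind the bits, no correlation structure between fingerprint
features, no matched molecular pairs, no assay noise heteroscedasticity,
and cluster sizes are near-uniform rather than the heavy-tailed series
sizes of screening collections. Passing tests therefore demonstrate the
*mechanism* — ε-insensitive regression smooths discontinuous SAR regions
and flattens predicted landscapes — under controlled conditions; they do
not certify effect sizes on any particular real data set. For real data the
TSV reader and K_i curation rules (measurements below 100 µM; per-compound
values combined on the pKi scale — i.e. geometric mean of K_i, the scale
all downstream arithmetic uses, with arithmetic-K_i averaging available —
when they agree within one order of magnitude `max/min ≤ 10`, discarded
otherwise; default potency floor pKi ≥ 5, configurable to the literal
100 µM cutoff of pKi > 4) provide the standard entry path.

## Problem sizes

The test suite and the acceptance script exercise the pipeline at sizes
chosen to make every effect measurable while keeping a full run on one CPU
in the minutes range: 12 data sets of 150 compounds in 12 clusters with
cliff fractions spanning 0–0.2, a C grid of {1–10, 25, 50}, 10 split trials,
landscapes on 60×60 grids, and a 120-set reference panel of 100–140
compounds each. At these sizes the artifact is unambiguous: test-context
discontinuity collapses below the observed score in every set, the
correlation between observed discontinuity and mean test error exceeds
0.95, continuity is reproduced within 0.03, and every cliff-bearing set
loses ≈ 2 pKi of peak height in its predicted landscape.

## Known limitations

- The Tanimoto kernel/similarity unification is valid for binary
  fingerprints only; count or real-valued descriptors are out of scope.
- Dense n×n similarity matrices cap practical set sizes at a few thousand
  compounds, which covers curated per-target K_i sets comfortably.
- SMACOF finds local stress optima; embeddings are reproducible but not
  certified global, and 2D projections of high-dimensional similarity
  necessarily distort some pairs (the stress value is reported).
- `select_best_c()` evaluates on the test split itself; this is the
  deliberate positive bias discussed above, not a benchmarking protocol.
- The discontinuity score is undefined on data sets without a single
  qualifying analog pair; the package refuses rather than guesses.
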