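---
title: "Estimating intraindividual dynamic symptom networks from daily ratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating intraindividual dynamic symptom networks from daily ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idna)
```

## The problem

When one person rates the same set of symptoms every day for a few months,
the resulting multivariate time series carries information that no
cross-sectional questionnaire can: which symptom today predicts which
symptom tomorrow, for *this* person. `idna` estimates that day-to-day
structure as a sparse, signed, directed **lag-1 network**: nodes are
symptom items, an edge \(i \to j\) means that item \(i\) yesterday
predicts item \(j\) today over and above every other item (including
\(j\) itself) yesterday. The motivating use case is a clinical daily
diary — on the order of 20 items rated on ~90 of ~120 consecutive days,
with whole days missing whenever no questionnaire was completed.

## The model, stage by stage

### 1. Polynomial detrending in week-time

Slow drift or monthly cyclicity would masquerade as strong day-to-day
coupling, so each item is first residualized on a polynomial in
*weeks since the first observed day* (`(day - 1) / 7`). Orders
\(0 \dots 10\) are fit by least squares on an orthogonalized basis
(`poly()`), order 10 being high enough to capture linear and curvilinear
trend plus monthly cycles in a four-month series. Residuals are exactly
mean-zero per item.

The order is chosen by **BIC**, \(n\ln(RSS/n) + k\ln n\) with
\(k = \text{order} + 1\). This is a deliberate, conservative choice: with
ten candidate orders and ~90 observations, an AIC-family penalty retains
a spurious high-order "trend" in roughly a quarter of pure-noise series
(the familiar \(P(\chi^2_1 > 2) \approx 0.16\) per candidate,
compounded), and every falsely removed trend eats genuine day-to-day
variance that the network stage needs. BIC keeps about 95% of null
series at order 0 while still detecting a planted quadratic essentially
always; `criterion = "aicc"` is available for sensitivity analysis.
Numerically, the RSS entering the criterion is floored at
`.Machine$double.eps` times the centered sum of squares so that a
noiseless polynomial (RSS at machine zero from the exact order upward)
ties across orders and the tie is broken toward the lowest order.

A lag-1 autocorrelation diagnostic (`test_ar1()`, t-test at
\(\alpha = .05\) over calendar-consecutive residual pairs) is reported
but **not** acted on: autoregression is modeled explicitly by the
network's self-loops, and removing it here as well would subtract the
same signal twice.

### 2. Lag pairs and standardization

A day counts as observed only when every item was rated — daily
questionnaires are completed or skipped as a unit. Under the default
`calendar` policy, day \(d\) is paired with day \(d+1\) only when both
are observed, so every design row is a true yesterday-to-today
transition; in a 90-of-122-day diary this typically yields far fewer
than 89 pairs. The alternative `sequential` policy pairs consecutive
observations across gaps and is intended only to probe sensitivity to
that choice — a pair spanning a five-day gap does not estimate a lag-1
effect.

Predictors (day \(t-1\)) and outcomes (day \(t\)) are z-standardized per
item over the pair set, using the population (\(1/n\)) denominator so
that a single standardized predictor's LASSO solution is exactly the
soft-thresholded sample correlation — a closed form the test suite
checks to \(10^{-8}\). Standardization makes edge weights
partial-correlation-like and comparable across edges, and makes the
network invariant to each item's rating scale.

### 3. Node-wise LASSO with AICc tuning

Each item at day \(t\) is regressed on all \(p\) items at day \(t-1\)
with the LASSO,
\[
\min_\beta \tfrac{1}{2n}\lVert y - X\beta\rVert^2 + \lambda\lVert\beta\rVert_1 ,
\]
solved by coordinate descent (`glmnet`, `thresh = 1e-12`,
unpenalized intercept, no internal standardization) over a log-spaced
grid of 100 penalties from just above \(\lambda_{\max}\) (the smallest
penalty with an all-zero solution — the grid starts a factor
\(1+10^{-6}\) above it so the first solution is exactly empty) down to
\(10^{-3}\lambda_{\max}\). The penalty minimizing the corrected AIC,
with degrees of freedom equal to the number of nonzero coefficients
(the standard LASSO df estimate), is selected per node; the selected
**penalized** coefficients are the edge weights — no post-selection
refitting, so weights stay shrunken by design. Column \(j\) of the
assembled \(p \times p\) matrix `W` holds the selected coefficients for
outcome \(j\); rows send, columns receive; the diagonal is the
autoregressive self-loop.

AICc is a *liberal* tuning criterion here, and that is worth
understanding when reading results. Our simulations (reproduced by
`scripts/acceptance.R`) show that with strong planted effects the
AICc-tuned network detects essentially every true edge, but small
spurious edges ride along: AICc lowers \(\lambda\) to unshrink the
strong coefficients, and weakly correlated noise enters with typical
magnitudes of 0.04–0.12. On pure-noise data at diary scale the retained
off-diagonal density is ~8–10% — the same order as a real sparse
estimate's density. Users who want a stricter network can pass
`criterion = "bic"` to `estimate_network()`; the default remains AICc
because it is the established tuning choice for single-subject
regularized time-series regression, where sample sizes make
cross-validation unattractive.

### 4. Pruning, counts, and cross-checks

Edge counts are reported on the full node set (\(p^2\) possible
relations including self-loops) *before* pruning, matching the usual
arithmetic for such analyses. A node whose off-diagonal row and column
are all zero is then removed as dynamically isolated — a self-loop alone
does not save it, since a symptom that only predicts itself tells us
nothing about the system. For every retained edge,
`bivariate_table()` reports the plain Pearson lag-1 correlation over the
same pair set: when predictors share variance, the partial weight can be
much smaller than the bivariate relation (or, under suppression,
larger), and comparing the two flags exactly those multicollinear cases.

### 5. Centrality

Out-strength \(\sum_{j \ne i} |w_{ij}|\), in-strength
\(\sum_{j \ne i} |w_{ji}|\), and directed weighted betweenness with edge
cost \(1/|w|\) and fractional (Brandes) counting over co-minimal
shortest paths. Absolute values are used throughout — the network has
negative edges, and the weighted-graph conventions this follows treat a
strong negative relation as strong coupling, not as distance. Ties in
shortest paths are split fractionally because integer "number of times
on the shortest path" is ill-defined under ties. Self-loops never enter
centrality; the diagonal is reported separately as *persistence*, with
a configurable flag threshold (default \(|w_{ii}| \ge 0.3\)). Each index
is z-standardized across the retained nodes with the sample (\(n-1\))
SD; standardizing over retained rather than all original nodes is a
choice — the pruned nodes carry no centrality information. Betweenness
is validated against an exhaustive path-enumeration oracle on all small
digraphs in the test suite.

### 6. Communities on the signed network

Community structure is sought with a signed spin-glass objective on the
symmetrized weights \((W + W^\top)/2\) (the spin-glass model is defined
on undirected graphs; direction is an estimation artifact of the
node-wise regressions, not of the coupling concept):
\[
H = -\sum_{i<j}\left[w^+_{ij} - \gamma^+ p^+_{ij}\right]\delta(\sigma_i,\sigma_j)
    + \sum_{i<j}\left[w^-_{ij} - \gamma^- p^-_{ij}\right]\delta(\sigma_i,\sigma_j),
\]
with configuration-model nulls \(p^\pm_{ij} = d^\pm_i d^\pm_j / 2m^\pm\)
and resolution parameters \(\gamma^\pm = 1\) by default. \(H\) is
minimized by simulated annealing in compiled code: geometric cooling
from \(T = 1.0\) to \(0.01\) with factor \(0.99\), \(50p\) single-spin
proposals per temperature, 20 restarts keeping the best, driven by R's
RNG so a seed makes the search bit-reproducible. Disconnected graphs are
partitioned per component with offset community ids.

The membership is scored with signed **directed** modularity
\(Q = Q^+ - Q^-\), each class normalized by its total weight, so
\(Q \le 1\) and \(Q \le 0\) means the grouping is no better than a
strength-preserving random null. Because some software reports the raw
(unnormalized) objective instead — on scales of tens for a 19-node
network, where the normalized value has magnitude below one — the
package reports *both* \(Q\) and the Hamiltonian, and any comparison
with externally printed "modularity" values should be made on sign, not
magnitude, unless the external scale is known.

## The synthetic generator

`synthetic_spec()` / `simulate_ratings()` generate the process the
estimator assumes: a stationary sparse VAR(1)
\(y_t = \mu(t) + A^\top(y_{t-1} - \mu(t-1)) + \varepsilon_t\) with
Gaussian innovations, polynomial week-time trend injected on the mean
(so the ground-truth \(A\) is unaffected and detrending + estimation can
be validated jointly), a 100-step discarded burn-in, and whole days
masked i.i.d. (or in blocks, to stress the calendar pairing policy).
The default study shape used across the tests mirrors the motivating
diary: 22 items, a 122-day span, whole-day missingness probability 0.26
(≈90 observed days), innovation SD 1, planted coefficients of magnitude
0.25–0.4.

What the generator does **not** emulate: bounded ordinal rating scales
(values are Gaussian), informative missingness (days are missed at
random, not because symptoms were severe), measurement reactivity,
non-Gaussian innovations, or time-varying coupling. Passing tests
therefore show that the pipeline recovers the structure of a
well-specified stationary process at diary scale — not that any real
diary satisfies those assumptions.

## Problem sizes and numerical conventions used in validation

The test suite and `scripts/acceptance.R` use: 100 replicates of a
\(p = 6\), 8-edge, \(|a| = 0.4\), 200-pair design for support recovery;
50 pure-noise replicates at \(p = 22\), 89 pairs for null calibration;
200 white-noise series (\(n = 90\)) for detrend calibration; exhaustive
3-node and sampled 4–5-node digraphs for the betweenness oracle; and a
60,000-day run for the Lyapunov covariance check. These sizes were
chosen as the smallest at which the Monte-Carlo rates are stable to a
couple of percentage points.

## Known limitations

* AICc tuning trades specificity for sensitivity (see above); reported
  networks at diary scale should be read with the bivariate cross-check
  table alongside.
* The calendar policy discards transitions broken by missing days rather
  than imputing them; no imputation is offered.
* Only lag-1, linear, single-subject structure is modeled: no
  contemporaneous network, no higher lags, no population pooling.
* A single person's estimates generalize to that person in that period,
  nothing more; the package's inferential surface is descriptive
  (penalized point estimates), with no standard errors on edges.
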