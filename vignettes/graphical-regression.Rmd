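---
title: "Covariate-dependent graphical models with graphreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-dependent graphical models with graphreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphreg)
```

## The model

Gaussian graphical models encode conditional independence between p
measured features (genes, proteins, metabolites) through the zeros of the
precision matrix: for `Y ~ N(0, Omega^-1)`, feature i and feature j are
conditionally independent given the rest exactly when `omega_ij = 0`.  In
heterogeneous study populations a single precision matrix is a fiction:
dependencies differ between disease subtypes, drift along continuous
indices such as stemness or age, and vary across a spatial tissue domain.

`graphreg` models this heterogeneity directly.  Writing `X` for a
q-vector of sample-level *intrinsic factors* (an intercept, group
indicators, continuous indices, spatial coordinates), the model lets
every off-diagonal precision entry be a linear function of `X`,
`Y | X ~ N(0, Omega(X)^-1)`, with constant diagonal `omega_ii`.  The
classical regression characterization of a GGM carries over: each node is
regressed on the other nodes, with regression coefficients that are
linear in the intrinsic factors,

    Y_i = sum_{j != i} gamma_ij(X) * Y_j + eps_i,
    gamma_ij(X) = sum_l beta_ijl X_l,

so a nonzero coefficient vector `beta_ij.` is an edge whose strength and
sign vary across samples.  With a known node ordering the same machinery
yields covariate-modulated DAG regressions on the predecessors (`mode =
"dag"`).

Sparsity is imposed by a spike-and-slab prior on each coefficient:
`beta = b * s` with `b ~ N(0, 1/tau_l)`, `s ~ Bernoulli(pi)`,
`pi ~ Beta(aPi, bPi)` per coefficient, and a Gamma(aTau, bTau) prior on
each factor's slab precision `tau_l` within a node regression.  The noise
precision `omega_ii` carries a flat prior.  The flat prior is placed on
the precision (not the variance): this keeps conjugacy, and yields a
Gamma variational posterior with shape `n/2 + 1`.

## Inference

Posterior inference uses coordinate-ascent mean-field variational Bayes
with the structured factorization `q(b, s) q(omega) q(pi) q(tau)`; the
`(b_k, s_k)` pairs are updated jointly because spike and slab are
strongly coupled.  One sweep updates, in a fixed order, every coefficient
pair, then each `tau_l`, each `pi_k`, and `omega`.  Each block update is
an exact conditional maximizer, so the evidence lower bound (ELBO) is
non-decreasing across sweeps — the suite checks this on every fit it
runs, with tolerance 1e-6.  The spike branch of `q(b_k | s_k = 0)` is set
to the conditional prior, so it cancels from the ELBO and the `tau`
updates use only slab moments weighted by the inclusion probabilities.

Numerical choices, all fixed for bit-reproducibility:

* **Initialization** is deterministic: inclusion probabilities at the
  prior mean `aPi / (aPi + bPi)`, slab means 0, and `q(tau)`, `q(omega)`
  initialized with unit means.  The unit mean matches standardized data;
  initializing `q(tau)` at the prior-*shaped* Gamma(0.005, 0.005) instead
  would put `E[log tau]` near -200 and freeze the fit in the null model,
  which is why the prior *mean* (not the prior) is used.
* **Convergence** is declared when `|delta ELBO| < elboTol * (|ELBO| + 1)`
  with `elboTol = 1e-4`, capped at `maxIter = 1000` sweeps;
  non-convergence sets a flag rather than raising an error.  Tightening
  the tolerance to 1e-6 changes benchmark summaries by less than 0.005,
  so the looser default is kept for speed.
* **Standardization** of the feature columns uses the sample (n - 1)
  variance convention; intrinsic factors are used exactly as supplied —
  no intercept is added implicitly, because indicator-only designs (one
  indicator per group, no intercept) are a first-class use case.
* The per-coefficient update guards its logistic against overflow and
  raises an error carrying the coefficient index if a non-finite update
  ever occurs.

Hyperparameter defaults (`graphRegHyper()`) are `aTau = bTau = 0.005`
(diffuse slab precision), `aPi = 1, bPi = 4` (prior inclusion 0.2).  For
pathway-style analyses that expect dense within-set connectivity,
`aPi = bPi = 0.05` is the conventional alternative: it pushes the
inclusion weights toward 0 or 1 and tolerates high connection density.

## From posteriors to networks

For an individual (or group) with factor values `x`, the evidence for
edge (i, j) is summarized by a **weighted posterior inclusion
probability**: the weighted mean of the per-factor inclusion
probabilities `E[s_ijl]` with weights `(x_l E[b_ijl])^2`, where
`E[b] = alpha * mu` is the marginal posterior mean of the coefficient.
When every weight is zero the PIP is defined as 0 — no factor carries any
evidence of the edge at that `x`.  The **partial correlation** reported
for the edge is `-(sum_l x_l E[beta_ijl]) / E[omega_ii]` on the
precision parametrization `omega_ij(x) = sum_l beta_ijl x_l`.  Because
the node regression estimates `gamma_ij(x) = -omega_ij(x) / omega_ii`,
the noise precision cancels and the reported value reduces to the
fitted covariate combination `sum_l x_l E[b s]` of the regression-scale
coefficients, whose sign agrees with the conditional association.  The
raw value is kept (no clipping).  This convention normalizes by
`omega_ii` rather than `sqrt(omega_ii omega_jj)`, so it is a per-node
partial regression coefficient rather than a symmetric correlation;
symmetrization averages the two directed versions.

Undirected fits produce two directed estimates per pair; they are
combined by arithmetic averaging (a `"max"` rule is available as an
option).  Edges are then selected by a **Bayesian FDR rule** applied
jointly across all (pair, covariate) records: sort the PIPs in
decreasing order and keep the largest prefix whose mean posterior
probability of being a false edge, `mean(1 - PIP)`, stays at or below
the target level (0.01 by default).  The realized Bayesian FDR of the
selected set is bounded by the level by construction, and lowering the
level can only remove edges.

Downstream summaries operate on the selected edge table: per-node
connectivity degrees (sum of |partial correlation| over selected
incident edges), pathway connectivity scores (selected within-pathway
edges over possible pairs), and, for per-sample spatial networks,
PIP-weighted regional partial correlations and weighted connectivity
degrees with an optional max-1 rescaling.  Figure-style filters
("|partial correlation| above a threshold in at least one condition",
"selected in more than half of the conditions") are composable
post-filters (`filterEdges()`), not part of the method.

## What the simulation scenarios emulate

The generators reproduce the benchmark designs used to validate the
method, each with exact ground truth:

* **Multi-category** (`simulateMulticategory`): N = 151 samples split as
  evenly as possible (76/75, or 51/50/50 for three groups) over groups
  with group-specific precisions; the first group's graph is
  Erdős–Rényi with 2% connection probability and entries uniform on
  `[-1,-0.5] U [0.5,1]`, each later group differs by a random 3-edge
  swap, and each precision is shifted by `0.1 I` until positive definite.
  Factors are group indicators (indicator-only encoding by default; an
  intercept + G-1 encoding is available).
* **Continuously varying** (`simulateContinuous`): 2% of the
  (pair, factor) coefficients are set to ±1, factors are Uniform(-1, 1),
  and each subject's precision is `I` plus the factor-weighted
  coefficients.  The whole draw is repeated until *every* subject's
  precision is positive definite.  This joint rejection is a defining
  part of the design: with 151 subjects it concentrates the accepted
  coefficient supports on vertex-disjoint edges carrying one loaded
  factor each, because any interfering configuration survives all
  subjects with probability on the order of `(3/4)^151`.  The
  per-dataset acceptance probability is around 1e-5, but rejected draws
  fail within a few subjects, so generation takes seconds.  A
  `pdPolicy = "subject"` variant (resample one subject's factors,
  keeping the coefficients) is provided for callers who want interfering
  supports retained.
* **Homogeneous** (`simulateHomogeneous`): one Erdős–Rényi precision,
  i.i.d. samples, intercept-only factor — the model degenerates to
  homogeneous neighbourhood selection and serves as positive control.
* **DAG** (`simulateDAG`): continuous factors Uniform(0, 1), discrete
  factors Bernoulli(0.5); per factor, 2% of ancestor-pair coefficients
  (j < i) equal the effect size (3 by default); node i is Gaussian with
  unit sd around the factor-weighted sum over its sample-standardized
  ancestors.
* **Simpson's paradox** (`simulateSimpsons`): two groups of 100 over 3
  nodes whose A–B conditional dependencies have opposite signs;
  `simpsonsAnalysis()` contrasts the group-indicator fit with an
  intercept-only (pooled) fit.

What passing these benchmarks does *not* show: the generators draw
exactly Gaussian data from exactly the assumed model family (linearity
of the precision in the factors, constant diagonal).  Real proteomic or
spatial data violate all of these to some degree — heavy tails,
nonlinear covariate effects, unmeasured heterogeneity — so benchmark
recovery rates are upper bounds on what to expect in applications.

## Evaluation conventions

Structure recovery is scored with TPR, FPR, FDR and the Matthews
correlation coefficient, plus a threshold-free AUC computed as the
tie-aware rank statistic of the PIPs (identical to sweeping the
selection threshold, without re-running selection).  Zero-denominator
conventions: FDR is 0 when nothing is selected, MCC is 0 when any factor
of its denominator vanishes.

`replicateStudy()` matches each scenario with its reporting convention:
the multi-category scenario is scored over (pair, group) records (pooled
primary metrics; per-group averages reported alongside); the continuous
scenario is scored per subject against the subject's own edge set
(`sum_l beta_ijl x_l != 0`) and averaged; the DAG scenario is scored as
coefficient-level variable selection — every (ancestor pair, factor)
coefficient ranked by its inclusion probability against the coefficient
support.  Per-subject AUC skips degenerate subjects (no true edges), as
happens with discrete factors.

The replication harness runs 50 replicates per scenario at the benchmark
dimensions (p = 33, N = 151 undirected; p = 50, n up to 500 directed) —
sizes chosen to match the reference study conditions while keeping a
full run in the minutes range on one core.

## Known limitations and open choices

* Estimated precision fields are not projected to positive definiteness;
  the method targets edge selection, and the reported partial
  correlations are per-edge summaries, not entries of a jointly PD
  matrix.
* The partial-correlation normalization (division by `omega_ii`) is kept
  as specified; values are not guaranteed to lie in [-1, 1] and are not
  clipped.
* The mean-field family factorizes over coefficient pairs; strongly
  correlated regressors can split inclusion probability between proxies.
  The enumeration-oracle tests bound this effect on small problems
  (rank agreement with the exact posterior), but it is the main
  approximation error at scale.
* Inference is deterministic CAVI from a fixed initialization; there are
  no restarts.  Multimodality is handled by the sparsity prior rather
  than by search.

```{r example, eval = FALSE}
# A minimal end-to-end run: simulate a two-group dataset, fit, and read
# off the group networks
sim <- simulateMulticategory(n = 151, p = 33, groups = 2, seed = 1)
fit <- fitGraphReg(simFeatures(sim), simFactors(sim))
net <- buildNetwork(fit, diag(2), fdrLevel = 0.01)
head(edgeRecords(net)[edgeRecords(net)$selected, ])
connectivityDegree(net)[1:5, ]
```
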