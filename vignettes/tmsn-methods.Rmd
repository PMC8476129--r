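---
title: "Temporal multilayer symptom networks: models, nulls, and diffusion prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal multilayer symptom networks: models, nulls, and diffusion prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmsn)
```

## The problem

Two-wave clinical panels record the severity of many symptoms -- items of
instruments such as the SIPS, CAARMS, BPRS, CBCL, or MADRS -- for the same
subjects at a baseline assessment and at a longitudinal follow-up.
Cross-sectional symptom-network analysis estimates how symptoms covary at a
single time point, but says nothing about direction in time: a central
symptom may broadly *cause* later psychopathology or be broadly *caused* by
earlier psychopathology. This package models both waves in a single graph,
the temporal multilayer symptom network (TMSN), and builds two analyses on
top of it: a population-level pathway analysis that flags *gateway* symptoms
(baseline symptoms mediating many longitudinal shortest paths) and *funnel*
symptoms (follow-up symptoms broadly receiving them), and an
individual-level prediction of follow-up severity by clamped Laplacian
diffusion, validated against the clinical-stability assumption that nothing
changes.

## The network model

Each of the $p$ items appears twice, as a baseline-layer node and a
follow-up-layer node, giving a single symmetric $2p \times 2p$ adjacency.
Before edges are estimated, every item is residualized on an intercept,
age at the corresponding wave, and sex (ordinary least squares, wave-specific
age because assessments are years apart), and z-scored per item so that
instruments with different ranges share one scale. Edges are Pearson
correlations (Spearman by flag, implemented as Pearson on ranks): the two
diagonal blocks hold the cross-sectional correlations within each wave and
the off-diagonal block holds the baseline-to-follow-up (longitudinal)
correlations.

The full family of $\binom{2p}{2}$ unique pairs is corrected at once with
the Benjamini--Yekutieli step-up procedure at level $\alpha = 0.05$,
using the harmonic correction $c(m) = \sum_{i=1}^m 1/i$, valid under the
arbitrary dependence that correlation matrices exhibit. The matrix is a
single statistical object, so one correction family is the natural choice.
Correlations that fail correction get weight zero (mask thresholding, no
shrinkage). Both signs of surviving edges are kept in the `signed` network;
the `positive_only` view -- also the default substrate for path analysis
and diffusion -- zeroes surviving negative edges, which are rare in practice
and have no meaningful path length or diffusion semantics.

## Spectral embedding and its validation

Eigendecomposition of the thresholded adjacency gives "principal network
components". Components are ranked by algebraic eigenvalue; since a signed
adjacency has negative eigenvalues, variance proportions are reported over
the positive part of the spectrum (the absolute-value normalization is also
computed). The number of meaningful components is chosen against a
permutation null that preserves the edge-weight multiset while re-assigning
edges to random node pairs: leading components are retained while their
observed variance proportion exceeds the null's 95th percentile, stopping at
the first failure. Applied to a draw of its own null this retains at least
one component in about 5% of runs, which the tests verify.

Eigenvectors are sign-ambiguous, so a recorded convention orients the
2-D embedding: the second component is flipped, if needed, so follow-up
nodes sit above baseline nodes on average, and the first component is
anchored by a named node or, by default, by non-negative loading skewness.
Embedding quality is checked by correlating pairwise Euclidean distance
with the correlation strength of surviving edges, overall and within the
baseline, follow-up, and longitudinal subsets -- a faithful embedding makes
all of these clearly negative. A layer-wise statistic correlates each
node's mean longitudinal edge strength with its second-component loading
and compares the two layers by Fisher's r-to-z (the test is a package
choice; independence of the two layers' node sets is assumed).

## Longitudinal pathways, gateways and funnels

Path analysis runs on the positive-edge network with edge length
$1/w$ (the convention of the brain-connectivity toolbox family;
$-\log w$ is available by flag). Floyd--Warshall gives all-pairs shortest
paths with a predecessor matrix; ties are broken deterministically by
strict improvement with intermediates scanned in node order -- with
continuous correlation weights, exact ties have probability zero.
*Longitudinal betweenness* counts, for every ordered (baseline item,
follow-up item) pair with a finite path, the strictly interior nodes of
the reconstructed shortest path; endpoints are excluded because mediation,
not mere participation, is the concept of interest.

Significance uses an edge-reshuffling null (default 10,000 networks; the
calibration and recovery experiments in the tests use 1,000): each null
network keeps the weight multiset and edge count, re-assigning edges
uniformly to distinct node pairs while nodes keep their layer labels.
After reshuffling, nodes within a layer are exchangeable, so the null
betweenness distribution is pooled within each layer (a per-node null is
available by flag), and empirical p-values use the add-one rule
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + N)$. The same BY
operation used for edges adjusts the node p-values; significant
baseline-layer nodes are gateways, significant follow-up-layer nodes are
funnels.

A property of winner-take-all path counting worth knowing: when a strong
funnel and a gateway coexist, the funnel's planted edges form the *first*
leg of baseline-to-follow-up paths while a gateway's planted edges form
the *second* leg behind an ordinary within-layer leg, so the funnel can
absorb most shortest paths and mask the gateway. The recovery experiments
therefore plant one structure per cohort; simultaneous planting is an
interesting stress case, not the calibration setting.

## Clamped diffusion prediction

For individual-level prediction the TMSN is re-fit on the $n-1$ training
subjects for each held-out subject (strict leave-one-out: residualization
coefficients, z statistics, correlations and the FDR threshold are all
re-estimated per fold). On the combinatorial Laplacian $L = D - W$ of the
positive-edge network (D the diagonal of node strengths), the held-out
subject's residualized, training-standardized baseline severities are
clamped on the baseline-layer nodes, follow-up nodes start at 0, and the
signal evolves by $\partial x/\partial t = -\gamma L x$ with the clamp
re-imposed after every step until the maximum absolute change over free
nodes falls below $10^{-9}$. The predicted follow-up profile is the
steady state on the follow-up layer, reported in z units and
destandardized (training statistics plus the training covariate fit) for
raw-scale use.

The equilibrium satisfies $L_{UU} x_U = -L_{UB} x_B$ on the free nodes --
the harmonic extension of the boundary -- so the default solver computes
that linear solve exactly; the explicit finite-difference iteration is
available (`solver = "iterative"`) and the test suite proves the two agree
to $10^{-6}$ on hundreds of random graphs. The steady state does not
depend on $\gamma$ or on the step size within the stability region
$\Delta t < 2/(\gamma \lambda_{max})$; the default step is
$1/(\gamma\lambda_{max})$. Free components with no edge into the clamped
layer are predicted 0 -- the training mean in z units -- and flagged.
Explicit Euler is first-order accurate: at $\Delta t = 10^{-3}$ and
$\gamma t = 1$ its per-mode global error is
$e^{-\lambda}\lambda^2\Delta t/2$, so closed-form agreement at the
$10^{-4}$ level is verified in the weak-coupling regime
($\lambda_{max} \lesssim 0.5$); the clamped equilibrium itself is
step-size-free and checked to much tighter tolerance.

Predictions are evaluated, over the identical $n \times q$ held-out
observations in fold-wise z units, by mean squared error against the
clinical-stability baseline (predicted follow-up = observed baseline, whose
MSE is exactly the mean squared symptom change), compared by a paired
t-test on per-observation squared errors (Wilcoxon by flag), and by four
correlations: pooled real-vs-predicted severity, pooled real-vs-predicted
change, per-subject mean severity, and per-subject mean change. A
regression-to-the-mean check correlates pooled baseline severity with
change; under a stationary process with autocorrelation $\rho$ this is
$-\sqrt{(1-\rho)/2}$ exactly, a useful reminder that strong negative
severity-change correlations need no causal story. The baseline layer can
be augmented with additional instruments while the follow-up layer keeps
only the target instrument's items.

## The synthetic cohort generator

No clinical data ship with the package, so a generator provides cohorts
with known ground truth. It is a linear-Gaussian two-wave model on the
standardized scale: baseline items are multivariate normal with a
two-module block covariance (an "affective" and a "negative/disorganized"
module; within-module correlation 0.3, between 0.05), and follow-up items
are $f = A^\top b + \varepsilon$, where $A[i,j]$ is the standardized
cross-lag of baseline item $i$ on follow-up item $j$. Innovations share
the block correlation so both temporal layers carry the same
cross-sectional module structure, and are scaled per item so variances are
stationary at 1. The default diagonal autocorrelation is 0.35, the level
of item-wise clinical stability typically seen over a multi-year follow-up
in high-risk cohorts. Age (uniform 12--18 at baseline, about 3 years
later at follow-up; slope 0.02 z/year) and sex (Bernoulli 1/2; offset
0.15 z on the first module) enter linearly and are what the
residualization step removes. Scores map affinely to an instrument-like
scale centred at 3, optionally discretized to 0--6 integers for Spearman
robustness checks. Defaults are n = 200 subjects and 20 items per wave.

Planting a gateway adds a cross-lag of 0.3 from one baseline item onto
half of the follow-up items; a funnel receives 0.3 from half of the
baseline items. Planted edges are interleaved across the two modules --
a contiguous target set leaves a single cross-module bridge item that
becomes a spurious hub of its own. A heavily planted funnel cannot keep
unit variance, so its innovation sd is floored at 0.2 and the item is
flagged non-stationary; planting that would explain more than twice the
stationary sd is rejected. Choosing a linear-Gaussian model (rather than
an ordinal item-response model) is deliberate: every statistic in the
pipeline is correlation-based, so closed-form expectations exist (the
regression-to-the-mean formula above, stationarity of variances, FDR
calibration under independence). What passing tests on these cohorts do
*not* establish is robustness to skewed, floor-inflated ordinal scores --
the discretized mode with Spearman edges probes that direction, but
calibrating to real instrument distributions is out of scope.

A second fixture, `planted_block_network()`, builds the adjacency directly
with a prescribed spectral architecture (weights by block/layer match:
0.6 within-block same-layer, 0.2 within-block cross-layer, -0.1 and -0.5
between anticorrelated modules). These four weights were chosen, once, so
that the block contrast is the leading non-global eigencomponent and the
layer contrast the second; the embedding tests then have unambiguous
ground truth for "block separates on x, layer separates on y".

## Numerical choices and degenerate inputs

* Correlation p-values come from the t transform with $n-2$ df; constant
  columns yield $r = 0$, $p = 1$ with a warning rather than an error.
* `fdr_threshold_by()` delegates to `p.adjust(method = "BY")`; the test
  suite checks it against a literal step-up evaluation on a thousand
  random p-vectors and verifies BY rejections are nested within BH's.
* Training-fold constant items are excluded from that fold's network and
  predicted 0 (flagged); numerically constant means sd below $10^{-10}$.
* Diverging diffusion (100 consecutive growing deltas) raises an error
  pointing at the step-size condition.
* Single-sex training folds drop the sex regressor with a warning.
* Problem sizes in tests and the acceptance script: 100 random graphs up
  to n = 50 for the diffusion oracle, 1,000 p-vectors for the FDR oracle,
  100 graphs up to 8 nodes for the exhaustive path oracle, 100 null and
  2 x 50 planted cohorts (n = 200, 20 items/wave, 1,000-network nulls),
  and 2 x 50 leave-one-out cohorts for the prediction comparison.

## Known limitations

Edges are bivariate correlations, not partial correlations: hub structure
can reflect shared causes. Betweenness uses one shortest path per pair;
fractional counting over co-optimal paths is unnecessary for continuous
weights but the winner-take-all behaviour described above is real.
The diffusion network is positive-only by default; a signed Laplacian mode
exists but can violate the maximum principle and is flagged experimental.
Two waves only: no time-series (ESM) networks, no moderators, no causal
claims.
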