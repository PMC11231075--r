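---
title: "Adjusted local assortativity for MPX cell graphs: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjusted local assortativity for MPX cell graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpxassort)
```

## The data model

A Molecular Pixelation (MPX) experiment renders one cell as a bipartite
graph: A-pixels and B-pixels are DNA-tagged spatial zones on the cell
surface, and each detected antibody–oligonucleotide molecule becomes a
unit of count on an (A-pixel, B-pixel, marker) edge. `mpxassort` works on
the **A-node projection** of that graph: two A-pixels are adjacent when
they share at least one B-pixel, and each A-node carries the vector of
marker counts summed over its incident bipartite edges. The projection
conserves per-marker totals, and downstream scores use adjacency only, so
the projected graph is kept **simple and unweighted** — multiple shared
B-pixels do not create weights. Parallel observations of the same
(A, B, marker) triple are aggregated by summing counts at read time.

Personalized random walks are ill-defined across disconnected parts, so
each cell is reduced to the **largest connected component** of its
projection before scoring; the number of dropped A-nodes is reported.

## Per-node scoring

For marker counts $x$ on a connected projection, the raw local
assortativity of focal node $\ell$ reweights the global degree-weighted
assortativity with a personalized-PageRank distribution $w(\ell)$:

$$ r(\ell) = \frac{1}{\sigma_e^2}\left(\sum_v w_v(\ell)\, x_v\,
   \frac{1}{d_v}\sum_{u\sim v} x_u \;-\; \mu_e^2\right), $$

where $\mu_e$ and $\sigma_e^2$ are the mean and variance of $x$ over the
$2m$ edge ends ($\mu_e = \sum_v d_v x_v / \sum_v d_v$). Two limits anchor
the interpretation: with restart probability $\to 1$ the walk stays home
and the score reflects the focal node's own neighborhood; with restart
$= 0$ the walk forgets its origin, $w_v = d_v/2m$, and every node's score
collapses to the global assortativity coefficient — a property the test
suite checks against an edge-list oracle. A constant attribute has
$\sigma_e = 0$ and is mapped to the all-zero field, the score of uniform
mixing.

Raw scores have no fixed range, which blocks comparison across cells.
The **adjustment** $\varrho = h \circ g \circ f$ repairs this:

* $f$ divides positive scores by the positive sum and negative scores by
  the absolute negative sum. Each sign block then carries unit mass, the
  field sums to zero whenever both signs occur, and exact zeros are
  preserved.
* $g$ divides by $\sqrt{\sum_i \tilde{x}_i^2}$, the spread of the
  zero-centered field. The printed form of this step is a division by the
  Euclidean norm rather than the $n-1$-denominator sample standard
  deviation; the norm is what makes every component lie in $[-1, 1]$
  afterwards, which is the property the final bound rests on, so that is
  what is implemented.
* $h(z) = \mathrm{sgn}(z)\,\ln(|z|+1)$ compresses outliers. Because
  $|z| \le 1$ componentwise after $g$, every adjusted score lies in
  $[-\ln 2, +\ln 2]$. The logarithm base is a uniform rescaling; natural
  log is used so the bound is exactly $\ln 2$.

All-zero fields are fixed points of all three maps, so filtered markers
pass through unchanged.

### Filters

Two per-cell filters decide whether a marker is scored at all:

* **Isotype threshold** — the maximum per-cell molecule total among the
  panel's isotype-control antibodies (e.g. mIgG2b, mIgG1, mIgG2a). A
  marker whose own total is below this noise floor is zeroed. The
  comparison is strict: a marker *tying* the ceiling is kept, a choice
  made because the threshold is itself a noisy estimate of background.
  Totals are per-cell sums, not per-node maxima.
* **Vertex threshold** — the marker must have non-zero counts on strictly
  more than `vertex_threshold` (default 10) A-nodes.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `restart_probability` | 0.15 | teleport probability back to the focal node; the complement 0.85 is the walk's continuation probability, matching the common PageRank damping convention. Larger values localize the score. |
| `weight_floor` | 1e-4 | converged walk weights below this are zeroed and the vector renormalized, cutting the long tail of remote nodes. The single-scale walk plus this floor is this package's parameterization of the scale choice; both knobs are exposed. |
| `vertex_threshold` | 10 | minimum vertex support (strict) for scoring a marker |
| `tol`, `max_iter` | 1e-13, 10000 | power-iteration stopping rule (L1 residual). The tolerance sits well below the 1e-10 accuracy the tests demand of the walk weights because, at continuation 0.85, the distance to the fixed point can exceed the last step size by roughly the factor (1−α)/α ≈ 5.7. |

Numerical notes: at `restart_probability = 0` the plain iteration
oscillates on bipartite graphs, so the implementation takes the lazy
half-step $(I + P)/2$, which has the same fixed point and always
converges; for any positive restart the plain iteration is used (the lazy
walk would change the fixed point there). Ties in ranks are handled by
average ranks throughout.

## Colocalization

Pairwise colocalization is the Spearman correlation of two adjusted
fields. The defining property — invariance under strictly monotone
transforms of either field — is what makes scores comparable between
cells whose score scales differ. If either field is all-zero (filtered or
degenerate) the score is defined as exactly 0 rather than undefined.
Centered Spearman is used, i.e. ranks are mean-centered before the
product, so rank-reversed fields score −1; an uncentered rank product
would not behave as a correlation.

Higher-order colocalization applies the multiple-site similarity
$C_T = \frac{T}{T-1}\bigl(1 - |\bigcup A_i| / \sum |A_i|\bigr)$ to the
markers' **positive-score node sets** $\{v : \varrho_v > 0\}$. The strict
threshold at zero selects nodes displaying assortative structure and
excludes the uniform-mixing zeros; it is exposed for sensitivity
analysis. $C_T$ reduces to the Sørensen index at $T = 2$ and equals the
inclusion–exclusion long form exactly in integer arithmetic, which the
tests verify. A filtered marker contributes an empty set, lowering the
score of any tuple containing it.

Differential analysis compares per-cell scores of two samples: mean
difference plus a two-sided Wilcoxon rank-sum p-value, categorized as 0–3
dots at 0.01 / 0.001 / 0.0001. The test is exact (full enumeration of
rank assignments, with average ranks under ties) when both groups have
fewer than 20 cells and the enumeration stays below half a million
subsets; otherwise a tie-corrected normal approximation is used.
Whether the original analyses used exact or asymptotic p-values is not
documented; the switch-at-20 rule is this package's choice, and the two
regimes agree to the approximation error where they meet. Sidedness was
likewise unstated; two-sided is used throughout. No multiple-testing
correction is applied by default because the dot categories describe raw
p-values; `stats::p.adjust` can be applied to the differential table by
the user.

An optional permutation correction (`permutation_null`) shuffles a
marker's counts across nodes, recomputes adjusted scores per draw, and
subtracts the per-node permutation mean — permuting *counts*, not ranks,
because the count vector is the primitive observable. It is off by
default: on unpolarized markers the correction is small relative to the
score scale while multiplying runtime by the permutation count.

## The synthetic generator

`simulate_cell` emulates the structure the scores operate on, not MPX
chemistry. A-pixels are placed uniformly on the unit sphere; each B-pixel
bonds the `mean_b_degree` (default 5) A-pixels nearest a random anchor,
so the projection is locally clustered the way shared-zone graphs are;
marker molecules are Poisson per A-node and land on uniformly random
incident attachments. Polarity is planted as the `cap_fraction` of
A-pixels nearest a random pole — contiguous by construction — shared by
all polarized markers of a cell, with the inside rate multiplied by
`enrichment_fold` and the outside rate scaled by
$n / (n + (f-1)\,n_{cap})$ so the **expected total is fold-invariant**:
polarization redistributes abundance rather than inflating it, which is
what lets the tests separate abundance effects from colocalization.
Isotype controls are never polarized and default to a low uniform rate
(0.05 per node against a baseline of 1), mirroring their role as
background.

Defaults are 300 A-pixels and 600 B-pixels per cell with a 0.2 cap at
8-fold enrichment for stimulated conditions — the scale used by the
package's own validation studies (40 cells per condition for the planted
recovery study, 30 per arm at 150 A-pixels for the abundance study).
Simulated cells are trimmed to the largest projected component before
delivery, as a handful of straggler pixels with too few molecules to link
up is expected at realistic densities; a draw whose largest component
covers less than 80% of molecule-bearing pixels is rejected and redrawn
(up to 10 times) under a derived seed. Poisson is the minimal count-noise
model; real MPX features the generator does **not** emulate — pixel
dropout, multiplets, saturation, antibody cross-reactivity, the empirical
degree distribution of pixels — mean that passing recovery tests
demonstrates the method's correctness and sensitivity under clean
geometry, not its error rates on real cells.

## Known limitations

* Scores are relative within a cell; absolute values are not comparable
  to other assays, which is why the differential contrasts are the
  primary readout.
* The covariance form of assortativity scores a homogeneous *zero*
  region negative (its products sit below the squared edge-end mean), so
  "assortative" regions are regions of co-elevated counts, not merely
  homogeneous ones.
* Highly abundant markers can reach moderate pairwise scores through
  shared graph structure alone; the permutation correction addresses
  this at a steep runtime cost.
* The multiscale integration of the original local-assortativity
  formulation (integrating over all restart values) is out of scope; one
  restart value plus the weight floor is used instead.
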