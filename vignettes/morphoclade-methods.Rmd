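---
title: "Methods behind morphoclade: elastic outlines, parsimony, and ancestral ranges"
author: "morphoclade authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind morphoclade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoclade)
```

`morphoclade` packages the four quantitative stages of a hadrosaurid
systematics workflow: elastic comparison of 2D anatomical outlines with
ordination, discrete-character maximum parsimony with clade supports,
dispersal–vicariance reconstruction of ancestral geographic ranges, and
length–length allometric regression.  This vignette explains the models,
their assumptions, the tunable parameters, and the numerical choices,
and states what the synthetic-data generators do and do not emulate.

## Elastic shape analysis of outline curves

An outline is an ordered polygon `(x, y)`; closed outlines implicitly
join their last vertex to their first.  Curves are first resampled to
`m` points uniformly spaced in cumulative arc length (default
`m = 128`), then mapped to the square-root velocity function
\[
q(t) \;=\; \frac{\dot\beta(t)}{\sqrt{\|\dot\beta(t)\|}},
\]
computed by central finite differences (circular for closed curves) and
rescaled to unit L2 norm.  Differentiation removes translation exactly;
normalization removes scale.  Unit-norm SRVFs live on a sphere in L2,
where the geodesic distance between two shapes is
\[
d \;=\; \arccos \langle q_1,\; O\,(q_2 \circ \gamma)\sqrt{\dot\gamma}\rangle ,
\]
minimized over rotations \(O \in SO(2)\), monotone reparameterizations
\(\gamma\), and — for closed curves — the starting point of the second
curve.  The three nuisance variables are handled as follows.

* **Rotation** has the closed-form Procrustes solution from a 2×2 SVD.
  Reflections are excluded by default because anatomical sidedness is
  meaningful (left and right elements should be mirrored explicitly);
  `allow_reflection = TRUE` widens the group to O(2).
* **Reparameterization** is solved by dynamic programming over monotone
  lattice paths on the m×m grid, with local slopes restricted to
  \([1/4, 4]\) to prevent degenerate warps, and ties broken toward the
  diagonal so identical inputs return the identity warp.  The DP kernel
  is compiled (C++) because it is the inner loop of every distance.
* **Starting point** is searched on the grid of all `m` cyclic shifts
  (exact row rotations of `q`), refined to sub-sample resolution by
  interpolating the raw polyline — outlines with high-curvature regions
  (the tear-shaped naris has a pointed end) are sensitive to
  half-sample seam misalignment that the endpoint-fixed DP cannot
  absorb.  When the rotation-only profile is nearly flat across shifts
  (near-symmetric shapes such as circles), several spread starting
  points and a coarse rotation grid are pushed through the DP before
  the usual alternation, because the cheap scan cannot discriminate
  basins in that regime.

The three optimizations alternate (seed → rotation → warp) until the
aligned inner product improves by less than `1e-8` or 20 rounds.  A
round is accepted only if the evaluated inner product improves: the DP
maximizes a quadrature approximation of the integral, so its warp can
occasionally evaluate slightly worse than the identity and is then
discarded.  Because the DP is asymmetric in its arguments, the distance
is computed in both argument orders and the smaller value returned;
this makes `elastic_distance(a, b)` exactly symmetric at roughly twice
the cost, which we consider the right trade for a quantity that feeds a
symmetric dissimilarity matrix.

The closed-curve treatment deserves emphasis: shapes are compared on
the *open-curve* pre-shape sphere (where geodesics are analytic arc
lengths) with closure respected through the starting-point search.
Exact projection onto the closed-curve shape space is out of scope.

The length/width **aspect ratio** of an outline is the extent along the
major principal axis over the extent along the perpendicular axis
(always ≥ 1), and the diagnostic naris character bins it at the cut
points 1.85 and 2.85.  The central interval is closed — a ratio exactly
at a cut point falls *inside* `[1.85, 2.85]` — matching the wording of
the diagnosis it encodes.

## Non-metric multidimensional scaling

`fit_nmds()` embeds a dissimilarity matrix into `p` dimensions
(default 2, the two plotted ordination axes) by minimizing Kruskal
stress-1,
\[
S \;=\; \sqrt{\frac{\sum_{i<j} (d_{ij} - \hat d_{ij})^2}
                   {\sum_{i<j} d_{ij}^2}},
\]
with disparities \(\hat d\) fitted by isotonic regression of the
configuration distances on the ranked input dissimilarities (primary
approach to ties).  The update is a Guttman majorization step with
step-halving, so the stress trace is non-increasing by construction;
iteration stops at `tol = 1e-10` or 300 iterations.  The first restart
starts from classical (metric) scaling of the input, the remaining
restarts (default 8) from seeded Gaussian configurations; the lowest
stress wins and coordinates are centered.  Degenerate configurations
with zero spread are assigned stress 1 rather than dividing by zero.
Because only ranks matter, any strictly increasing transform of the
dissimilarities leaves the result essentially unchanged — one of the
property tests.

No stress value is published for the original ordination, so the
package makes no numeric claim about it; the tests instead check
self-consistency (exact Euclidean inputs embed with ~zero stress and
recover their configuration up to similarity) and the scientifically
relevant property that outline samples generated at length/width ratios
2.0 versus 3.2 separate linearly in the first two axes.

## Maximum parsimony on discrete matrices

Character matrices hold *state sets* per cell: singletons are scores,
multi-state sets are polymorphisms (`(01)`, `{01}`, `0/1`), and `?`/`-`
are the full set.  Minimal NEXUS and TNT `xread` readers (plus CSV)
preserve these semantics, and an exclusion list of original 1-based
character indices can be applied at read time — published analyses
often exclude characters, and the active-character count is then
tracked through `orig_index` rather than hard-coded.

Tree length is Fitch parsimony (intersection if non-empty, else union
and one step), summed over characters × weights, computed on a
bitmask-per-cell representation; ordered (additive) characters use the
interval variant behind a per-character flag (all characters default to
unordered, since ordering is rarely stated).  Length is a property of
the unrooted topology; an outgroup is used only to root trees for
display.

`char_min_steps` is the number of distinct observed states minus one;
`char_max_steps` is the length on a completely unresolved bush (scored
taxa minus the modal state's frequency, or the minimal absolute
deviation from a median state for ordered characters).  Polymorphic
cells are resolved to their globally most frequent contained state for
these bounds — the standard convention that keeps the retention index
well defined.  From these, `CI = Σm/L` and `RI = (Σg − L)/(Σg − Σm)`;
values are rounded only when printed.  Both "all included characters"
and "informative only" conventions exist in the literature; the default
includes everything and `informative_only = TRUE` switches (adjusting
`L` by the fixed contribution of uninformative characters).

The search is classical: random addition sequences build a starting
tree taxon by taxon at the cheapest insertion (ties broken at random
from the replicate's seeded stream), then SPR or TBR branch swapping
descends, holding up to `hold` equally parsimonious trees; distinct
optima pool over replicates, deduplicated by their set of nontrivial
bipartitions.  Trees are manipulated in a light unrooted adjacency
representation; the SPR neighborhood was validated against the known
count \(2(n-3)(2n-7)\) of distinct neighbors.  Defaults at the package
level stay modest; published-scale settings (thousands of replicates,
bootstrap in the thousands) are reachable by arguments but the tests
and examples run reduced sizes sufficient for the matrices they build.

Bootstrap proportions resample characters with replacement (implemented
as integer weight multiplication), re-run a reduced search, and count
the percentage of pseudo-replicates whose strict consensus contains
each nontrivial bipartition.  Bremer decay indices come from
converse-constraint searches: the same engine with a large penalty on
trees containing the clade, so the optimum is the shortest tree lacking
it; values are capped at `max_extra_steps` for effectively unbreakable
clades.  On five-taxon matrices the whole procedure is checked against
exhaustive enumeration of all 15 topologies.

## Dispersal–vicariance reconstruction

Ranges are bitsets over an ordered area list (the study uses four:
Europe, Asia, northern and southern North America).  Speciation is
free: a single-area ancestor duplicates, a widespread ancestor splits
by vicariance into any pair of disjoint non-empty subsets covering its
range (`2^(k-1) − 1` bipartitions; a `single_area_split` flag restricts
one daughter to one area for compatibility with stricter
implementations — the cost model itself does not restrict split sizes,
which is why unrestricted is the default).  Along each daughter branch,
every area gained costs one dispersal and every area lost costs one
extinction: `transition_cost` is the symmetric-difference size.

`diva_reconstruct` is an exact dynamic program over all candidate
distributions per node (subsets up to `maxareas`, default all areas —
no constraint is assumed because none is reported for the original
analysis):
\[
c(v, F) = \min_{(S_1,S_2)\,\in\,\mathrm{splits}(F)} \;\sum_{d=1,2}\;
\min_G\,\bigl[\,|S_d \,\triangle\, G| + c(d, G)\,\bigr],
\]
with leaves fixed at their observed ranges.  A top-down pass then marks,
for every internal node, *all* distributions that occur in at least one
globally optimal reconstruction (reported in deterministic bitset
order), mirroring the alternative reconstructions a practitioner
expects to see.  For up to 6 leaves and 3 areas the DP is verified
against exhaustive enumeration of every assignment of ranges to
internal nodes — cost and per-node optimal sets both.

The package ships a rooted topology and tip-area table for the 19
lambeosaurines *transcribed by hand from the published tree figure and
the text*; the files are flagged as transcriptions and used only for a
qualitative check: the ancestor of the southern (Velafrons +
Magnapaulia) clade and the northern helmet-crested clade includes the
widespread northern+southern North America range among its optima, the
configuration that lets the north–south split be pure vicariance.

## Allometric regression

`fit_allometry` is ordinary least squares of one length on another on
untransformed axes — the published scatterplots are linear and no model
is stated, so OLS on raw lengths is the default and a log-log (power
law) form sits behind `log = TRUE`.  The model reports slope,
intercept, residual standard deviation and standard errors, requires
`n ≥ 3` and positive finite lengths, and refuses zero predictor
variance.  Predictions carry optional 95% prediction intervals;
`estimate_body_length` converts a humerus-to-body-length model's output
to meters.  The published point estimates for the partial humerus (a
total length of 803 mm, a body length of about 12.5 m) depend on
figure data that are not printed, so the package treats them as
anchors for the workflow rather than reproducible targets; the shipped
comparative humerus-length table marks the 803 mm entry as itself an
estimate.

## Synthetic data: what it does and does not emulate

Every generator is a pure function of its arguments and seed, restores
the caller's RNG state, and records a truth table sufficient to
recompute the expected values used downstream.

* `gen_outlines` draws tear-shaped closed curves
  \(x = \cos t,\; y = w\,\sin t\,\sin^p(t/2)\) (pointedness default
  `p = 2`, a reasonable tear shape), anisotropically rescaled so the
  pre-noise aspect ratio hits each group's target *exactly*, then
  perturbed by smooth low-frequency radial noise and randomized
  rotation/translation/scale/starting point.  The default sample is 30
  outlines in two classes — 15 at ratio 2.4 (the published value for
  the taxon of interest, inside the diagnostic 1.85–2.85 band) and 15
  at 3.2 (the "above 2.85" class) with 2% noise, a sample size matching
  the digitized material.  It does not emulate digitization artifacts,
  ontogenetic series, or left/right asymmetry.
* `gen_matrix` places a fixed budget of state changes per character on
  random branches of a known topology; budget 1 gives a homoplasy-free
  matrix (CI = 1 on the generating tree by construction).  It is not a
  stochastic model of morphological evolution (no branch lengths, no
  rate variation) — recovery tests on it show the search works, not
  that real matrices behave this way.
* `gen_ranges` simulates the event-cost model forward (free
  vicariance/duplication at nodes, a set number of dispersals and
  extinctions on random branches), so the inferred cost is bounded by
  the number of placed events.
* `gen_allometry` is a plain linear model with Gaussian noise; the
  default calibration sample (n = 12, slope 1.05, σ = 10 mm over
  250–450 mm) is the size a comparative long-bone scatter of this kind
  typically has.

Passing tests on these generators demonstrates correctness of the
algorithms under the stated models and invariances; they cannot certify
behavior on features the generators omit (digitization noise spectra,
correlated characters, time-stratified dispersal, heteroscedastic
allometry).

## Numerical choices and limitations

* SRVF grids: inner products use trapezoid weights for open curves and
  uniform weights for closed ones; `m ≥ 16` for distances, `m ≥ 4` for
  SRVFs, DP grids capped at 1024.
* Problem sizes in tests and the acceptance script (outline samples of
  30 at `m = 96`, invariance checks at `m = 128`, 8–12 taxon matrices,
  bootstrap in the tens to hundreds) were chosen as the smallest sizes
  at which the checked properties are meaningful for this pipeline.
* The heuristic search is a local optimizer: completeness is
  demonstrated only at sizes where exhaustive enumeration is possible
  (≤ 8 taxa) and on homoplasy-free matrices; like any RAS+swap search
  it can in principle miss islands on hard matrices with few
  replicates.
* Split bitmasks support up to 31 taxa; DIVA supports up to 16 areas
  (practically far fewer, as candidate sets grow as `2^areas`).
* The elastic alternation is a heuristic for a non-convex problem; it
  is validated against a frozen dense seed × rotation × DP reference on
  a worst-case symmetric pair, not guaranteed globally optimal.
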