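---
title: "Landscape ecological risk assessment for oasis-desert regions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape ecological risk assessment for oasis-desert regions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oasisrisk)
```

## The problem

Oasis cities in arid regions sit inside a concentric landscape: an
irrigated, densely vegetated core; a sparse vegetated buffer that traps
wind-blown sand and stabilises soils; and open desert. Development
reshuffles this structure — cropland and built-up land expand, grassland
and unused land shrink — and the ecological risk borne by each part of the
landscape shifts with it. `oasisrisk` quantifies that risk and its
evolution: it delineates the three belts from NDVI, scores ecological risk
on a square sampling grid from landscape-pattern metrics, measures the
spatial clustering of risk, accounts for land-use transitions, projects
class areas under policy scenarios, and ranks candidate drivers of risk.
A synthetic-landscape generator supplies inputs with known structure, so
every stage of the pipeline is exercised and tested without external data.

## Zonation

NDVI (a reflectance ratio in $[-1, 1]$) is cut at two thresholds: cells
with NDVI $\ge$ 0.30 are oasis, cells with NDVI $\le$ 0.10 are desert,
anything strictly between is transition zone. The boundary assignment is
deliberate and exact — 0.30 belongs to the oasis, 0.10 to the desert —
because the two tie-break choices are otherwise arbitrary and silently
flip boundary cells between belts. Thresholds written as percentages
("30%") are parsed to fractions. Classification quality is scored against
labelled reference points with a confusion matrix and the standard overall
accuracy, Cohen's kappa, and per-class user's/producer's accuracies.
Because published accuracy tables do not always state whether rows hold
the mapped or the reference class — and user's/producer's accuracies swap
under transposition while OA and kappa do not — `accuracy_metrics()`
exposes the orientation as an argument rather than hard-coding it.
Reference points are nearest-cell lookups by 1-based row/column index
(origin top-left); there is no interpolation.

## The ecological risk index

For each landscape type $i$ present in an epoch, five global indices are
computed from the patch mosaic:

* fragmentation $C_i = N_i / A_i$ (patches per km²),
* separation $S_i = \frac{A}{2 A_i} \sqrt{N_i / A}$,
* dominance $D_i = (Q_i + M_i)/4 + L_i/2$, with $Q_i$ the fraction of
  sampling cells in which the type occurs, $M_i$ its share of all patches,
  $L_i$ its share of the mapped area,
* disturbance $LDI_i = a C_i + b S_i + c D_i$, weighted
  $(0.5, 0.3, 0.2)$ for utilized land and $(0.3, 0.2, 0.5)$ for
  unutilized land — fragmentation is what destabilises worked land, while
  sheer dominance is what matters on unused land,
* fragility $LFI_i$, the sum-normalised vulnerability rank of the type.
  The default ranks are construction 6 > forest 5 > cropland 4 >
  grassland 3 > water 2 > unused/desert 1; with seven land-use classes and
  six ranks, both grassland cover classes share rank 3 before
  normalisation.

On a 1 km × 1 km sampling grid, each cell $k$ with in-study area $A_k$
and per-type composition $A_{ki}$ receives

$$ERI_k = \sum_i \frac{A_{ki}}{A_k} \, LDI_i \cdot LFI_i,$$

a convex combination, so $0 \le ERI_k \le \max_i LDI_i \, LFI_i$ always
holds and is asserted in the test suite.

Design choices worth stating explicitly:

* **Global vs per-cell indices.** $C_i$, $S_i$, $D_i$ are computed once
  per type per epoch over the whole study area, not per sampling cell;
  $ERI_k$ then varies only through composition. The occurrence term $Q_i$
  is defined against the total number of sampling cells, which is a
  global quantity; computing the other indices at the same scope keeps
  the index internally consistent. A per-cell variant is common in the
  wider literature but is not what this index's definitions describe.
* **Separation form.** The separation index is implemented in the
  standard form $(A / 2A_i)\sqrt{N_i/A}$ used throughout this
  methodology's lineage; it is monotone in patch count and inversely
  related to the type's areal share, which is the behaviour the
  disturbance index needs.
* **Connectivity.** Patch delineation defaults to 8-connectivity
  (diagonal neighbours merge), the common remote-sensing convention;
  4-connectivity is available. Components are labelled by a depth-first
  scan implemented in C++ and are cross-checked in the tests against an
  independent pure-R flood fill on random rasters.
* **Boundary cells.** A sampling cell's $A_k$ is its actual data
  coverage; cells covering less than 10% of the nominal cell area are
  dropped, because sliver compositions are dominated by a handful of
  pixels and produce unstable ERI values.
* **Risk levels.** Published risk maps rarely state their break method.
  Here ordinal levels (default 5) use equal-interval breaks over the
  pooled min–max of all epochs supplied, so a level means the same ERI
  range in every epoch; the breaks are attached to the output. A
  constant field collapses to one level with a warning rather than an
  error.
* **Interpolation.** An inverse-distance-weighted surface (power 2) is
  available for display; analysis always uses raw cell values.

## Spatial autocorrelation

Global Moran's I over the sampling cells is

$$I = \frac{n \sum_i \sum_j w_{ij}(x_i - \bar x)(x_j - \bar x)}
           {\left(\sum_{ij} w_{ij}\right) \sum_i (x_i - \bar x)^2},$$

with contiguity weights between cells sharing an edge (rook) or an edge
or corner (queen, the default), optionally row-standardised (the
default). The local statistic
$I_i = n (x_i - \bar x) \sum_j w_{ij} (x_j - \bar x) / \sum_i (x_i -
\bar x)^2$ satisfies $\sum_i I_i / S_0 = I$ for any weights with total
weight $S_0$; the tests assert this identity at $10^{-9}$ and the exact
closed form $I = -1$ on an alternating checkerboard with rook
row-standardised weights. Significance uses conditional permutation:
holding $x_i$ fixed, neighbour values are redrawn from the remaining
cells (999 draws by default, seeded), and the pseudo-p is the one-sided
rank of the observed $I_i$. Cells with pseudo-p $\le \alpha$ (default
0.05) are typed by the sign quadrant of the centred value and its spatial
lag as High-High, High-Low, Low-High or Low-Low; everything else is
"ns". Cells without neighbours get lag 0 and are never significant.
These inference settings are conventions of the surrounding software
ecosystem, chosen here explicitly because published analyses often leave
them unstated.

## Transitions, Markov projection and scenarios

Co-registered map pairs are cross-tabulated into area-flow matrices
(km²); row-normalising a flow matrix gives the decadal Markov matrix
$P$. Classes with no source area receive identity rows with a warning —
an absent class cannot be sourced, and silently renormalising zeros would
fabricate dynamics. Projection is areal:
$\mathbf{a}_{t+1} = \mathbf{a}_t P$, one step per calibration decade;
total area is conserved to $10^{-9}$ and long-run iterates converge to
the stationary distribution, which the tests verify against the
eigen-decomposition.

The government-control scenario multiplies targeted transition
probabilities: ×0.8 for cropland/woodland/grassland → built-up and
unused land, ×1.3 for unused → cropland/woodland/grassland, ×1.1 for
built-up → woodland/grassland. Two resolutions were genuinely open:

* **Probabilities vs areas.** The multipliers act on transition
  probabilities (not transferred areas); the two differ only in the
  renormalisation rule, and probability space is where a Markov scenario
  engine naturally operates.
* **Renormalisation.** After adjustment, each row's diagonal
  (persistence) entry absorbs the difference so the row re-sums to 1.
  Restricting a transfer should leave the land where it is — persistence
  absorption encodes exactly that, whereas proportional rescaling would
  leak the restriction into unrelated transfers. If the diagonal would go
  negative, the row is rescaled proportionally with a warning; entries
  pushed above 1 are clipped with a warning.

## Driver analysis

The risk response is regressed on nine predictors (elevation, slope, soil
erosion, temperature, precipitation, GDP, population, distance to roads,
distance to towns) with a random-forest regression. Predictors are
min–max normalised with the minima and ranges taken from the training
rows only; the split is a seeded random draw with default fraction
484/646 (~75%). Hyperparameters (number of trees, maximum depth, mtry)
are tuned by exhaustive grid search with 4-fold cross-validation on the
training rows; ties in mean CV RMSE go to the first grid row, so a fixed
seed yields identical choices. The default grid is deliberately reduced —
trees {10, 20, 30, 40, 50}, depth {3, 6, 10, 15, 20}, mtry {2, 4, 6, 8} —
so a full search runs in seconds; denser ranges can be passed to
`driver_grid()`.

Validation is scored with $R^2$, RMSE and the ratio of performance to
deviation $\mathrm{RPD} = \sqrt{\sum(y-\bar y)^2 / \sum(\hat y - y)^2}$
(excellent $\ge 2$, fair $[1.4, 2)$, low $< 1.4$). $R^2$ is the
conventional coefficient of determination $1 - SS_{res}/SS_{tot}$, which
ties the two by $\mathrm{RPD} = 1/\sqrt{1-R^2}$ — an identity the tests
assert at $10^{-9}$.

Importance uses the out-of-bag permutation score: for each tree,
$err_{OOB1}$ is its mean squared error on its out-of-bag rows and
$err_{OOB2}$ the error after disturbing the target predictor among those
same rows; the importance of a predictor is the mean of
$err_{OOB2} - err_{OOB1}$ over the trees. "Disturbance" is implemented
as a within-OOB permutation — the standard operationalisation, since it
destroys the predictor-response association while preserving the
predictor's marginal distribution; additive Gaussian noise is available
behind `method = "noise"`. Scores are reported raw and sum-normalised
over their positive parts. The tree ensemble itself comes from `ranger`
(with `keep.inbag` bookkeeping); the importance score is computed by this
package from the per-tree OOB sets, not taken from the library.

## The synthetic landscape generator

The generator emulates the statistical structure the analysis assumes:

* **NDVI** is a deterministic radial profile
  $v(d) = v_0 e^{-\lambda d}$ ($v_0 = 0.6$, $d$ in cells) plus Gaussian
  noise (sd 0.03 by default), clamped to $[-1,1]$. The exponential is
  monotone and crosses each threshold exactly once, so with zero noise
  the three belts are exact concentric rings with closed-form radii —
  which the tests exploit. Marching $\lambda$ down across epochs (0.026
  → 0.018 in the default pipeline) grows the oasis and shrinks the
  desert, the trajectory of a developing oasis city. One consequence of
  the fixed exponential shape is that the transition ring is wide
  relative to real oasis belts: the ratio of the desert radius to the
  oasis radius is pinned at $\ln(v_0/0.1)/\ln(v_0/0.3) \approx 2.6$.
* **Land use** starts as a Voronoi mosaic: seed points (one per ~20×20
  cells; every class gets at least one) carry classes drawn from a
  specified share vector, dominated by cropland, low-cover grassland and
  unused land as in real arid-region land-use products. Later epochs
  apply the configured row-stochastic transition matrix independently
  per cell, followed by an optional single 3×3 majority pass that
  consolidates patches. With smoothing off, the series is an exact
  per-cell Markov chain, so the estimated transition matrix converges to
  the planted one — the tests demand max-entry error < 0.02 on a 200×200
  grid, two epochs.
* **Drivers** are independent uniforms on $[0,1]$, one row per sampling
  cell, and the response is the planted linear combination plus Gaussian
  noise (sd 0.1). The default effects put the signal on the two
  accessibility measures (distance to towns 1.0, distance to roads 0.5)
  against seven inert predictors, which is exactly the situation the
  importance harness must resolve. The response noise keeps the signal
  strong (attainable $R^2 \approx 0.9$) without making recovery trivial.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: drivers are mutually independent (real
predictors are strongly collinear, which spreads permutation importance
across correlated variables); the land-use mosaic is independent of the
NDVI field (real cropland concentrates in the oasis belt); transition
dynamics are spatially homogeneous (no neighbourhood suitability, no
patch-growing allocation); and NDVI noise is white (no sensor striping,
clouds or phenology). Conclusions about the method's behaviour under
collinearity or spatial allocation must come from elsewhere.

Every generator call derives deterministic sub-stream seeds from the
single configured seed, so identical configurations are bit-reproducible
and partial regeneration is stable.

## Numerical choices and degenerate inputs

Row-stochasticity is checked at $10^{-9}$; composition closure at
$10^{-6}$ km². Moran statistics raise an error on constant fields rather
than returning 0 (an undefined statistic should not masquerade as "no
autocorrelation"). Undefined user's/producer's accuracies (zero row or
column) are `NA`, not 0. A perfect regression fit reports RPD = ∞ with
category "excellent". The ASCII-grid writer emits full double precision
(`%.17g`) so float rasters round-trip bit-exactly; integer rasters
round-trip exactly by construction.

## Problem sizes

The default test suite runs the Markov-recovery check at 200×200 cells,
the patch-statistics oracle on one hundred 20×20 rasters, the driver
harness at n = 646 samples (484/162 split) with 20 importance
replicates, and the ERI property sweep on fifty 40×40 landscapes; the
full pipeline demo uses a 200×200-cell scene (20 km × 20 km at 100 m)
with a 1-km sampling grid, i.e. a 20×20 block of 400 sampling cells.
These sizes give the asymptotic checks (law-of-large-numbers recovery,
permutation nulls) comfortable headroom while the whole suite stays fast.

## Known limitations

Spatial allocation of projected demand (patch-growing cellular automata)
is out of scope: projections are class-area totals. The package reads and
writes single-band ESRI ASCII grids; GeoTIFF and vector inputs are not
supported. Real-data results from any particular study region (specific
ERI thresholds, Moran values, 2030 risk shares) are not reproducible from
the synthetic generator and are not claimed by the test suite; the suite
verifies the method's internal contracts and its published, printed-table
arithmetic instead.
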