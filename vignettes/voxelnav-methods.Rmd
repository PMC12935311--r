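---
title: "Quantifying 3D navigation behaviour: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D navigation behaviour: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxelnav)
```

voxelnav analyses how people learn object locations while moving through a
3D voxel world (the motivating task is a Minecraft-style memory-and-navigation
game: two 10-minute training sessions to find 12 hidden objects on a terrain,
followed by a placement test). The package covers the whole arc from raw
terrain and trajectory logs to a participant-level regression, and ships a
simulator so that every stage can be validated against known ground truth.

## The terrain graph and Dijkstra distance

Terrain is a height field: each (x, y) cell carries one integer elevation z
and an obstruction flag (water, trees, fences). Blocks are the nodes of a
directed weighted graph. A step from block $u$ to block $v$ is *walkable*
when

1. neither cell is obstructed,
2. the cells are distinct 8-neighbours ($|\Delta x| \le 1$, $|\Delta y| \le 1$),
3. the elevation change satisfies $-\text{max\_fall} \le \Delta z \le \text{max\_climb}$.

Defaults are max_climb = 2 and max_fall = 3: a player can hop up at most two
blocks and drop at most three in a single step. (Game descriptions are not
perfectly consistent about the climbing limit — three blocks is sometimes
quoted — so the limit is a `movement_rules()` parameter; all results are
conditional on the configured rules.)

A walkable edge costs

$$w(u, v) \;=\; \sqrt{\Delta x^2 + \Delta y^2}
  \;+\; \alpha_\uparrow \max(\Delta z, 0)
  \;+\; \alpha_\downarrow \max(-\Delta z, 0),$$

the 2D Euclidean step length plus an asymmetric vertical surcharge. The
exact functional form and coefficients of the vertical term are a modelling
choice; this additive form is the simplest one that (i) reduces to plain 2D
distance on flat ground, (ii) grows with $|\Delta z|$, and (iii) makes
ascending strictly costlier than descending. Defaults are
$\alpha_\uparrow = 2$, $\alpha_\downarrow = 1$, both configurable. Because
the weights are direction-asymmetric the graph must be directed, and
distances from all cells *to* a target are computed by single-source
shortest paths on the edge-reversed graph (`distance_field()`). Shortest
paths themselves are delegated to igraph's Dijkstra implementation; the
package builds the graph and the tests validate distances against an
independent exhaustive path enumeration and against the octile closed form
$\max(|dx|,|dy|) + (\sqrt2 - 1)\min(|dx|,|dy|)$ on flat open maps.

## Segments and the cost-difference curve

Training paths (1 Hz position samples) are cut at object-find events: each
segment runs from the session start or the previous find to the next find,
and a participant finding $m$ objects contributes $m$ segments. The sample
recorded at an event time closes one segment and anchors the start of the
next, so interiors are disjoint while every segment still knows its starting
position; path recorded after the last find is discarded, since a curve
needs a destination object.

For samples $t_0, \dots, t_N$ of a segment, define the *actual cost-to-go*

$$A(t_j) = \sum_{k=j}^{N-1} c\!\left(P(t_k), P(t_{k+1})\right),$$

where $c$ is the step cost (0 when stationary, the edge weight for a
walkable step, and the Dijkstra distance for any larger jump — the
generalisation that keeps the triangle-inequality structure below), and the
*optimal cost-to-go* $O(t_j) = d\!\left(P(t_j), P(t_N)\right)$, the Dijkstra
distance from the current block to the segment-end block. The
*cost-difference curve* is

$$D(t_j) = A(t_j) - O(t_j).$$

This cost-to-go reading is a deliberate design decision. It guarantees
three invariants that the package asserts on every processed segment:
$D \ge 0$ (the realised remainder can never beat the optimum),
$D$ non-increasing (each step spends at least as much actual cost as it can
reduce the optimal cost-to-go, by the triangle inequality), and
$D(T_s) = 0$. A cumulative-from-start reading would be non-decreasing and
could never reproduce the observed "drops sharply before the middle" /
"stays high for most of the segment" shapes that distinguish navigation
strategies, so it cannot be the intended statistic. The curve is evaluated
at every 1 Hz sample; the optimal cost is read off one distance field per
segment.

Because segment durations vary, each curve is linearly rescaled to a
unified time interval $[0, T]$ and linearly interpolated on a fixed grid
(`normalize_curve()`). The unified scale is $T = 100$ with 101 grid points
by default — the value of $T$ is immaterial (it is a pure relabelling of
time) and only the grid resolution matters; 101 points oversample curves
whose typical duration is tens of seconds. Linear interpolation preserves
endpoints exactly and maps monotone sequences to monotone sequences, so the
three invariants survive normalisation, and the operation is idempotent on
the unified grid.

## Functional clustering

Each normalised curve is represented by its ordinary least-squares
coefficients on a clamped cubic B-spline basis with equally spaced knots
(12 basis functions by default; the clustering is insensitive to this
within reason, and the count is a parameter). K-means is run on the raw
coefficient vectors — they all share path-cost units, so standardisation
would distort relative amplitudes — with 10 random restarts per seed, and
curves from all environments and sessions are pooled before clustering.
Clusters are relabelled by decreasing size, so cluster 1 is always the
dominant (most efficient) pattern. The number of clusters is chosen by the
mean silhouette width over a candidate range, and the stability of a
solution is quantified by re-clustering under fresh seeds and averaging the
adjusted Rand index against the reference solution. Composition tables
cross-tabulate cluster shares by training session, environment, and
first/intermediate/final segment position.

On synthetic curves planted from four archetype shapes (flat-zero;
shallow-decreasing; high-until-late; early-sharp-drop) the silhouette
criterion selects $K = 4$, the planted partition is recovered with ARI
$\ge 0.9$, and the mean ARI across 100 reseeds exceeds 0.99.

## Participant features and test outcomes

Segments are triaged by their optimal start-to-end cost with a cutoff of
70 path-cost units: segments at or above the cutoff (the boundary is read
strictly, "below 70" = low) are *removed* from the participant's mean curve
and counted as the removed-curve count — they represent long or
intrinsically hard legs whose curves are not comparable with typical ones.
The participant's functional covariate is the pointwise mean of the
normalised curves of low-cost segments; cluster proportions (shares of
clusters 2..K) and the average segment time are computed over *all*
segments. Participants with no low-cost segment are excluded from the
functional regression and reported.

The placement test yields three outcomes per participant: $Y_1$, the number
of objects placed within 10 blocks of their true location; $Y_2$, the mean
time from teleport-in to placement over correct trials; and $Y_3$, the mean
distance from the true location over correct trials. Correctness and $Y_3$
both use the directed Dijkstra distance from the placed block to the true
block — the metric the precision outcome is defined in — so a placement
separated from the truth by an uncrossable river is wrong even when the
Euclidean gap is small (Euclidean correctness is available as an option).
$Y_2$ and $Y_3$ are undefined (NA) when nothing was placed correctly.

## Scalar-on-functional regression

Each outcome is modelled separately as

$$y_i \;=\; z_i^\top \gamma \;+\; \int_0^T X_i(t)\,\beta(t)\,dt \;+\;
  \varepsilon_i, \qquad \varepsilon_i \sim N(0, \sigma^2),$$

with $z_i$ the scalar covariates, $X_i$ the participant's mean low-cost
curve, and $\beta(t)$ expanded on a cubic B-spline basis with 10 functions.
Estimation minimises the penalised sum of squares with curvature penalty
$\lambda \int \beta''(t)^2\,dt$, $\lambda = 0.1$ by default. Numerical
choices:

* the functional integral uses trapezoidal quadrature on the unified grid —
  exact for the piecewise-linear normalised curves;
* the penalty matrix is integrated exactly by per-interval 3-point
  Gauss–Legendre quadrature (the integrand is piecewise quadratic for cubic
  splines);
* the penalised normal equations are solved in closed form; a system whose
  eigenvalue ratio falls below $10^{-13}$ is declared singular (legitimate
  designs sit many orders of magnitude above this);
* standard errors and p-values for $\gamma$ use the effective-degrees-of-
  freedom sandwich approximation for penalised least squares and are
  flagged approximate;
* if the curve matrix carries no information at all ($X \equiv 0$) the fit
  reduces exactly to ordinary least squares on the scalar covariates with
  $\beta \equiv 0$;
* when the curves are rank-deficient (e.g. many identically-zero mean
  curves from optimal navigators, as happens in small simulated cohorts),
  the linear part of $\beta$ — the curvature penalty's null space — is
  genuinely unidentified and no $\lambda$ can fix it. `sofr()` then errors;
  an optional proportional ridge (`ridge` argument) provides a documented
  minimum-norm stabilisation, and the pipeline falls back to
  `ridge = 1e-6` automatically, recording the fact in its report.

Pointwise 95% confidence bands for $\beta(t)$ come from a case-resampling
bootstrap over participants (percentile method); replicates with singular
refits are redrawn and counted. Increasing $\lambda$ never increases the
fitted roughness $\int \hat\beta''^2$, a property the tests assert.

## The synthetic-data generator

Because raw participant data for this kind of study are typically not
shareable, the generator is a first-class module that emulates the study's
structure: smoothed integer terrains (white noise through a box blur,
rounded, shifted positive) with a random obstruction mask; 12 objects and a
start cell, regenerated until mutually reachable in both directions;
10-minute (600 s) training sessions at 1 Hz; and a placement test with
four edge start cells, Gaussian placement error, and a 180 s per-trial cap.

Agents move on the lattice at one cell per second — a simplification of
continuous player motion — and visit objects in nearest-next order with
policy noise, under four styles mirroring the strategy clusters: *direct*
walks Dijkstra paths (identically-zero curves); *corrective* inserts short
random detours (shallow decreasing curves); *prolonged_wanderer* performs a
weakly goal-biased random walk for most of a segment (curves high past the
midpoint); *late_adapter* wanders for an early fraction (default 0.3) and
then commits (early completed drop). The default cohort mixes styles as
(0.45, 0.30, 0.15, 0.10) — efficient navigation dominating, all styles
represented — on 40×40 maps with elevation amplitude 2 blocks and 10%
obstruction; these values were fixed once as a realistic regime and are all
configurable. Outcomes are drawn from the scalar-on-functional generative
model itself, using each participant's own simulated mean curve and
per-outcome coefficient sets on disjoint covariates (so outcome
correlations stay near zero, matching the separate-regressions treatment).

For estimator validation, `simulate_sofr_data()` draws the functional
covariate as random smooth curves with full-rank variation in basis space
(iid coefficients on a 12-function B-spline). This is deliberate: the four
archetype shapes span a low-dimensional space in which $\beta(t)$ is only
identified up to the span, so archetype curves are the right input for
clustering validation but the wrong one for recovery and coverage studies.

What the simulator does *not* emulate: continuous sub-cell motion and
sprint/jump mechanics, genuinely exploratory search order, head-orientation
data, and learning across sessions. Passing tests therefore demonstrate
that the statistical machinery recovers known structure under the stated
generative assumptions — not that real players satisfy those assumptions.

## Validation scale

The shipped checks run at sizes chosen to balance statistical resolution
against desk-scale runtimes: exhaustive shortest-path enumeration on all
grids up to 5×5 (100 random terrains plus adversarial hand-built cases);
1,000 random pairs for the octile closed form; a 50-participant cohort for
the curve invariants; 2,000 planted curves with 100 reseeds for clustering;
100 Monte-Carlo replicates at $n = 200$ for $\gamma$ recovery, with the
$\beta$ ISE trend over $n \in \{50, 100, 200, 400\}$ averaged over 20
seeds; and 200 replicates with 200 bootstrap resamples each for band
coverage at the mid-grid point.

## Known limitations

* Eq.-style edge weights are one member of a family; all downstream
  quantities are conditional on the configured `movement_rules()`.
* Diagonal steps may cut corners past obstructed cells unless
  `strict_corners = TRUE`; the permissive default matches the bare
  walkability conditions.
* p-values from the penalised fit are approximate; inference about
  $\beta(t)$ should lean on the bootstrap bands.
* Percentile bootstrap bands can undercover when the curvature penalty
  induces non-negligible bias (large $\lambda$, rough true $\beta$).
* K-means on spline coefficients assumes roughly spherical clusters in
  coefficient space; heavily skewed or overlapping strategy mixtures may
  need model-based alternatives.
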