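# voxelnav

Quantifying how people navigate and learn object locations in 3D voxel
environments.

The package targets studies of spatial memory built on Minecraft-style
tasks: participants explore a block world during timed training sessions to
find hidden objects, then place the objects back from memory in a test
phase. The raw material is unforgiving — integer terrain with cliffs, water
and fences; 1 Hz position logs; event streams of finds and placements — and
plain Euclidean path metrics misrepresent it, because vertical movement is
constrained (climbs of at most two blocks, falls of at most three) and
asymmetric in effort. voxelnav provides the full analysis arc:

1. **Terrain graph.** The map becomes a weighted *directed* graph. A step
   between 8-neighbour cells costs
   `sqrt(dx^2 + dy^2) + alpha_up * max(dz, 0) + alpha_down * max(-dz, 0)`
   (defaults `alpha_up = 2`, `alpha_down = 1`), and the minimal path cost
   between blocks — the Dijkstra distance `d(a, b)` — is the task's notion
   of distance (`dijkstra()`, `distance_field()`).
2. **Cost-difference curves.** Training paths are segmented at object
   finds. For each segment, `D(t) = A(t) - O(t)` compares the actual
   remaining (cost-to-go) path cost `A(t)` with the optimal remaining cost
   `O(t) = d(P(t), end)`; `D` is non-negative, non-increasing, and zero at
   the segment end. Curves are rescaled to a common grid for comparison
   (`cost_difference_curve()`, `normalize_curve()`).
3. **Functional clustering.** Curves are summarised by cubic B-spline
   coefficients and clustered with K-means; the cluster count comes from
   the silhouette score and stability from the adjusted Rand index across
   reseeds (`cluster_curves()`, `select_k_silhouette()`,
   `clustering_stability()`, `composition_tables()`).
4. **Scalar-on-functional regression.** Test outcomes (objects correctly
   placed within 10 blocks; mean time and mean Dijkstra distance of correct
   placements) are regressed on scalar covariates plus the participant's
   mean curve: `y_i = z_i' gamma + int X_i(t) beta(t) dt + e_i`, with
   `beta(t)` on a 10-function B-spline basis under a curvature penalty
   (`lambda = 0.1`) and bootstrap confidence bands (`sofr()`,
   `sofr_bootstrap()`).
5. **Simulation.** Agent-based generators for terrains, four navigation
   styles (direct / corrective / prolonged wanderer / late adapter), test
   sessions, and full cohorts with known ground truth
   (`generate_terrain()`, `simulate_training_session()`,
   `generate_cohort()`), plus `run_pipeline()` to orchestrate everything
   deterministically.

## Worked example

```r
library(voxelnav)

terr <- generate_terrain(width = 30, depth = 30, seed = 42)
terr$map
#> Terrain map: 30 x 30 cells, elevation [1, 18], 91 obstructed (10.1%)

dijkstra(terr$map, terr$start, c(terr$objects$x[1], terr$objects$y[1]))
#> Path: 9 blocks, Dijkstra distance 12.89949
```

The distance 12.9 is the cheapest walkable route: nine blocks including
diagonal moves and vertical surcharges, not the straight-line length.
Simulate a "late adapter" (wanders early, then commits) and score one of
its segments:

```r
sim <- simulate_training_session(terr, agent_policy("late_adapter"), seed = 1)
segs <- segment_training_path(sim$path, sim$events)
cv <- cost_difference_curve(terr$map, segs[[2]])
cv
#> Cost-difference curve obj8 -> obj1: D(0) = 16.6569, T = 17 s, optimal start cost 21.0711
```

`D(0) = 16.7` says this 17-second leg wasted 16.7 cost units over the
optimum (21.1); the curve falls to 0 by construction as the agent closes in.
Cluster 2,000 synthetic curves from the four planted strategy shapes:

```r
ac <- simulate_archetype_curves(2000, seed = 7)
co <- spline_coefficients(ac$values, ac$grid, bspline_basis(12))
select_k_silhouette(co, 2:6, seed = 1)$best_k
#> [1] 4
cl <- cluster_curves(co, 4, seed = 1)
cl
#> K-means curve clustering: k = 4, sizes 908/582/313/197 (45.4%/29.1%/15.7%/9.8%), inertia 281573
mclust::adjustedRandIndex(cl$assignments, ac$truth)
#> [1] 1
```

The silhouette score picks the true number of strategies and the partition
matches the planted labels exactly (ARI = 1). Finally, fit the
scalar-on-functional regression on simulated data with known coefficients
(`gamma = (2, 0.05, -1, -1.5)`, `beta(t) = 0.01 sin(pi t / 100)`):

```r
d <- simulate_sofr_data(n = 200, seed = 3)
fit <- sofr_bootstrap(sofr(y ~ age + skill, d$data, d$curves, d$grid),
                      n_boot = 200, seed = 1)
summary(fit)
#>               term estimate      se      t   p_value
#>        (Intercept)  1.87300 0.37090  5.050 1.051e-06
#>                age  0.06253 0.01194  5.237 4.397e-07
#>  skillIntermediate -1.34600 0.17710 -7.601 1.401e-12
#>        skillNovice -1.58600 0.17420 -9.103 1.363e-16
#> beta(t): 10 basis functions, lambda = 0.1, effective df 14
#> n = 200, R-squared = 0.95, residual variance = 0.9828
plot(fit)   # beta(t) with 95% bootstrap bands
```

Every estimate sits within two standard errors of its generating value.
`run_pipeline(pipeline_config(...), out_dir)` chains all stages on a
simulated cohort and writes plain CSV/JSON artifacts plus a `report.json`.

## Documentation

The methods vignette (`vignettes/voxelnav-methods.Rmd`) describes the
movement model, the cost-to-go construction and its invariants, the
clustering and regression machinery, every numerical choice and default,
what the simulator does and does not emulate, and known limitations.
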