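---
title: "Target-range tuning of stochastic sampling parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-range tuning of stochastic sampling parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopt)
```

## The problem

Stochastic sampling engines — most prominently MCMC samplers used in
integrative structure modeling — expose tuning parameters such as maximum
move sizes for coarse-grained beads and rigid bodies.  Each parameter
$x_i \in [c_i, d_i]$ influences one or more *metrics* $f_j$ (for example the
proposal acceptance rate of the corresponding Monte Carlo mover), and
sampling is efficient only when each metric's expected value lies in a
target range $[a_j, b_j]$ (a typical acceptance-rate band is $[0.3, 0.6]$).
The metrics have no known functional form, are expensive to evaluate (each
evaluation is a sampling run), and are noisy: the observable is
$f'_j(x, \eta)$ with $f_j(x) = E_\eta[f'_j(x, \eta)]$, estimated by
averaging a fixed number of *replicates*.  With $R$ replicates of Gaussian
noise of standard deviation $\sigma$, the averaged noise has standard
deviation $\sigma/\sqrt{R}$.

`stopt` implements a derivative-free, global, stochastic, parallel,
multiobjective heuristic for this problem, together with the baselines used
to benchmark it.  The goal is a point $x^*$ with
$f_j(x^*) \in [a_j, b_j]$ for every metric — *any* such point, not an
optimum.

## The procedure

**Grouping.**  The user declares a bipartite dependency graph from
parameters to metrics.  Its connected components ("groups") are
independently optimizable: the metrics of one group are functions of that
group's parameters only.  Components are computed with igraph and ordered
by smallest parameter name for reproducibility.

```{r grouping}
groups <- partition_groups(docking_problem())
groups
```

**m-ary search.**  Within a group with $n$ parameters the root samples all
$m(n)^n$ combinations of $m(n)$ linearly spaced values per axis, endpoints
included.  A *feasible range* is an interval between two axis-adjacent
evaluated points whose metric values bracket the target range; by the
intermediate value theorem a continuous metric must pass through the band
inside it.  Each feasible range becomes a node of a depth-first search
tree; below the root every node is a 1-D search along its range's axis,
with the other coordinates frozen at the *anchor* values of the grid line
where the range was found.  A child node adds $m$ strictly interior points
and inherits its endpoint values from the parent, so the root rejects
$(m-2)/(m-1)$ of the domain and each deeper level $m/(m+1)$ of its range.
The search ends at the first candidate whose replicate-averaged values are
inside all target ranges (closed intervals; boundary values count), or when
all nodes are exhausted or the depth cap is reached.

**Multiple metrics.**  An interval is kept only if it is feasible for
*every* metric of the group.  A common feasible range does not guarantee a
common solution — the per-metric desired ranges inside it may not overlap —
which is why the DFS backtracks into sibling ranges:

```{r backtracking}
ls6b <- worked_example("fig6b")
tr <- run_group_search(
  partition_groups(landscape_problem(ls6b))[[1]],
  synthetic_evaluator(ls6b, noise_sd = 0),
  search_settings(m = 3, seed = 1))
tr$visit_log
tr$solution$coords
```

**Prioritization.**  When several ranges are found, each metric's values
along the range's grid line are interpolated (cubic spline with at least 4
support points, exact quadratic with 3, linear with 2) and all interpolants
are queried at 100 equally spaced points per range; ranges are explored in
descending order of the fraction of query points at which every
interpolated metric is in band.  Ties preserve discovery order, which is
what makes the symmetric worked example reproducibly explore its left
range first.

**Scheduling.**  Every black-box run needs a value for *every* parameter of
the problem, so the scheduler pairs, slot by slot, one unexplored candidate
from each active group (completed groups contribute their fixed values: the
solution, or the last explored point after a failure).  A *block* holds
$\min_j t_j$ slots, where $t_j$ is the number of unexplored candidates in
group $j$'s current node, each slot expanded into $R$ replicate requests.
Random streams are derived from (seed, group key, node id, candidate id,
replicate, metric name), where the group key hashes the group's sorted
parameter names; a group's tree is therefore bit-identical whether it is
optimized alone or co-scheduled, and results do not depend on dispatch
order or concurrency.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `m` | `"auto"` | branching factor per dimensionality; entries must be >= 2 |
| `max_depth` | 5 | DFS depth cap (root = 0); bounds runtime and guards against noise-induced misclassification of feasible ranges |
| `replicates` | 1 | evaluations averaged per candidate; noise shrinks as $1/\sqrt{R}$ |
| `max_processes` | 1 | concurrency cap for dispatching a block |
| `n_interp` | 100 | spline query points per range in prioritization |

The `"auto"` rule sets $m(1) = 8$ and, for $n > 1$, the largest
$q \ge 2$ with $q^n \le \max(m(1)^2, 64)$ such that $q^n$ is a multiple of
$m(1)$, falling back to 2.  The multiplicity requirement keeps block sizes
commensurate with $m(1)$ so a machine with `max_processes` a multiple of
$m(1)$ stays fully loaded; the configuration `m(1)=8, m(2)=4, m(3)=4` with
8 processes satisfies the recommendation exactly.  Violations are
*warnings*, never errors, because the rule is a utilization recommendation,
not a correctness condition.

## Synthetic landscapes and what they do (not) show

Four worked polynomial examples (`worked_example("fig6a")` …
`"fig6d"`) exercise every code path — success at depth 2, multi-metric
backtracking, a 2-D root grid, and a failure where the target band hugs the
function's maximum between grid points.  All use additive Gaussian noise
with sd 0.05 and $m = 3$ on $[-1, 1]$ domains.

`random_landscape(dimension, h, seed)` generates benchmark surfaces as a
seeded sum of $h$ Gaussian radial bumps (centers uniform in the domain,
widths $U(0.3, 0.9)$, signed amplitudes with magnitude $U(0.4, 1)$),
affinely rescaled so the minimum and maximum over a dense probe grid (2001
points in 1-D, $201^2$ in 2-D) are 0 and 1.  $h$ acts as a roughness knob:
$h = 1$ is unimodal, $h = 5$ gives the moderately multi-modal surfaces used
in the benchmark.  This generator is the package's own design; benchmark
claims made with it are property-based (success, evaluation-count
percentiles), not numeric reproductions of any external benchmark set.

These landscapes are smooth, low-dimensional, and carry homoscedastic
Gaussian noise.  Passing tests on them demonstrates the search logic —
bracketing, prioritization, backtracking, replicate averaging, scheduling —
but not robustness to the pathologies of real sampling metrics:
heteroscedastic or heavy-tailed noise, drift between replicates, or
landscapes rougher than the spline interpolant assumes.  The depth cap is
the main guard when a noisy pair of values spuriously brackets the band.

## Baselines

* `binary_search_1d()` bisects under an assumed monotonic
  parameter-metric relationship with a known gradient sign; it halves the
  search space per iteration, so localizing a desired range that is $1/r$
  of the domain takes at most $\lceil \log_2 r \rceil$ iterations.
* `worst_case_iterations(r, m)` returns the m-ary analogue
  $\log(r/(m-1))/\log(m+1) + 1$, the level count at which the retained
  interval is no wider than the desired range.
* `ga_search()` is a generational genetic algorithm: fitness is the
  negative distance of the metric value to the nearest target-range edge
  (0 inside, so any in-band point is an immediate success), the fittest
  25% are retained, 75% of the next generation are mutants of the retained
  set (each coordinate perturbed uniformly within the maximum mutation
  size and clipped to the domain), and one uniformly chosen coordinate is
  swapped within random pairs drawn without replacement from a subset half
  the population size.  With an evaluation budget of 10,000 this is
  exactly 2000 generations at population 5 and 200 at population 50 when
  no early convergence occurs.

## Numerical and design choices

* **Feasibility test.**  An interval is metric-feasible iff the closed
  interval spanned by its two endpoint values *intersects* the target
  range.  This generalizes strict flanking (one endpoint below the band,
  the other above) to endpoint values lying inside the band; in the
  single-metric case the two rules coincide, because an in-band averaged
  value terminates the search as a solution before range detection runs.
* **Closed boundaries.**  A value exactly at a target-range edge counts as
  inside.
* **Depth convention.**  The root is depth 0; "a solution at depth 2" means
  two refinement levels below the root grid.
* **Spline degree switch.**  Cubic needs 4 support points; with exactly 3
  the quadratic through them is used, with 2 the straight line.  The
  interpolant is only a ranking heuristic — it never decides feasibility.
* **Tie-breaking.**  Range sorting is stable, so equal scores preserve
  lexicographic grid order.
* **Degenerate inputs.**  Zero-width domains, reversed targets, orphan
  parameters/metrics and unresolvable dependency names are all collected
  by `validate_problem()` and reported together; a degenerate child range
  raises immediately.
* **GA fractional counts.**  At population 5 the retained 25% rounds to 1
  member (`max(1, round(...))`); the crossover subset is
  `floor(population / 2)`.
* **External runs.**  The file protocol passes one JSON key per parameter
  plus a reserved `.seed` key so external replicates are reproducible;
  values are serialized with 17 significant digits so they round-trip the
  interchange format exactly.

## Problem sizes used by the test suite

The shipped tests run the worked examples at their stated conditions
(noise sd 0.05, 100 replicates, 50 seeds for the stochastic agreement
rates), the worst-case bound over $r \in \{10, 10^2, 10^3, 10^4\}$ and
$m \in \{3, 4, 5, 8\}$, and the benchmark property on 20 random 2-D
landscapes at $h = 5$ with the grid/DFS search at $m = 5$ and a GA
mutation-size sweep $\{0.02, 0.05, 0.1, 0.25, 0.5\}$ with 3 initializations
per landscape — sizes chosen so the whole suite completes in a few minutes
on one core while still measuring every documented property.

## Known limitations

* Cost grows as $m(n)^n$ at the root: the method is not efficient in high
  dimensions, and a gradient-based method will beat it there.
* It is a heuristic: a target band lying strictly between grid values with
  no bracketing pair (the `fig6d` fixture) is not found; increasing `m`,
  widening the band, or shrinking the domain are the remedies.
* Backtracking explores ranges sequentially per group; only groups and
  within-node candidates are parallelized, as in the reference flow.
* The GA baseline's crossover operator is underdetermined in the
  literature it follows; the implemented operator (single-coordinate swap)
  is one documented choice among several reasonable ones.
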