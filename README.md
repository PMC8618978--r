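# stopt

Derivative-free, global, stochastic, parallel, multiobjective optimization
of simulation parameters whose noisy metrics must land inside target
ranges — an R implementation of the StOP (Stochastic Optimization of
Parameters) heuristic, built for tuning MCMC move sizes in integrative
structure modeling and any other black box with the same shape.

## The problem and who it is for

Samplers used in integrative modeling (and molecular simulation generally)
expose parameters such as rigid-body maximum rotations/translations and
flexible-bead maximum translations.  Each parameter $x_i$ has an input
domain $[c_i, d_i]$; each metric $f_j$ — typically a Monte Carlo proposal
acceptance rate — must end up with its expected value inside a target range
$[a_j, b_j]$ (for example $[0.3, 0.6]$).  The metrics are black boxes:
expensive (one evaluation = one sampling run), noisy
($f_j(x) = E_\eta[f'_j(x,\eta)]$, estimated by averaging $R$ replicates),
and without gradients.  The goal is any $x^*$ with
$f_j(x^*) \in [a_j, b_j]$ for all $j$.

## The algorithm

1. **Group** the bipartite parameter→metric dependency graph into connected
   components; each group is optimized independently (and concurrently).
2. **Root grid**: sample all $m(n)^n$ combinations of $m(n)$ linearly
   spaced values per parameter, endpoints included.
3. **Feasible ranges**: an interval between two axis-adjacent evaluated
   points whose metric values bracket the target band must contain the band
   (intermediate value theorem, given continuity) — for every metric of the
   group at once.
4. **Depth-first refinement**: each feasible range becomes a node of a DFS
   tree; a child places $m$ interior points inside its range (inheriting
   endpoint values), rejecting $(m-2)/(m-1)$ of the domain at the root and
   $m/(m+1)$ per level thereafter.  Ranges are explored in descending order
   of a spline-interpolated estimate of in-band coverage.  The search
   backtracks out of dead branches and stops at the first candidate whose
   replicate-averaged metrics are all in band, or at the depth cap.
5. **Scheduling**: every run needs the full parameter vector, so blocks of
   $\min_j t_j$ slots pair one unexplored candidate per active group with
   the fixed values of completed groups, each slot times $R$ replicates,
   dispatched up to `max_processes` at a time.

Baselines for comparison: 1-D binary search under a known gradient sign,
the worst-case m-ary iteration formula $\log(r/(m-1))/\log(m+1) + 1$, and a
generational genetic algorithm with elitism, clipped uniform mutation and
single-coordinate crossover.

## Worked example

Tune the 1-D quadratic-peak landscape $f(x) = 1 - x^2$ on $[-1, 1]$ into
the band $[0.6, 0.68]$, with Gaussian noise (sd 0.05) averaged over 100
replicates and ternary branching:

```r
library(stopt)

landscape <- worked_example("fig6a")
problem   <- landscape_problem(landscape)
settings  <- search_settings(m = 3, replicates = 100, seed = 1)
report    <- run_optimization(problem,
                              synthetic_evaluator(landscape, noise_sd = 0.05),
                              settings)
report
#> <optimization_report> 1 group(s), 3 block(s), 900 request(s)
#>   [x] success at depth 2: x = 0.625
report$groups$x$solution$values$metric1
#> [1] 0.609506
```

The root grid $\{-1, 0, 1\}$ measures values near $\{0, 1, 0\}$ and finds
two feasible ranges ($[-1, 0]$ and $[0, 1]$, a prioritization tie).  Two
refinement levels later the candidate $x = 0.625$ measures
$0.6095 \in [0.6, 0.68]$ — a solution at depth 2 after 900 evaluator calls
(9 candidates × 100 replicates).  Noiseless, the same search
deterministically returns $|x| = 0.625$ with metric value exactly
$1 - 0.625^2 = 0.609375$.

Grouping on the protein-docking example (rigid-body rotation/translation
drive two acceptance rates, flexible-bead translation a third):

```r
partition_groups(docking_problem())
#> [[1]]
#> <stop_group 1> parameters: FBTrans | metrics: FB-AB
#>
#> [[2]]
#> <stop_group 2> parameters: RBRot, RBTrans | metrics: RB-A, RB-B
```

`write_report(report, "outdir")` serializes the report (JSON), per-group
DFS trees (JSON + DOT, visit-ordered), and per-node candidate tables (CSV).
Configs (YAML or JSON) drive the same machinery via `load_config()` /
`run_config()`; a CLI wrapper lives at `inst/cli/stop.R` with subcommands
`run`, `example` and `benchmark`, and `inst/exec/mock_sampler.R` is a small
random-walk MCMC demonstrating the external-command evaluator protocol
(JSON in, JSON out, one invocation per replicate).

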