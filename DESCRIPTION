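Package: stopt
Title: Stochastic Optimization of Parameters for Target-Range Tuning of
    Noisy Black-Box Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derivative-free, global, stochastic, parallel, multiobjective
    optimization of simulation parameters whose noisy metrics (for example,
    Markov chain Monte Carlo move sizes and their proposal acceptance rates)
    must fall inside user-given target ranges.  Implements the StOP heuristic:
    the parameter/metric dependency graph is partitioned into independently
    optimizable groups, each group is searched with an m-ary grid at the root
    and depth-capped depth-first refinement of feasible ranges detected by
    intermediate-value bracketing, with spline-based prioritization of ranges
    and replicate averaging of stochastic metrics.  Includes a block scheduler
    for co-optimizing groups against expensive black-box evaluators, synthetic
    polynomial and random smooth landscapes for verification, an external
    command evaluator with a JSON file protocol, and baseline methods (1-D
    binary search, worst-case m-ary iteration counts, and a genetic
    algorithm) for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
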