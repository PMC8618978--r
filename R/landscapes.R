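# Synthetic metric landscapes: the worked polynomial examples and a seeded
# random smooth-landscape generator for benchmarking.

new_landscape <- function(dimension, parameters, metrics, domains, targets,
                          noise_sd = 0, m = NULL, name = "landscape") {
  structure(
    list(dimension = dimension, parameters = parameters, metrics = metrics,
         domains = domains, targets = targets, noise_sd = noise_sd, m = m,
         name = name),
    class = "stop_landscape"
  )
}

#' Worked polynomial example landscapes
#'
#' Four small polynomial landscapes with additive Gaussian noise
#' (recommended sd 0.05) used to exercise every code path of the search:
#'
#' * `fig6a` - one parameter, one metric: `f(x) = 1 - x^2`, domain
#'   `[-1, 1]`, target `[0.6, 0.68]`.  A successful search: two feasible
#'   ranges at the root, solution at depth 2.
#' * `fig6b` - one parameter, two metrics: `f1(x) = 1 - x^2` and
#'   `f2(x) = 1 - x^3 - 1.2*x^2 + 0.5*x`, both targets `[0.6, 0.68]`.
#'   Exercises multi-metric intersection and DFS backtracking: the first
#'   depth-1 branch has non-overlapping metric-specific ranges and fails.
#' * `fig6c` - two parameters, one metric:
#'   `f(x1, x2) = 1 - ((x1 + x2)/2)^2`, target `[0.6, 0.68]`.  A 2-D root
#'   grid with four feasible ranges along grid lines.
#' * `fig6d` - one parameter, one metric: `f(x) = 1 - (x - 0.5)^2`, target
#'   `[0.85, 0.95]`.  The target sits near the maximum between grid points,
#'   so no feasible range is found and the search fails.
#'
#' @param name one of `"fig6a"`, `"fig6b"`, `"fig6c"`, `"fig6d"`.
#' @return a `stop_landscape` with elements `metrics` (named list of
#'   functions of a named parameter vector), `domains`, `targets`,
#'   recommended `noise_sd` (0.05) and `m` (3).
#' @export
#' @examples
#' ls6a <- worked_example("fig6a")
#' ls6a$metrics$metric1(c(x = 0))  # 1
worked_example <- function(name) {
  band <- c(lower = 0.6, upper = 0.68)
  dom <- c(lower = -1, upper = 1)
  switch(
    name,
    fig6a = new_landscape(
      1, "x",
      metrics = list(metric1 = function(x) 1 - x[["x"]]^2),
      domains = list(x = dom), targets = list(metric1 = band),
      noise_sd = 0.05, m = 3, name = "fig6a"),
    fig6b = new_landscape(
      1, "x",
      metrics = list(
        metric1 = function(x) 1 - x[["x"]]^2,
        metric2 = function(x) 1 - x[["x"]]^3 - 1.2 * x[["x"]]^2 + 0.5 * x[["x"]]
      ),
      domains = list(x = dom),
      targets = list(metric1 = band, metric2 = band),
      noise_sd = 0.05, m = 3, name = "fig6b"),
    fig6c = new_landscape(
      2, c("x1", "x2"),
      metrics = list(
        metric1 = function(x) 1 - ((x[["x1"]] + x[["x2"]]) / 2)^2
      ),
      domains = list(x1 = dom, x2 = dom), targets = list(metric1 = band),
      noise_sd = 0.05, m = 3, name = "fig6c"),
    fig6d = new_landscape(
      1, "x",
      metrics = list(metric1 = function(x) 1 - (x[["x"]] - 0.5)^2),
      domains = list(x = dom),
      targets = list(metric1 = c(lower = 0.85, upper = 0.95)),
      noise_sd = 0.05, m = 3, name = "fig6d"),
    stop("unknown worked example: '", name, "'")
  )
}

#' Random smooth landscape generator
#'
#' Builds a seeded random smooth function on `[-1, 1]^dimension` as a sum of
#' `h` Gaussian radial bumps
#' `raw(x) = sum_j a_j * exp(-||x - c_j||^2 / (2 * w_j^2))`
#' with centers `c_j` uniform in the domain, widths `w_j ~ U(0.3, 0.9)` and
#' signed amplitudes `|a_j| ~ U(0.4, 1)`, rescaled affinely so that its
#' minimum and maximum over a dense probe grid are 0 and 1.  Larger `h` gives
#' rougher, more multi-modal surfaces; `h = 1` is unimodal.
#'
#' @param dimension number of parameters (`>= 1`).
#' @param h number of bumps (smoothness knob, `>= 1`).
#' @param seed integer seed; the landscape is a deterministic function of
#'   `(dimension, h, seed)`.
#' @return a `stop_landscape` with a single metric `metric1` and parameters
#'   `x1 ... xd` on `[-1, 1]`.
#' @export
#' @examples
#' ls <- random_landscape(2, h = 5, seed = 42)
#' ls$metrics$metric1(c(x1 = 0, x2 = 0))
random_landscape <- function(dimension, h, seed) {
  stopifnot(dimension >= 1, h >= 1)
  pars <- paste0("x", seq_len(dimension))
  draws <- with_stream(stream_seed("landscape", seed, dimension, h), {
    list(
      centers = matrix(stats::runif(h * dimension, -1, 1), nrow = h),
      widths = stats::runif(h, 0.3, 0.9),
      amps = stats::runif(h, 0.4, 1) * sample(c(-1, 1), h, replace = TRUE)
    )
  })
  raw_matrix <- function(X) {
    # X: N x d matrix -> length-N raw values
    acc <- numeric(nrow(X))
    for (j in seq_len(h)) {
      d2 <- rowSums((X - matrix(draws$centers[j, ], nrow(X), dimension,
                                byrow = TRUE))^2)
      acc <- acc + draws$amps[j] * exp(-d2 / (2 * draws$widths[j]^2))
    }
    acc
  }
  probe_per_axis <- if (dimension == 1) 2001L else if (dimension == 2) 201L
                    else if (dimension == 3) 41L else 11L
  axes <- rep(list(seq(-1, 1, length.out = probe_per_axis)), dimension)
  probe <- as.matrix(expand.grid(axes))
  pv <- raw_matrix(probe)
  rmin <- min(pv)
  rmax <- max(pv)
  f <- function(x) {
    xv <- matrix(as.numeric(x[pars]), nrow = 1)
    (raw_matrix(xv) - rmin) / (rmax - rmin)
  }
  new_landscape(
    dimension, pars,
    metrics = list(metric1 = f),
    domains = stats::setNames(rep(list(c(lower = -1, upper = 1)), dimension),
                              pars),
    targets = list(metric1 = c(lower = 0.6, upper = 0.68)),
    noise_sd = 0,
    name = sprintf("random-d%d-h%d-seed%d", dimension, h, seed)
  )
}

#' Build a problem from a landscape
#'
#' Declares every landscape metric as depending on every landscape parameter
#' (the worked examples and random landscapes are fully coupled within a
#' single group).
#'
#' @param landscape a `stop_landscape`.
#' @return a [stop_problem()].
#' @export
landscape_problem <- function(landscape) {
  stop_problem(
    parameters = lapply(names(landscape$domains), function(p) {
      d <- landscape$domains[[p]]
      stop_parameter(p, d[["lower"]], d[["upper"]])
    }),
    metrics = lapply(names(landscape$targets), function(m) {
      t <- landscape$targets[[m]]
      stop_metric(m, t[["lower"]], t[["upper"]])
    }),
    dependencies = stats::setNames(
      rep(list(names(landscape$targets)), length(landscape$domains)),
      names(landscape$domains))
  )
}

#' @export
print.stop_landscape <- function(x, ...) {
  cat(sprintf("<stop_landscape '%s'> %d parameter(s), %d metric(s)\n",
              x$name, x$dimension, length(x$metrics)))
  invisible(x)
}
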