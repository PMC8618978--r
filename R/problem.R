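# Problem definition: parameters with input domains, metrics with target
# ranges, and the bipartite parameter -> metric dependency graph.

#' Declare an optimization parameter
#'
#' A parameter is a tunable scalar of the modeling setup (for example an MCMC
#' move size such as a rigid-body maximum translation, in problem-specific
#' units) searched over a closed input domain `[lower, upper]`.
#'
#' @param name unique identifier.
#' @param lower,upper closed input domain bounds, `lower < upper`.
#' @return an object of class `stop_parameter`.
#' @export
#' @examples
#' stop_parameter("FBTrans", 0.1, 10)
stop_parameter <- function(name, lower, upper) {
  structure(
    list(name = as.character(name), lower = as.numeric(lower),
         upper = as.numeric(upper)),
    class = "stop_parameter"
  )
}

#' Declare a metric with its target range
#'
#' A metric is a stochastic objective evaluated by the black-box backend (for
#' example an MCMC proposal acceptance rate).  A solution must place the
#' replicate-averaged value of every metric inside its closed target range
#' `[lower, upper]`.
#'
#' @param name unique identifier.
#' @param lower,upper closed target range bounds, `lower <= upper`.
#' @return an object of class `stop_metric`.
#' @export
#' @examples
#' stop_metric("FB-AB", 0.3, 0.6)
stop_metric <- function(name, lower, upper) {
  structure(
    list(name = as.character(name), lower = as.numeric(lower),
         upper = as.numeric(upper)),
    class = "stop_metric"
  )
}

#' Assemble an optimization problem
#'
#' @param parameters list of [stop_parameter()] objects.
#' @param metrics list of [stop_metric()] objects.
#' @param dependencies named list mapping each parameter name to the character
#'   vector of metric names that depend on it (the bipartite dependency
#'   graph: an edge `x -> f` means `f` is a function of `x`).
#' @return an object of class `stop_problem` with elements `parameters`
#'   (named list of `c(lower, upper)`), `metrics` (named list of
#'   `c(lower, upper)`) and `edges` (data frame with columns `parameter`,
#'   `metric`).
#' @seealso [validate_problem()], [partition_groups()]
#' @export
#' @examples
#' docking_problem()
stop_problem <- function(parameters, metrics, dependencies) {
  par_names <- vapply(parameters, `[[`, character(1), "name")
  met_names <- vapply(metrics, `[[`, character(1), "name")
  pars <- lapply(parameters, function(p) c(lower = p$lower, upper = p$upper))
  mets <- lapply(metrics, function(m) c(lower = m$lower, upper = m$upper))
  names(pars) <- par_names
  names(mets) <- met_names
  edges <- data.frame(
    parameter = rep(names(dependencies),
                    vapply(dependencies, length, integer(1))),
    metric = unlist(dependencies, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  structure(
    list(parameters = pars, metrics = mets, edges = edges),
    class = "stop_problem"
  )
}

#' Validate an optimization problem
#'
#' Checks every structural invariant of the problem and returns all
#' violations at once rather than stopping at the first.
#'
#' @param problem a [stop_problem()].
#' @return character vector of human-readable violations; empty when the
#'   problem is well-formed.
#' @export
validate_problem <- function(problem) {
  v <- character(0)
  pn <- names(problem$parameters)
  mn <- names(problem$metrics)
  if (anyDuplicated(pn)) {
    v <- c(v, sprintf("duplicated parameter name(s): %s",
                      paste(unique(pn[duplicated(pn)]), collapse = ", ")))
  }
  if (anyDuplicated(mn)) {
    v <- c(v, sprintf("duplicated metric name(s): %s",
                      paste(unique(mn[duplicated(mn)]), collapse = ", ")))
  }
  for (p in pn) {
    d <- problem$parameters[[p]]
    if (!all(is.finite(d)) || d[["lower"]] >= d[["upper"]]) {
      v <- c(v, sprintf(
        "parameter '%s' has a degenerate input domain [%g, %g] (need lower < upper)",
        p, d[["lower"]], d[["upper"]]))
    }
  }
  for (m in mn) {
    t <- problem$metrics[[m]]
    if (!all(is.finite(t)) || t[["lower"]] > t[["upper"]]) {
      v <- c(v, sprintf(
        "metric '%s' has an invalid target range [%g, %g] (need lower <= upper)",
        m, t[["lower"]], t[["upper"]]))
    }
  }
  e <- problem$edges
  bad_p <- setdiff(unique(e$parameter), pn)
  bad_m <- setdiff(unique(e$metric), mn)
  if (length(bad_p)) {
    v <- c(v, sprintf("dependency references undeclared parameter(s): %s",
                      paste(bad_p, collapse = ", ")))
  }
  if (length(bad_m)) {
    v <- c(v, sprintf("dependency references undeclared metric(s): %s",
                      paste(bad_m, collapse = ", ")))
  }
  orphan_p <- setdiff(pn, e$parameter)
  orphan_m <- setdiff(mn, e$metric)
  if (length(orphan_p)) {
    v <- c(v, sprintf("parameter(s) with no dependent metric: %s",
                      paste(orphan_p, collapse = ", ")))
  }
  if (length(orphan_m)) {
    v <- c(v, sprintf("metric(s) that depend on no parameter: %s",
                      paste(orphan_m, collapse = ", ")))
  }
  v
}

#' Partition a problem into independently optimizable groups
#'
#' Computes the connected components of the bipartite parameter/metric
#' dependency graph.  Each component ("group") can be optimized without any
#' knowledge of the other groups, because its metrics are functions of its
#' parameters only.  Groups are ordered by their smallest parameter name for
#' reproducibility.
#'
#' @param problem a valid [stop_problem()].
#' @return list of `stop_group` objects; each has named elements `parameters`
#'   (named list of domains), `metrics` (named list of target ranges), `n`,
#'   `k` and `index`.
#' @export
#' @examples
#' groups <- partition_groups(docking_problem())
#' length(groups)  # 2
partition_groups <- function(problem) {
  viol <- validate_problem(problem)
  if (length(viol)) {
    stop("invalid problem:\n", paste("-", viol, collapse = "\n"))
  }
  e <- problem$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("p:", e$parameter),
               to = paste0("m:", e$metric)),
    directed = FALSE
  )
  comp <- igraph::components(g)
  membership <- comp$membership
  groups <- lapply(seq_len(comp$no), function(i) {
    members <- names(membership)[membership == i]
    pars <- sort(sub("^p:", "", members[startsWith(members, "p:")]))
    mets <- sort(sub("^m:", "", members[startsWith(members, "m:")]))
    structure(
      list(parameters = problem$parameters[pars],
           metrics = problem$metrics[mets],
           n = length(pars), k = length(mets), index = NA_integer_),
      class = "stop_group"
    )
  })
  ord <- order(vapply(groups, function(g) names(g$parameters)[1], character(1)))
  groups <- groups[ord]
  for (i in seq_along(groups)) groups[[i]]$index <- i
  groups
}

#' @export
print.stop_problem <- function(x, ...) {
  cat(sprintf("<stop_problem> %d parameter(s), %d metric(s), %d edge(s)\n",
              length(x$parameters), length(x$metrics), nrow(x$edges)))
  invisible(x)
}

#' @export
print.stop_group <- function(x, ...) {
  cat(sprintf("<stop_group %s> parameters: %s | metrics: %s\n",
              ifelse(is.na(x$index), "?", x$index),
              paste(names(x$parameters), collapse = ", "),
              paste(names(x$metrics), collapse = ", ")))
  invisible(x)
}

# A single-group "problem view" used when a group is searched on its own.
group_as_problem <- function(group) {
  structure(
    list(parameters = group$parameters, metrics = group$metrics,
         edges = expand.grid(parameter = names(group$parameters),
                             metric = names(group$metrics),
                             stringsAsFactors = FALSE)),
    class = "stop_problem"
  )
}

#' Protein-docking example problem
#'
#' A three-parameter, three-metric move-size tuning setup for docking two
#' proteins A and B: rigid-body maximum rotation (`RBRot`) and translation
#' (`RBTrans`) drive the per-protein rigid-body acceptance rates (`RB-A`,
#' `RB-B`), while the flexible-bead maximum translation (`FBTrans`) drives the
#' joint flexible-bead acceptance rate (`FB-AB`).  All acceptance-rate targets
#' are `[0.3, 0.6]`.  Partitioning yields two groups.
#'
#' @return a [stop_problem()].
#' @export
docking_problem <- function() {
  stop_problem(
    parameters = list(
      stop_parameter("RBRot", 0.01, 3.14),
      stop_parameter("RBTrans", 0.01, 10),
      stop_parameter("FBTrans", 0.01, 10)
    ),
    metrics = list(
      stop_metric("RB-A", 0.3, 0.6),
      stop_metric("RB-B", 0.3, 0.6),
      stop_metric("FB-AB", 0.3, 0.6)
    ),
    dependencies = list(
      RBRot = c("RB-A", "RB-B"),
      RBTrans = c("RB-A", "RB-B"),
      FBTrans = "FB-AB"
    )
  )
}
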