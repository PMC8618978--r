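# Depth-first search over feasible ranges, as a resumable state machine.
#
# Nodes are environments linked into a tree; the tree is also an environment
# so the scheduler can feed results incrementally.  Traversal is depth-first:
# a node's subtree is fully resolved before a sibling is opened, and the
# search ends at the first solution.

new_node <- function(tree, parent, depth, rank, axis = NA_character_,
                     lower = NA_real_, upper = NA_real_, anchor = NULL,
                     inherited = NULL, score = NA_real_) {
  node <- new.env(parent = emptyenv())
  node$id <- if (is.null(parent)) "0" else paste0(parent$id, ".", rank)
  node$depth <- depth
  node$rank <- rank
  node$axis <- axis
  node$lower <- lower
  node$upper <- upper
  node$anchor <- anchor
  node$inherited <- inherited
  node$cands <- NULL
  node$children <- list()
  node$parent <- parent
  node$status <- "pending"
  node$score <- score
  node$visit <- NA_integer_
  node$m <- NA_integer_
  tree$n_nodes <- tree$n_nodes + 1L
  node
}

new_group_search <- function(group, settings) {
  tree <- new.env(parent = emptyenv())
  class(tree) <- "dfs_tree"
  tree$group <- group
  tree$settings <- settings
  tree$status <- "running"
  tree$solution <- NULL
  tree$visit_log <- character(0)
  tree$visit_n <- 0L
  tree$n_nodes <- 0L
  tree$n_explored <- 0L
  tree$n_requests <- 0L
  tree$last_explored <- NULL
  root <- new_node(tree, parent = NULL, depth = 0L, rank = 1L)
  root$m <- m_value(settings, group$n)
  root$cands <- generate_root_grid(group, settings)
  tree$root <- root
  tree$current <- NULL
  visit_node(tree, root)
  tree
}

visit_node <- function(tree, node) {
  tree$visit_n <- tree$visit_n + 1L
  node$visit <- tree$visit_n
  tree$visit_log <- c(tree$visit_log, node$id)
  node$status <- "exploring"
  if (is.null(node$cands)) {
    node$cands <- generate_child_points(
      list(axis = node$axis, lower = node$lower, upper = node$upper,
           anchor = node$anchor),
      node$m)
  }
  tree$current <- node
  invisible(node)
}

unexplored_indices <- function(node) {
  which(vapply(node$cands, function(p) p$status == "unexplored", logical(1)))
}

# Record one replicate for candidate `i` of the current node; the candidate
# becomes explored (averaged values stored) once all replicates arrived.
gs_submit_replicate <- function(tree, i, replicate, values) {
  node <- tree$current
  if (is.null(node) || i < 1L || i > length(node$cands)) {
    stop("result submitted for an unknown candidate")
  }
  cand <- node$cands[[i]]
  if (cand$status == "explored") {
    stop("result submitted for an already explored candidate")
  }
  mets <- names(tree$group$metrics)
  if (!all(mets %in% names(values))) {
    stop("result is missing metric(s): ",
         paste(setdiff(mets, names(values)), collapse = ", "))
  }
  cand$reps[[as.character(replicate)]] <- values[mets]
  tree$n_requests <- tree$n_requests + 1L
  if (length(cand$reps) >= tree$settings$replicates) {
    cand$avg <- average_replicates(cand$reps)
    cand$status <- "explored"
    tree$n_explored <- tree$n_explored + 1L
    tree$last_explored <- cand$coords
  }
  node$cands[[i]] <- cand
  invisible(tree)
}

# Advance the DFS as far as the available results allow: expand fully
# explored nodes, descend into prioritized children, backtrack on failure.
gs_advance <- function(tree) {
  repeat {
    node <- tree$current
    if (is.null(node)) break
    if (length(unexplored_indices(node)) > 0L) break
    out <- expand_node(node, tree$group, tree$settings)
    if (out$outcome == "success") {
      node$status <- "success"
      tree$status <- "success"
      tree$solution <- list(
        coords = out$solution$coords,
        values = out$solution$avg,
        depth = node$depth,
        node_id = node$id
      )
      tree$current <- NULL
      break
    }
    if (out$outcome == "max-depth") {
      node$status <- "failed-max-depth"
      gs_backtrack(tree)
      next
    }
    if (out$outcome == "no-ranges") {
      node$status <- "failed-no-ranges"
      gs_backtrack(tree)
      next
    }
    # children: create in priority order and descend into the first
    node$children <- lapply(seq_along(out$ranges), function(r) {
      rng <- out$ranges[[r]]
      child <- new_node(
        tree, parent = node, depth = node$depth + 1L, rank = r,
        axis = rng$axis, lower = rng$lower, upper = rng$upper,
        anchor = rng$anchor,
        inherited = list(
          list(pos = rng$lower, values = rng$endpoint_values$lower),
          list(pos = rng$upper, values = rng$endpoint_values$upper)
        ),
        score = rng$score)
      child$m <- m_value(tree$settings, 1L)
      child
    })
    node$status <- "expanded"
    visit_node(tree, node$children[[1L]])
  }
  invisible(tree)
}

gs_backtrack <- function(tree) {
  node <- tree$current
  nxt <- NULL
  repeat {
    parent <- node$parent
    if (is.null(parent)) break
    sibs <- parent$children
    pending <- Filter(function(s) s$status == "pending" && s$rank > node$rank,
                      sibs)
    if (length(pending)) {
      nxt <- pending[[1L]]
      break
    }
    parent$status <- "exhausted" # every child subtree failed
    node <- parent
  }
  if (is.null(nxt)) {
    tree$status <- "failure"
    tree$current <- NULL
  } else {
    visit_node(tree, nxt)
  }
  invisible(tree)
}

#' Run the full DFS for one group against an evaluator
#'
#' Drives the complete search of a single group: root grid exploration,
#' feasible-range detection, prioritized depth-first refinement with
#' backtracking, and termination at the first solution or when all nodes are
#' visited.  Every candidate point is evaluated `settings$replicates` times
#' with random streams derived from
#' `(seed, group key, node id, candidate id, replicate)`, so the resulting
#' tree is bit-identical whether the group is run alone or co-scheduled with
#' other groups (see [run_optimization()]).
#'
#' @param group a `stop_group`.
#' @param evaluator `function(params, stream)` returning named metric
#'   values for one replicate; see [synthetic_evaluator()],
#'   [external_evaluator()].
#' @param settings a [search_settings()].
#' @return the search tree, an environment of class `dfs_tree`: `status`
#'   (`"success"` or `"failure"`), `solution` (coords, averaged values,
#'   depth, node id), `root`, `visit_log`, and evaluation counters.
#' @export
#' @examples
#' g <- partition_groups(landscape_problem(worked_example("fig6a")))[[1]]
#' tr <- run_group_search(g, synthetic_evaluator(worked_example("fig6a"), 0),
#'                        search_settings(m = 3, seed = 1))
#' tr$solution$coords  # x = -0.625
run_group_search <- function(group, evaluator, settings) {
  tree <- new_group_search(group, settings)
  key <- group_stream_key(group)
  while (tree$status == "running") {
    node <- tree$current
    for (i in unexplored_indices(node)) {
      cand <- node$cands[[i]]
      for (r in seq_len(settings$replicates)) {
        s <- stream_seed(settings$seed, key, node$id, cand$id, r)
        vals <- evaluator(cand$coords, s)
        gs_submit_replicate(tree, i, r, vals)
      }
    }
    gs_advance(tree)
  }
  tree
}

#' Solution of a finished group search
#'
#' @param tree a `dfs_tree` from [run_group_search()].
#' @return list with `coords`, `values`, `depth` and `node_id`, or `NULL`
#'   when the search failed.
#' @export
tree_solution <- function(tree) tree$solution

#' @export
print.dfs_tree <- function(x, ...) {
  cat(sprintf("<dfs_tree> status: %s | nodes: %d | visited: %d | candidate evaluations: %d\n",
              x$status, x$n_nodes, x$visit_n, x$n_requests))
  if (!is.null(x$solution)) {
    cat(sprintf("  solution at depth %d (node %s): %s\n",
                x$solution$depth, x$solution$node_id,
                paste(sprintf("%s = %.6g", names(x$solution$coords),
                              x$solution$coords), collapse = ", ")))
  }
  invisible(x)
}
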