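# Optimization report: construction, JSON/DOT/CSV serialization.
# Timestamps are deliberately excluded from the canonical report (they live
# only in the run log) so that identical config + seed yields byte-identical
# report files.

build_report <- function(problem, states, settings, block_log, n_requests) {
  groups <- stats::setNames(lapply(states, function(s) {
    tree <- s$tree
    list(
      parameters = names(s$group$parameters),
      metrics = names(s$group$metrics),
      status = s$status,
      solution = if (s$status == "completed-success") {
        list(coords = as.list(tree$solution$coords),
             values = as.list(tree$solution$values),
             depth = tree$solution$depth,
             node_id = tree$solution$node_id)
      },
      fixed_values = as.list(s$fixed),
      evaluations = tree$n_requests,
      nodes = tree$n_nodes,
      visited = tree$visit_n,
      visit_log = tree$visit_log,
      tree = node_as_list(tree$root)
    )
  }), vapply(states, `[[`, character(1), "label"))
  structure(
    list(
      groups = groups,
      totals = list(
        blocks = if (is.null(block_log)) 0L else nrow(block_log),
        requests = n_requests,
        candidate_points = sum(vapply(states, function(s)
          s$tree$n_explored, integer(1)))
      ),
      settings = list(
        max_depth = settings$max_depth, replicates = settings$replicates,
        max_processes = settings$max_processes, seed = settings$seed,
        m = if (identical(settings$m, "auto")) "auto"
            else as.list(settings$m)
      ),
      block_log = block_log
    ),
    class = "optimization_report"
  )
}

node_as_list <- function(node) {
  list(
    id = node$id,
    depth = node$depth,
    status = node$status,
    visit = node$visit,
    axis = node$axis,
    lower = node$lower,
    upper = node$upper,
    anchor = as.list(node$anchor),
    score = node$score,
    candidates = lapply(node$cands %||% list(), function(p) {
      list(id = p$id, coords = as.list(p$coords), status = p$status,
           n_replicates = length(p$reps),
           mean_values = as.list(p$avg))
    }),
    children = lapply(node$children, node_as_list)
  )
}

#' Export a DFS tree as a DOT graph description
#'
#' Visited nodes are drawn green and numbered in visit order; nodes created
#' but never visited are black.
#'
#' @param tree a `dfs_tree` environment or a tree list from a report.
#' @return a single character string in DOT syntax.
#' @export
tree_to_dot <- function(tree) {
  root <- if (inherits(tree, "dfs_tree")) node_as_list(tree$root) else tree
  lines <- c("digraph dfs_tree {", "  node [shape=circle];")
  walk <- function(nd) {
    visited <- !is.na(nd$visit) && !is.null(nd$visit)
    label <- if (visited) {
      sprintf("%s\\n#%d %s", nd$id, nd$visit, nd$status)
    } else {
      sprintf("%s\\nunvisited", nd$id)
    }
    color <- if (visited) "green" else "black"
    lines <<- c(lines, sprintf("  \"%s\" [label=\"%s\", color=%s];",
                               nd$id, label, color))
    for (ch in nd$children) {
      lines <<- c(lines, sprintf("  \"%s\" -> \"%s\";", nd$id, ch$id))
      walk(ch)
    }
  }
  walk(root)
  paste(c(lines, "}"), collapse = "\n")
}

# Flatten a tree's candidate points into one table.
tree_candidate_table <- function(root, group_label) {
  rows <- list()
  walk <- function(nd) {
    for (p in nd$candidates) {
      row <- data.frame(group = group_label, node_id = nd$id,
                        depth = nd$depth, candidate = p$id,
                        status = p$status, n_replicates = p$n_replicates,
                        stringsAsFactors = FALSE)
      for (cn in names(p$coords)) row[[cn]] <- p$coords[[cn]]
      for (mn in names(p$mean_values)) {
        row[[paste0("mean_", mn)]] <- p$mean_values[[mn]]
      }
      rows[[length(rows) + 1L]] <<- row
    }
    for (ch in nd$children) walk(ch)
  }
  walk(root)
  if (length(rows) == 0) return(NULL)
  all_cols <- unique(unlist(lapply(rows, names)))
  do.call(rbind, lapply(rows, function(r) {
    for (cn in setdiff(all_cols, names(r))) r[[cn]] <- NA
    r[all_cols]
  }))
}

#' Write an optimization report to disk
#'
#' Writes `report.json` (statuses, solutions, evaluation counts, trees),
#' one `tree_<group>.json` and `tree_<group>.dot` per group, a
#' `candidates_<group>.csv` table per group, and `run.log`.  All numeric
#' fields are serialized at full precision, so re-loading the report JSON
#' round-trips them exactly.
#'
#' @param report an `optimization_report` from [run_optimization()].
#' @param outdir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  paths <- character(0)
  fp <- file.path(outdir, "report.json")
  jsonlite::write_json(unclass(report), fp, auto_unbox = TRUE,
                       digits = I(17),
                       pretty = TRUE, null = "null", dataframe = "columns")
  paths <- c(paths, fp)
  for (lab in names(report$groups)) {
    g <- report$groups[[lab]]
    safe <- gsub("[^A-Za-z0-9_.-]", "_", lab)
    tp <- file.path(outdir, paste0("tree_", safe, ".json"))
    jsonlite::write_json(g$tree, tp, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE, null = "null")
    dp <- file.path(outdir, paste0("tree_", safe, ".dot"))
    writeLines(tree_to_dot(g$tree), dp)
    tab <- tree_candidate_table(g$tree, lab)
    cp <- file.path(outdir, paste0("candidates_", safe, ".csv"))
    if (!is.null(tab)) utils::write.csv(tab, cp, row.names = FALSE)
    paths <- c(paths, tp, dp, cp)
  }
  lg <- file.path(outdir, "run.log")
  log_lines <- c(sprintf("run completed at %s",
                         format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  if (!is.null(report$block_log)) {
    log_lines <- c(log_lines, sprintf(
      "block %d: size %d, %d requests, groups [%s], nodes [%s]",
      report$block_log$block, report$block_log$size,
      report$block_log$n_requests, report$block_log$groups,
      report$block_log$nodes))
  }
  for (lab in names(report$groups)) {
    g <- report$groups[[lab]]
    log_lines <- c(log_lines, sprintf(
      "group [%s]: %s after %d evaluations; visit order: %s",
      lab, g$status, g$evaluations, paste(g$visit_log, collapse = " -> ")))
  }
  writeLines(log_lines, lg)
  invisible(c(paths, lg))
}

#' Re-load a report written by [write_report()]
#'
#' @param path path to a `report.json` (or the directory containing it).
#' @return the report as nested lists, numeric fields intact.
#' @export
read_report <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "report.json")
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE,
                      simplifyMatrix = FALSE)
}

#' @export
print.optimization_report <- function(x, ...) {
  cat(sprintf("<optimization_report> %d group(s), %d block(s), %d request(s)\n",
              length(x$groups), x$totals$blocks, x$totals$requests))
  for (lab in names(x$groups)) {
    g <- x$groups[[lab]]
    if (g$status == "completed-success") {
      cat(sprintf("  [%s] success at depth %d: %s\n", lab,
                  g$solution$depth,
                  paste(sprintf("%s = %.6g", names(g$solution$coords),
                                unlist(g$solution$coords)),
                        collapse = ", ")))
    } else {
      cat(sprintf("  [%s] %s (fixed at %s)\n", lab, g$status,
                  paste(sprintf("%s = %.6g", names(g$fixed_values),
                                unlist(g$fixed_values)),
                        collapse = ", ")))
    }
  }
  invisible(x)
}
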