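# Block scheduler: co-optimizes all groups, assembling parallel blocks of
# full-parameter-vector evaluations and updating group states after each
# block.
#
# Every evaluation of the black box requires a value for EVERY parameter of
# the problem, so one "slot" of a block pairs one unexplored candidate from
# each active group with the fixed values of the completed groups.  The
# number of slots is the minimum unexplored-candidate count over active
# groups; each slot expands into `replicates` requests.

new_group_state <- function(group, settings) {
  state <- new.env(parent = emptyenv())
  class(state) <- "group_state"
  state$group <- group
  state$label <- paste(names(group$parameters), collapse = "+")
  state$key <- group_stream_key(group)
  state$tree <- new_group_search(group, settings)
  state$status <- "active"
  state$fixed <- NULL
  state
}

state_t <- function(state) {
  if (state$status != "active") return(0L)
  length(unexplored_indices(state$tree$current))
}

#' Assemble the next parallel block of evaluation requests
#'
#' Block size `b` is the minimum over active groups of the number of
#' unexplored candidate points in their current nodes (completed groups are
#' removed from the calculation and contribute their fixed parameter
#' values).  Slot `i` pairs the `i`-th unexplored candidate of each active
#' group into one full parameter vector; each slot expands into `replicates`
#' requests with distinct replicate indices and derived random streams.
#'
#' @param states list of group states from [run_optimization()]'s loop.
#' @param replicates replicates per candidate point.
#' @return an object of class `stop_block`: `size` (slot count `b`) and
#'   `requests`, each with `params` (full named vector), `replicate`,
#'   `provenance` (group label -> candidate identity) and `streams` (one
#'   derived stream per metric).
#' @export
assemble_block <- function(states, replicates) {
  active <- Filter(function(s) s$status == "active", states)
  if (length(active) == 0L) stop("no active group to schedule")
  ts <- vapply(active, state_t, integer(1))
  b <- min(ts)
  stopifnot(b >= 1L)
  requests <- list()
  for (slot in seq_len(b)) {
    params <- numeric(0)
    prov <- list()
    slot_info <- list()
    for (s in states) {
      if (s$status == "active") {
        node <- s$tree$current
        i <- unexplored_indices(node)[slot]
        cand <- node$cands[[i]]
        params <- c(params, cand$coords)
        prov[[s$label]] <- list(cand_index = i, cand_id = cand$id,
                                node_id = node$id)
        slot_info[[s$label]] <- list(node_id = node$id, cand_id = cand$id,
                                     metrics = names(s$group$metrics),
                                     seed = s$tree$settings$seed, key = s$key)
      } else {
        params <- c(params, s$fixed)
      }
    }
    for (r in seq_len(replicates)) {
      streams <- integer(0)
      for (s in states) {
        if (s$status == "active") {
          info <- slot_info[[s$label]]
          base <- stream_seed(info$seed, info$key, info$node_id,
                              info$cand_id, r)
        } else {
          base <- stream_seed(s$tree$settings$seed, s$key, "fixed", r)
        }
        ms <- names(s$group$metrics)
        streams <- c(streams, stats::setNames(rep(base, length(ms)), ms))
      }
      requests[[length(requests) + 1L]] <- list(
        params = params, replicate = r, provenance = prov, streams = streams)
    }
  }
  structure(list(size = b, requests = requests), class = "stop_block")
}

#' Dispatch a block of requests to an evaluator
#'
#' Evaluates every request, never exceeding `max_processes` concurrent
#' evaluations (forked workers via the parallel package when
#' `max_processes > 1` on Unix).  Because each request carries its own
#' derived random streams, results are independent of execution order.  A
#' failed evaluation is retried once; a second failure aborts with a
#' diagnostic naming the request.
#'
#' @param block a `stop_block` from [assemble_block()].
#' @param evaluator `function(params, streams)` returning named metric
#'   values.
#' @param max_processes maximum concurrency.
#' @return list of named numeric vectors, one per request, in request order.
#' @export
dispatch_block <- function(block, evaluator, max_processes = 1) {
  run_one <- function(req) {
    tryCatch(list(ok = TRUE, value = evaluator(req$params, req$streams)),
             error = function(e) list(ok = FALSE, err = conditionMessage(e)))
  }
  raw <- if (max_processes > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(block$requests, run_one, mc.cores = max_processes)
  } else {
    lapply(block$requests, run_one)
  }
  lapply(seq_along(raw), function(i) {
    res <- raw[[i]]
    if (!isTRUE(res$ok)) {
      res <- run_one(block$requests[[i]]) # retry once
    }
    if (!isTRUE(res$ok)) {
      req <- block$requests[[i]]
      stop(sprintf(
        "evaluation failed twice for request %d (replicate %d; groups %s): %s",
        i, req$replicate, paste(names(req$provenance), collapse = ", "),
        res$err))
    }
    res$value
  })
}

#' Apply a block's results to one group's state
#'
#' Replicate values are accumulated per candidate; a candidate becomes
#' explored once all replicates arrived (its averaged values are stored).
#' When the current node has no unexplored candidates left, the DFS advances
#' (expansion, descent, backtracking) and the group either continues or
#' completes: on success its parameters are fixed at the solution point, on
#' failure at the last candidate point explored.
#'
#' @param state a group state.
#' @param results list of `list(cand_index, cand_id, replicate, values)` for
#'   this group's candidates in the current node.
#' @return the state, invisibly (modified in place).
#' @export
update_group_state <- function(state, results) {
  tree <- state$tree
  for (res in results) {
    node <- tree$current
    i <- res$cand_index
    if (is.null(node) || i < 1L || i > length(node$cands) ||
        node$cands[[i]]$id != res$cand_id) {
      stop("result refers to an unknown candidate (", res$cand_id, ")")
    }
    gs_submit_replicate(tree, i, res$replicate, res$values)
  }
  if (state$status == "active" &&
      length(unexplored_indices(tree$current)) == 0L) {
    gs_advance(tree)
    if (tree$status == "success") {
      state$status <- "completed-success"
      state$fixed <- tree$solution$coords
    } else if (tree$status == "failure") {
      state$status <- "completed-failure"
      state$fixed <- tree$last_explored
    }
  }
  invisible(state)
}

#' Optimize all groups of a problem simultaneously
#'
#' The top-level loop: partitions the problem into independently optimizable
#' groups, then repeats assemble -> dispatch -> update until every group
#' completes.  Fully reproducible given `settings$seed`: per-candidate
#' streams depend only on the group's parameter names, node id, candidate
#' id and replicate index, so each group's DFS tree is identical to running
#' that group alone.
#'
#' @param problem a valid [stop_problem()].
#' @param evaluator `function(params, streams)` returning one replicate's
#'   named metric values for a full parameter vector.
#' @param settings a [search_settings()].
#' @return an `optimization_report`: per-group outcome (solution vector or
#'   failure with last explored point), DFS trees, evaluation totals and the
#'   per-block log.
#' @export
#' @examples
#' prob <- landscape_problem(worked_example("fig6a"))
#' ev <- synthetic_evaluator(worked_example("fig6a"), noise_sd = 0)
#' rep <- run_optimization(prob, ev, search_settings(m = 3, seed = 1))
#' rep$groups$x$status  # "completed-success"
run_optimization <- function(problem, evaluator, settings) {
  viol <- validate_problem(problem)
  if (length(viol)) {
    stop("invalid problem:\n", paste("-", viol, collapse = "\n"))
  }
  groups <- partition_groups(problem)
  check_recommended_m(settings, vapply(groups, `[[`, integer(1), "n"))
  states <- lapply(groups, new_group_state, settings = settings)
  block_log <- list()
  n_requests <- 0L
  while (any(vapply(states, function(s) s$status == "active", logical(1)))) {
    block <- assemble_block(states, settings$replicates)
    values <- dispatch_block(block, evaluator, settings$max_processes)
    per_state <- stats::setNames(vector("list", length(states)),
                                 vapply(states, `[[`, character(1), "label"))
    for (i in seq_along(block$requests)) {
      req <- block$requests[[i]]
      for (lab in names(req$provenance)) {
        pr <- req$provenance[[lab]]
        per_state[[lab]] <- c(per_state[[lab]], list(list(
          cand_index = pr$cand_index, cand_id = pr$cand_id,
          replicate = req$replicate, values = values[[i]])))
      }
    }
    involved <- character(0)
    for (s in states) {
      res <- per_state[[s$label]]
      if (!is.null(res)) {
        involved <- c(involved, s$label)
        update_group_state(s, res)
      }
    }
    n_requests <- n_requests + length(block$requests)
    block_log[[length(block_log) + 1L]] <- data.frame(
      block = length(block_log) + 1L,
      size = block$size,
      n_requests = length(block$requests),
      groups = paste(involved, collapse = ";"),
      nodes = paste(vapply(block$requests[[1]]$provenance, `[[`,
                           character(1), "node_id"), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  build_report(problem, states, settings,
               block_log = do.call(rbind, block_log),
               n_requests = n_requests)
}
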