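# Block assembly, dispatch, group-state updates, and co-scheduled
# optimization with the group-independence contract.

# A 2-group problem: one tunable group (quadratic peak, like the 1-D worked
# example) and one hopeless group (target beyond reach), with distinct
# parameter names so both appear in every full vector.
combo_problem <- function() {
  stop_problem(
    parameters = list(stop_parameter("xa", -1, 1),
                      stop_parameter("xd", -1, 1)),
    metrics = list(stop_metric("ma", 0.6, 0.68),
                   stop_metric("md", 0.85, 0.95)),
    dependencies = list(xa = "ma", xd = "md")
  )
}

combo_landscape <- function() {
  make_landscape(
    metrics = list(ma = function(x) 1 - x[["xa"]]^2,
                   md = function(x) 1 - (x[["xd"]] - 0.5)^2),
    domains = list(xa = c(-1, 1), xd = c(-1, 1)),
    targets = list(ma = c(0.6, 0.68), md = c(0.85, 0.95)),
    name = "combo")
}

test_that("block size is the minimum unexplored count over active groups", {
  # group dims 2 and 1 with m = 2: root candidate counts 4 and 2
  prob <- stop_problem(
    parameters = list(stop_parameter("a1", 0, 1), stop_parameter("a2", 0, 1),
                      stop_parameter("b", 0, 1)),
    metrics = list(stop_metric("fa", 0.2, 0.8), stop_metric("fb", 0.2, 0.8)),
    dependencies = list(a1 = "fa", a2 = "fa", b = "fb")
  )
  groups <- partition_groups(prob)
  settings <- search_settings(m = 2, seed = 1)
  states <- lapply(groups, stopt:::new_group_state, settings = settings)
  expect_equal(sort(vapply(states, stopt:::state_t, integer(1))), c(2L, 4L))
  blk <- assemble_block(states, replicates = 1)
  expect_equal(blk$size, 2L)
  expect_length(blk$requests, 2)
  # every request carries the full parameter vector
  expect_setequal(names(blk$requests[[1]]$params), c("a1", "a2", "b"))

  blk2 <- assemble_block(states, replicates = 2)
  expect_equal(blk2$size, 2L)
  expect_length(blk2$requests, 4) # 2 slots x 2 replicates
  expect_equal(vapply(blk2$requests, `[[`, integer(1), "replicate"),
               c(1L, 2L, 1L, 2L))
})

test_that("completed groups contribute fixed values to every request", {
  groups <- partition_groups(combo_problem())
  settings <- search_settings(m = 3, seed = 1)
  states <- lapply(groups, stopt:::new_group_state, settings = settings)
  done <- states[[2]] # the xd group
  done$status <- "completed-failure"
  done$fixed <- c(xd = 0.25)
  blk <- assemble_block(states, replicates = 1)
  expect_equal(blk$size, 3L) # only xa active, t = 3
  for (req in blk$requests) {
    expect_equal(req$params[["xd"]], 0.25)
    expect_false("xd" %in% names(req$provenance))
  }
  # no active group at all is an error
  states[[1]]$status <- "completed-success"
  states[[1]]$fixed <- c(xa = 0)
  expect_error(assemble_block(states, 1), "no active group")
})

test_that("dispatch retries a failed evaluation once, then aborts", {
  groups <- partition_groups(combo_problem())
  states <- lapply(groups, stopt:::new_group_state,
                   settings = search_settings(m = 3, seed = 1))
  blk <- assemble_block(states, replicates = 1)

  flaky_counter <- new.env()
  flaky_counter$n <- 0L
  flaky <- function(params, stream = NULL) {
    flaky_counter$n <- flaky_counter$n + 1L
    if (flaky_counter$n == 2L) stop("transient backend glitch")
    evaluate_synthetic(params, combo_landscape())
  }
  vals <- dispatch_block(blk, flaky, max_processes = 1)
  expect_length(vals, 3)
  expect_true(all(vapply(vals, function(v) all(is.finite(v)), logical(1))))

  always_fails <- function(params, stream = NULL) stop("backend down")
  expect_error(dispatch_block(blk, always_fails, 1),
               "failed twice for request 1")
})

test_that("state updates count replicates and finish nodes when t hits 0", {
  ls <- worked_example("fig6a")
  g <- single_group(ls)
  settings <- search_settings(m = 3, replicates = 2, seed = 1)
  state <- stopt:::new_group_state(g, settings)
  expect_equal(stopt:::state_t(state), 3L)
  node <- state$tree$current
  ev <- synthetic_evaluator(ls, 0)
  res_one <- lapply(1:2, function(r) {
    list(cand_index = 1L, cand_id = node$cands[[1]]$id, replicate = r,
         values = ev(node$cands[[1]]$coords))
  })
  update_group_state(state, res_one)
  expect_equal(stopt:::state_t(state), 2L) # one candidate fully explored
  expect_equal(state$status, "active")
  # unknown candidate id is rejected
  expect_error(
    update_group_state(state, list(list(cand_index = 2L, cand_id = "nope",
                                        replicate = 1, values = c(metric1 = 0)))),
    "unknown candidate")
})

test_that("co-scheduled optimization reproduces isolated group searches", {
  prob <- combo_problem()
  land <- combo_landscape()
  settings <- search_settings(m = 3, replicates = 10, seed = 7)
  rep <- run_optimization(prob, synthetic_evaluator(land, 0.05), settings)

  expect_equal(rep$groups$xa$status, "completed-success")
  expect_equal(rep$groups$xd$status, "completed-failure")
  # failure group fixed at its last explored candidate
  expect_equal(names(rep$groups$xd$fixed_values), "xd")

  # independence contract: identical tree when the xa group runs alone
  la <- make_landscape(list(ma = land$metrics$ma),
                       domains = list(xa = c(-1, 1)),
                       targets = list(ma = c(0.6, 0.68)), name = "a-alone")
  ga <- single_group(la)
  tra <- run_group_search(ga, synthetic_evaluator(la, 0.05), settings)
  expect_identical(stopt:::node_as_list(tra$root), rep$groups$xa$tree)
  expect_identical(tra$visit_log, rep$groups$xa$visit_log)

  # block-size law from the log: co-scheduled first block, then xa alone
  expect_equal(rep$block_log$size[1], 3)
  expect_true(all(rep$block_log$n_requests ==
                    rep$block_log$size * settings$replicates))

  # conservation: each group consumed exactly (its candidates x replicates)
  # evaluations, and every explored candidate received every replicate
  count_cands <- function(nd) {
    length(nd$candidates) + sum(vapply(nd$children, count_cands, numeric(1)))
  }
  for (lab in names(rep$groups)) {
    g <- rep$groups[[lab]]
    expect_equal(g$evaluations, count_cands(g$tree) * settings$replicates)
    check_reps <- function(nd) {
      for (p in nd$candidates) {
        if (p$status == "explored") {
          expect_equal(p$n_replicates, settings$replicates)
        }
      }
      for (ch in nd$children) check_reps(ch)
    }
    check_reps(g$tree)
  }
  # one request can serve several groups, so the request total is bounded by
  # the per-group sum and by the block log
  expect_lte(rep$totals$requests,
             sum(vapply(names(rep$groups),
                        function(l) rep$groups[[l]]$evaluations, numeric(1))))
  expect_equal(rep$totals$requests, sum(rep$block_log$n_requests))
})

test_that("results are independent of dispatch concurrency", {
  prob <- combo_problem()
  land <- combo_landscape()
  ev <- synthetic_evaluator(land, 0.05)
  r1 <- run_optimization(prob, ev, search_settings(m = 3, replicates = 4,
                                                   seed = 3))
  r2 <- run_optimization(prob, ev, search_settings(m = 3, replicates = 4,
                                                   seed = 3,
                                                   max_processes = 3))
  r1$settings$max_processes <- r2$settings$max_processes
  expect_identical(r1, r2)
})

test_that("an invalid problem is rejected before any evaluation", {
  bad <- stop_problem(list(stop_parameter("x", 1, 1)),
                      list(stop_metric("f", 0, 1)), list(x = "f"))
  expect_error(run_optimization(bad, function(p, s) c(f = 0),
                                search_settings(m = 3)),
               "invalid problem")
})
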