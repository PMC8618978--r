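# Full single-group DFS: worked-example traces, backtracking, depth cap,
# traversal discipline and termination bounds.

noiseless <- function(name) synthetic_evaluator(worked_example(name), 0)

test_that("the 1-parameter/1-metric search follows the analytic trace", {
  g <- single_group(worked_example("fig6a"))
  tr <- run_group_search(g, noiseless("fig6a"),
                         search_settings(m = 3, seed = 1))
  expect_equal(tr$status, "success")
  expect_identical(tr$visit_log, c("0", "0.1", "0.1.1"))
  d1 <- tr$root$children[[1]]
  expect_equal(c(d1$lower, d1$upper), c(-1, 0))
  d2 <- d1$children[[1]]
  expect_equal(c(d2$lower, d2$upper), c(-0.75, -0.5))
  expect_equal(tr$solution$depth, 2)
  expect_equal(tr$solution$coords[["x"]], -0.625)
  expect_equal(tr$solution$values[["metric1"]], 0.609375)
})

test_that("multi-metric search backtracks out of a non-overlapping branch", {
  g <- single_group(worked_example("fig6b"))
  tr <- run_group_search(g, noiseless("fig6b"),
                         search_settings(m = 3, seed = 1))
  expect_equal(tr$status, "success")
  # both common ranges at the root
  kids <- tr$root$children
  expect_length(kids, 2)
  expect_equal(c(kids[[1]]$lower, kids[[1]]$upper), c(-1, 0))
  expect_equal(c(kids[[2]]$lower, kids[[2]]$upper), c(0, 1))
  # [-1, 0] branch dies at depth 1: per-metric brackets do not coincide
  expect_equal(kids[[1]]$status, "failed-no-ranges")
  # sibling opened only after the first subtree resolved
  expect_identical(tr$visit_log, c("0", "0.1", "0.2", "0.2.1", "0.2.1.1"))
  expect_lte(tr$solution$depth, 3)
  x <- tr$solution$coords[["x"]]
  expect_equal(x, 0.59375)
  expect_equal(tr$solution$values[["metric1"]], 1 - x^2)
  expect_equal(tr$solution$values[["metric2"]],
               1 - x^3 - 1.2 * x^2 + 0.5 * x)
})

test_that("a target near the maximum between grid points fails at the root", {
  g <- single_group(worked_example("fig6d"))
  tr <- run_group_search(g, noiseless("fig6d"),
                         search_settings(m = 3, seed = 1))
  expect_equal(tr$status, "failure")
  expect_equal(tr$visit_n, 1L)
  expect_equal(tr$root$status, "failed-no-ranges")
  expect_false(is.null(tr$last_explored))
})

test_that("the 2-D root may solve directly on a grid line", {
  g <- single_group(worked_example("fig6c"))
  tr <- run_group_search(g, noiseless("fig6c"),
                         search_settings(m = 3, seed = 1))
  expect_equal(tr$status, "success")
  expect_length(tr$root$children, 4)
  v <- tr$solution$values[["metric1"]]
  expect_true(v >= 0.6 && v <= 0.68)
})

test_that("the depth cap stops refinement and is reported as failure", {
  g <- single_group(worked_example("fig6a"))
  tr <- run_group_search(g, noiseless("fig6a"),
                         search_settings(m = 3, max_depth = 1, seed = 1))
  expect_equal(tr$status, "failure")
  statuses <- vapply(tr$root$children, `[[`, character(1), "status")
  expect_true(any(statuses == "failed-max-depth"))
  depths <- vapply(strsplit(tr$visit_log, ".", fixed = TRUE), length,
                   integer(1)) - 1L
  expect_true(all(depths <= 1))
})

test_that("DFS discipline and termination bounds hold across landscapes", {
  cases <- list(
    list(ls = worked_example("fig6a"), m = 3),
    list(ls = worked_example("fig6b"), m = 3),
    list(ls = linear_landscape(100), m = 4),
    list(ls = linear_landscape(1000), m = 5)
  )
  for (cs in cases) {
    g <- single_group(cs$ls)
    tr <- run_group_search(g, synthetic_evaluator(cs$ls, 0),
                           search_settings(m = cs$m, max_depth = 8,
                                           seed = 1))
    # every visited node's parent was visited before it
    log <- tr$visit_log
    for (id in log[-1]) {
      parent <- sub("\\.[0-9]+$", "", id)
      expect_lt(match(parent, log), match(id, log))
    }
    # siblings open only after the previous subtree is resolved: visit ids
    # never revisit a shallower sibling branch of an unresolved subtree
    expect_false(anyDuplicated(log) > 0)
    # termination: candidate evaluations bounded by m^n + (nodes - 1) * m
    m <- cs$m
    expect_lte(tr$n_explored, m^g$n + (tr$n_nodes - 1) * m)
  }
})

test_that("m-ary level counts respect the worst-case formula (spot check)", {
  for (r in c(10, 100)) {
    for (m in c(3, 5)) {
      ls <- linear_landscape(r)
      tr <- run_group_search(single_group(ls), synthetic_evaluator(ls, 0),
                             search_settings(m = m, max_depth = 12,
                                             seed = 1))
      expect_equal(tr$status, "success")
      expect_lte(tr$solution$depth + 1,
                 ceiling(worst_case_iterations(r, m)))
    }
  }
})
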