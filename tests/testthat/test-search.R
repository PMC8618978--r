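# Candidate grids, feasibility detection, prioritization, node expansion.

test_that("root grids are endpoint-inclusive and complete", {
  ls2 <- make_landscape(
    list(f = function(x) 0),
    domains = list(x1 = c(-1, 1), x2 = c(-1, 1)),
    targets = list(f = c(0, 1)))
  g2 <- single_group(ls2)
  pts <- generate_root_grid(g2, search_settings(m = 3))
  expect_length(pts, 9)
  coords <- t(vapply(pts, function(p) p$coords, numeric(2)))
  expect_setequal(paste(coords[, 1], coords[, 2]),
                  paste(rep(c(-1, 0, 1), 3), rep(c(-1, 0, 1), each = 3)))

  ls1 <- make_landscape(list(f = function(x) 0),
                        domains = list(x = c(0, 1)),
                        targets = list(f = c(0, 1)))
  g1 <- single_group(ls1)
  expect_equal(vapply(generate_root_grid(g1, search_settings(m = 2)),
                      function(p) p$coords[["x"]], numeric(1)),
               c(0, 1))

  ls10 <- make_landscape(list(f = function(x) 0),
                         domains = list(x = c(0, 10)),
                         targets = list(f = c(0, 1)))
  expect_equal(vapply(generate_root_grid(single_group(ls10),
                                         search_settings(m = 5)),
                      function(p) p$coords[["x"]], numeric(1)),
               c(0, 2.5, 5, 7.5, 10))
})

test_that("child points are strictly interior with m+1 sub-intervals", {
  rng <- list(axis = "x", lower = -1, upper = 0,
              anchor = stats::setNames(numeric(0), character(0)))
  pts <- generate_child_points(rng, 3)
  expect_equal(vapply(pts, function(p) p$coords[["x"]], numeric(1)),
               c(-0.75, -0.5, -0.25))

  rng01 <- list(axis = "x", lower = 0, upper = 1, anchor = NULL)
  expect_equal(vapply(generate_child_points(rng01, 2),
                      function(p) p$coords[["x"]], numeric(1)),
               c(1 / 3, 2 / 3))

  deep <- list(axis = "x", lower = -0.75, upper = -0.5, anchor = NULL)
  xs <- vapply(generate_child_points(deep, 3),
               function(p) p$coords[["x"]], numeric(1))
  expect_equal(xs, c(-0.6875, -0.625, -0.5625))
  expect_equal(1 - (-0.625)^2, 0.609375) # the depth-2 solution value

  expect_error(generate_child_points(list(axis = "x", lower = 1, upper = 1,
                                          anchor = NULL), 3),
               "degenerate")
})

test_that("solution testing uses closed target ranges on averaged values", {
  g <- single_group(worked_example("fig6a"))
  cand <- list(coords = c(x = -0.625), avg = c(metric1 = 0.609375),
               status = "explored")
  expect_true(is_solution(cand, g))
  cand$avg <- c(metric1 = 0.6) # boundary counts as inside
  expect_true(is_solution(cand, g))
  cand$avg <- c(metric1 = 0.68)
  expect_true(is_solution(cand, g))
  cand$avg <- c(metric1 = 0.5999999)
  expect_false(is_solution(cand, g))

  gb <- single_group(worked_example("fig6b"))
  two <- list(coords = c(x = 0.625), status = "explored",
              avg = c(metric1 = 0.609375, metric2 = 0.599609375))
  expect_false(is_solution(two, gb)) # metric2 just below the band

  unexp <- list(coords = c(x = 0), avg = NULL, status = "unexplored")
  expect_error(is_solution(unexp, g), "not been explored")
})

test_that("feasible ranges of the worked-example roots match the traces", {
  # 1-D: values {0, 1, 0} at {-1, 0, 1} bracket [0.6, 0.68] on both sides
  er <- explored_root(worked_example("fig6a"), m = 3)
  ranges <- find_feasible_ranges(er$node, er$group)
  expect_length(ranges, 2)
  expect_equal(vapply(ranges, function(r) c(r$lower, r$upper), numeric(2)),
               matrix(c(-1, 0, 0, 1), 2))

  # 2-D: exactly 4 ranges, along grid lines touching the (-1,-1)/(1,1) corners
  erc <- explored_root(worked_example("fig6c"), m = 3)
  rc <- find_feasible_ranges(erc$node, erc$group)
  expect_length(rc, 4)
  desc <- sort(vapply(rc, function(r) {
    sprintf("%s[%g,%g]@%s=%g", r$axis, r$lower, r$upper,
            names(r$anchor), r$anchor)
  }, character(1)))
  expect_identical(desc, sort(c(
    "x1[-1,0]@x2=-1", "x2[-1,0]@x1=-1", "x1[0,1]@x2=1", "x2[0,1]@x1=1")))

  # failure case: endpoint values never reach the [0.85, 0.95] band
  erd <- explored_root(worked_example("fig6d"), m = 3)
  expect_length(find_feasible_ranges(erd$node, erd$group), 0)

  # unexplored points are an error
  ls <- make_landscape(list(f = function(x) x[["x"]]),
                       domains = list(x = c(0, 1)),
                       targets = list(f = c(0.4, 0.5)))
  g <- single_group(ls)
  tree <- stopt:::new_group_search(g, search_settings(m = 3, seed = 1))
  expect_error(find_feasible_ranges(tree$current, g), "explored")
})

test_that("range detection matches the brute-force adjacent-pair oracle", {
  set.seed(42)
  for (case in 1:12) {
    nd <- sample(1:2, 1)
    m <- sample(3:5, 1)
    co <- stats::rnorm(6) # random polynomial landscape
    f <- if (nd == 1) {
      function(x) co[1] + co[2] * x[["x1"]] + co[3] * x[["x1"]]^2 +
        co[4] * x[["x1"]]^3
    } else {
      function(x) co[1] + co[2] * x[["x1"]] + co[3] * x[["x2"]] +
        co[4] * x[["x1"]] * x[["x2"]] + co[5] * x[["x1"]]^2 +
        co[6] * x[["x2"]]^2
    }
    tl <- sort(stats::rnorm(2, sd = 0.8))
    doms <- stats::setNames(rep(list(c(-1, 1)), nd), paste0("x", seq_len(nd)))
    ls <- make_landscape(list(f = f), domains = doms,
                         targets = list(f = c(tl[1], tl[2])))
    er <- explored_root(ls, m = m)
    ranges <- find_feasible_ranges(er$node, er$group)
    got <- sort(vapply(ranges, range_key, character(1),
                       group = er$group, node = er$node))
    expect_identical(got, feasible_pairs_oracle(er$node, er$group),
                     label = sprintf("case %d (n=%d, m=%d)", case, nd, m))
  }
})

test_that("prioritization scores ranges by interpolated target coverage", {
  # single range comes back unchanged
  er1 <- explored_root(linear_landscape(10), m = 3)
  r1 <- find_feasible_ranges(er1$node, er1$group)
  expect_length(r1, 1)
  pr1 <- prioritize_ranges(er1$node, r1, er1$group, er1$settings)
  expect_equal(pr1[[1]]$lower, r1[[1]]$lower)

  # symmetric landscape: equal scores, discovery order preserved
  era <- explored_root(worked_example("fig6a"), m = 3)
  ra <- find_feasible_ranges(era$node, era$group)
  pra <- prioritize_ranges(era$node, ra, era$group, era$settings)
  expect_equal(pra[[1]]$score, pra[[2]]$score)
  expect_equal(c(pra[[1]]$lower, pra[[1]]$upper), c(-1, 0))

  # asymmetric construction: scores match a direct spline evaluation oracle
  ls <- make_landscape(
    list(f = function(x) 1 - 0.8 * (x[["x"]] - 0.2)^2),
    domains = list(x = c(-1, 1)), targets = list(f = c(0.9, 1.0)))
  er <- explored_root(ls, m = 5)
  rr <- find_feasible_ranges(er$node, er$group)
  expect_gte(length(rr), 2)
  pr <- prioritize_ranges(er$node, rr, er$group, er$settings)
  oracle_score <- function(range) {
    fit <- stats::splinefun(range$support_pos, range$support_values[, "f"],
                            method = "fmm")
    q <- seq(range$lower, range$upper, length.out = 100)
    mean(fit(q) >= 0.9 & fit(q) <= 1.0)
  }
  for (r in pr) expect_equal(r$score, oracle_score(r))
  scores <- vapply(pr, `[[`, numeric(1), "score")
  expect_true(all(diff(scores) <= 0)) # descending
})

test_that("node expansion resolves success, depth cap and dead ends", {
  era <- explored_root(worked_example("fig6a"), m = 3)
  out <- expand_node(era$node, era$group, era$settings)
  expect_equal(out$outcome, "children")
  expect_length(out$ranges, 2)

  erd <- explored_root(worked_example("fig6d"), m = 3)
  expect_equal(expand_node(erd$node, erd$group, erd$settings)$outcome,
               "no-ranges")

  # depth cap: same explored node at max_depth reports max-depth
  era$node$depth <- 5L
  expect_equal(expand_node(era$node, era$group, era$settings)$outcome,
               "max-depth")
  era$node$depth <- 0L

  # a grid point inside the band is an immediate success
  ls <- make_landscape(list(f = function(x) x[["x"]]),
                       domains = list(x = c(0, 1)),
                       targets = list(f = c(0.45, 0.55)))
  er <- explored_root(ls, m = 3) # grid {0, 0.5, 1}; f(0.5) in band
  out <- expand_node(er$node, er$group, er$settings)
  expect_equal(out$outcome, "success")
  expect_equal(out$solution$coords[["x"]], 0.5)
})
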