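# Candidate-point generation, feasible-range detection, multi-metric
# intersection, and spline-based prioritization.
#
# Candidate placement convention: the root grid INCLUDES the domain endpoints
# (m points, m-1 intervals per axis), while a child node adds m strictly
# interior points and inherits its endpoint values from the parent (m+1
# sub-intervals).  This is the placement consistent with the search-space
# rejection fractions (m-2)/(m-1) at the root and m/(m+1) at every deeper
# level.

new_candidate <- function(index, coords, id) {
  list(index = index, coords = coords, id = id,
       status = "unexplored", reps = list(), avg = NULL)
}

#' Generate the root grid of candidate points for a group
#'
#' Samples all `m(n)^n` combinations of `m(n)` linearly spaced values per
#' parameter, endpoints included, over the group's input domains.
#'
#' @param group a `stop_group` from [partition_groups()].
#' @param settings a [search_settings()].
#' @return list of candidate points; each has `index` (integer grid tuple,
#'   first axis varying fastest), `coords` (named values), `status` and,
#'   once explored, replicate-averaged metric values in `avg`.
#' @export
#' @examples
#' g <- partition_groups(landscape_problem(worked_example("fig6a")))[[1]]
#' length(generate_root_grid(g, search_settings(m = 3)))  # 3
generate_root_grid <- function(group, settings) {
  m <- m_value(settings, group$n)
  pn <- names(group$parameters)
  axes <- lapply(group$parameters, function(d) {
    seq(d[["lower"]], d[["upper"]], length.out = m)
  })
  idx <- expand.grid(rep(list(seq_len(m)), group$n))
  lapply(seq_len(nrow(idx)), function(i) {
    ii <- as.integer(idx[i, ])
    coords <- vapply(seq_along(pn), function(a) axes[[a]][ii[a]], numeric(1))
    names(coords) <- pn
    new_candidate(ii, coords, paste(ii, collapse = "."))
  })
}

#' Generate the interior candidate points of a child node
#'
#' Places `m` strictly interior, equally spaced points
#' `u + j * (v - u) / (m + 1)`, `j = 1..m`, inside the feasible range
#' `[u, v]`.  Together with the endpoint values inherited from the parent
#' this yields `m + 1` sub-intervals, so selecting one rejects `m/(m+1)` of
#' the range.
#'
#' @param range a feasible range (list with `axis`, `lower`, `upper`,
#'   `anchor`), as returned by [find_feasible_ranges()].
#' @param m number of interior points, `>= 2`.
#' @return list of candidate points with coordinates `anchor` plus the axis
#'   value.
#' @export
generate_child_points <- function(range, m) {
  u <- range$lower
  v <- range$upper
  if (!(u < v)) stop("degenerate range: lower must be < upper")
  lapply(seq_len(m), function(j) {
    pos <- u + j * (v - u) / (m + 1)
    coords <- c(range$anchor, stats::setNames(pos, range$axis))
    new_candidate(j, coords, paste0("j", j))
  })
}

#' Is an explored candidate point a solution?
#'
#' @param point an explored candidate (replicate-averaged metric values
#'   present in `avg`).
#' @param group the `stop_group` whose metrics define the target ranges.
#' @return `TRUE` iff every group metric's averaged value lies within its
#'   closed target range (boundary values count as inside).
#' @export
is_solution <- function(point, group) {
  if (is.null(point$avg)) stop("candidate point has not been explored")
  all(vapply(names(group$metrics), function(mname) {
    t <- group$metrics[[mname]]
    v <- point$avg[[mname]]
    v >= t[["lower"]] && v <= t[["upper"]]
  }, logical(1)))
}

# Does the closed interval spanned by two endpoint metric values intersect
# every metric's target range?  This generalizes strict flanking (one value
# below the band, the other above) to endpoint values lying inside the band.
pair_feasible <- function(v1, v2, metrics) {
  all(vapply(names(metrics), function(mname) {
    t <- metrics[[mname]]
    lo <- min(v1[[mname]], v2[[mname]])
    hi <- max(v1[[mname]], v2[[mname]])
    lo <= t[["upper"]] && hi >= t[["lower"]]
  }, logical(1)))
}

new_feasible_range <- function(axis, lower, upper, anchor, support_pos,
                               support_values, endpoint_values) {
  structure(
    list(axis = axis, lower = lower, upper = upper, anchor = anchor,
         support_pos = support_pos, support_values = support_values,
         endpoint_values = endpoint_values, score = NA_real_),
    class = "feasible_range"
  )
}

#' Detect feasible ranges in a fully explored node
#'
#' Scans every pair of axis-adjacent (non-diagonal) evaluated points; a pair
#' brackets a metric iff the closed interval spanned by its two averaged
#' values intersects the metric's target range, and the interval between the
#' points is returned as a feasible range iff it brackets ALL metrics of the
#' group.  For a multi-parameter root node each range lies along a grid line
#' and the remaining coordinates are recorded as its anchor.  For non-root
#' nodes the endpoint values inherited from the parent participate in the
#' scan.  Ranges are returned in lexicographic grid order, before
#' prioritization.
#'
#' @param node a search node (see [run_group_search()]) with all candidate
#'   points explored.
#' @param group the `stop_group`.
#' @return list of feasible ranges (possibly empty); each has `axis`,
#'   `lower`, `upper`, `anchor`, its support points along the grid line, and
#'   the metric values at its two endpoints.
#' @export
find_feasible_ranges <- function(node, group) {
  unexplored <- vapply(node$cands, function(p) p$status != "explored",
                       logical(1))
  if (any(unexplored)) {
    stop("all candidate points must be explored before range detection")
  }
  if (node$depth == 0L) {
    find_ranges_root(node, group)
  } else {
    find_ranges_line(node, group)
  }
}

find_ranges_root <- function(node, group) {
  pn <- names(group$parameters)
  n <- group$n
  m <- node$m
  cands <- node$cands
  key <- vapply(cands, function(p) paste(p$index, collapse = ","),
                character(1))
  lookup <- stats::setNames(seq_along(cands), key)
  ranges <- list()
  for (i in seq_along(cands)) {
    p <- cands[[i]]
    for (a in seq_len(n)) {
      if (p$index[a] >= m) next
      nb_idx <- p$index
      nb_idx[a] <- nb_idx[a] + 1L
      q <- cands[[lookup[[paste(nb_idx, collapse = ",")]]]]
      if (!pair_feasible(p$avg, q$avg, group$metrics)) next
      # support: the m evaluated points along this grid line
      line_pos <- numeric(m)
      line_vals <- matrix(NA_real_, m, group$k,
                          dimnames = list(NULL, names(group$metrics)))
      for (s in seq_len(m)) {
        s_idx <- p$index
        s_idx[a] <- s
        sp <- cands[[lookup[[paste(s_idx, collapse = ",")]]]]
        line_pos[s] <- sp$coords[[pn[a]]]
        line_vals[s, ] <- sp$avg[names(group$metrics)]
      }
      ranges[[length(ranges) + 1L]] <- new_feasible_range(
        axis = pn[a],
        lower = p$coords[[pn[a]]], upper = q$coords[[pn[a]]],
        anchor = p$coords[setdiff(pn, pn[a])],
        support_pos = line_pos, support_values = line_vals,
        endpoint_values = list(lower = p$avg, upper = q$avg)
      )
    }
  }
  ranges
}

find_ranges_line <- function(node, group) {
  mets <- names(group$metrics)
  pos <- c(vapply(node$inherited, `[[`, numeric(1), "pos"),
           vapply(node$cands, function(p) p$coords[[node$axis]], numeric(1)))
  vals <- rbind(
    do.call(rbind, lapply(node$inherited, function(e) e$values[mets])),
    do.call(rbind, lapply(node$cands, function(p) p$avg[mets]))
  )
  colnames(vals) <- mets
  ord <- order(pos)
  pos <- pos[ord]
  vals <- vals[ord, , drop = FALSE]
  ranges <- list()
  for (i in seq_len(length(pos) - 1L)) {
    v1 <- vals[i, ]
    v2 <- vals[i + 1L, ]
    if (!pair_feasible(as.list(v1), as.list(v2), group$metrics)) next
    ranges[[length(ranges) + 1L]] <- new_feasible_range(
      axis = node$axis, lower = pos[i], upper = pos[i + 1L],
      anchor = node$anchor,
      support_pos = pos, support_values = vals,
      endpoint_values = list(lower = v1, upper = v2)
    )
  }
  ranges
}

# Interpolant through evaluated points along a grid line: cubic spline with
# >= 4 support points, exact quadratic with 3, linear with 2.
interp_fun <- function(x, y) {
  n <- length(x)
  if (n >= 4) {
    stats::splinefun(x, y, method = "fmm")
  } else if (n == 3) {
    co <- solve(cbind(1, x, x^2), y)
    function(q) co[1] + co[2] * q + co[3] * q^2
  } else if (n == 2) {
    stats::approxfun(x, y, rule = 2)
  } else {
    stop("a feasible range needs at least 2 support points")
  }
}

#' Prioritize feasible ranges by interpolated target coverage
#'
#' For each metric, fits a one-dimensional interpolant (degree
#' `min(3, points - 1)`) through the evaluated points along each range's
#' grid line, evaluates all metric interpolants at `n_interp` (default 100)
#' linearly spaced query values inside the range, and scores the range by
#' the fraction of query values at which ALL metrics' interpolated values
#' lie in their target ranges.  Ranges are returned sorted by descending
#' score; ties preserve the original lexicographic discovery order.
#'
#' @param node the search node in which the ranges were discovered.
#' @param ranges list of feasible ranges from [find_feasible_ranges()].
#' @param group the `stop_group`.
#' @param settings a [search_settings()] (`n_interp` queries per range).
#' @return the ranges, scores filled in, in exploration order.
#' @export
prioritize_ranges <- function(node, ranges, group, settings) {
  if (length(ranges) <= 1L) {
    for (i in seq_along(ranges)) {
      ranges[[i]]$score <- range_score(ranges[[i]], group, settings)
    }
    return(ranges)
  }
  scores <- vapply(ranges, range_score, numeric(1),
                   group = group, settings = settings)
  for (i in seq_along(ranges)) ranges[[i]]$score <- scores[i]
  ranges[order(-scores)] # stable: ties keep discovery order
}

range_score <- function(range, group, settings) {
  if (length(range$support_pos) < 2) {
    stop("a feasible range needs at least 2 support points")
  }
  q <- seq(range$lower, range$upper, length.out = settings$n_interp)
  ok <- rep(TRUE, length(q))
  for (mname in names(group$metrics)) {
    fit <- interp_fun(range$support_pos, range$support_values[, mname])
    v <- fit(q)
    t <- group$metrics[[mname]]
    ok <- ok & v >= t[["lower"]] & v <= t[["upper"]]
  }
  mean(ok)
}

#' Resolve a fully explored node into its outcome
#'
#' If any candidate is a solution the group search ends in success.
#' Otherwise, at the depth cap the node fails (`failed-max-depth`); below
#' the cap its feasible ranges are detected and prioritized, and the node
#' either spawns children or fails (`failed-no-ranges`).
#'
#' @param node a search node with all candidate points explored.
#' @param group the `stop_group`.
#' @param settings a [search_settings()].
#' @return list with `outcome` (one of `"success"`, `"max-depth"`,
#'   `"no-ranges"`, `"children"`), `solution` (the first solution candidate
#'   in grid order, or `NULL`) and `ranges` (prioritized feasible ranges,
#'   when `outcome == "children"`).
#' @export
expand_node <- function(node, group, settings) {
  for (p in node$cands) {
    if (is_solution(p, group)) {
      return(list(outcome = "success", solution = p, ranges = list()))
    }
  }
  if (node$depth >= settings$max_depth) {
    return(list(outcome = "max-depth", solution = NULL, ranges = list()))
  }
  ranges <- find_feasible_ranges(node, group)
  if (length(ranges) == 0L) {
    return(list(outcome = "no-ranges", solution = NULL, ranges = list()))
  }
  list(outcome = "children", solution = NULL,
       ranges = prioritize_ranges(node, ranges, group, settings))
}
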