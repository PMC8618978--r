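# Shared fixtures and independent oracles, all built in code.

# Construct a stop_landscape from plain functions of a named parameter
# vector.
make_landscape <- function(metrics, domains, targets, name = "test") {
  structure(
    list(dimension = length(domains), parameters = names(domains),
         metrics = metrics,
         domains = lapply(domains, function(d) c(lower = d[1], upper = d[2])),
         targets = lapply(targets, function(t) c(lower = t[1], upper = t[2])),
         noise_sd = 0, m = NULL, name = name),
    class = "stop_landscape"
  )
}

# Monotonic 1-D landscape f(x) = x on [0, 1] whose desired range is 1/r of
# the domain, centered slightly off any grid-aligned point.
linear_landscape <- function(r, center = 0.3371) {
  make_landscape(
    metrics = list(f = function(x) x[["x"]]),
    domains = list(x = c(0, 1)),
    targets = list(f = c(center - 0.5 / r, center + 0.5 / r)),
    name = sprintf("linear-r%g", r)
  )
}

single_group <- function(landscape) {
  partition_groups(landscape_problem(landscape))[[1]]
}

# Root node of a group's search, fully explored against a noiseless
# landscape, without advancing the DFS.  Exposes the internal state machine
# for feasibility/prioritization tests.
explored_root <- function(landscape, m, n_interp = 100) {
  group <- single_group(landscape)
  settings <- search_settings(m = m, seed = 1, n_interp = n_interp)
  tree <- stopt:::new_group_search(group, settings)
  node <- tree$current
  ev <- synthetic_evaluator(landscape, 0)
  for (i in stopt:::unexplored_indices(node)) {
    stopt:::gs_submit_replicate(tree, i, 1, ev(node$cands[[i]]$coords))
  }
  list(tree = tree, node = tree$current, group = group, settings = settings)
}

# Brute-force connected components of a bipartite edge list by repeated
# pairwise merging until fixpoint (the transitive-closure oracle).
merge_components_oracle <- function(edges) {
  comps <- lapply(seq_len(nrow(edges)), function(i) {
    c(paste0("p:", edges$parameter[i]), paste0("m:", edges$metric[i]))
  })
  repeat {
    merged <- FALSE
    i <- 1
    while (i < length(comps)) {
      j <- i + 1
      while (j <= length(comps)) {
        if (length(intersect(comps[[i]], comps[[j]])) > 0) {
          comps[[i]] <- union(comps[[i]], comps[[j]])
          comps[[j]] <- NULL
          merged <- TRUE
        } else {
          j <- j + 1
        }
      }
      i <- i + 1
    }
    if (!merged) break
  }
  lapply(comps, sort)
}

# Random valid bipartite dependency graph: every metric and every parameter
# gets at least one edge.
random_bipartite_problem <- function(seed, n_par = 5, n_met = 4) {
  set.seed(seed)
  pn <- paste0("p", seq_len(n_par))
  mn <- paste0("f", seq_len(n_met))
  edges <- do.call(rbind, lapply(mn, function(m) {
    data.frame(parameter = sample(pn, sample(1:3, 1)), metric = m,
               stringsAsFactors = FALSE)
  }))
  for (p in setdiff(pn, edges$parameter)) {
    edges <- rbind(edges, data.frame(parameter = p, metric = sample(mn, 1)))
  }
  edges <- unique(edges)
  deps <- split(edges$metric, edges$parameter)
  stop_problem(
    parameters = lapply(pn, function(p) stop_parameter(p, 0, 1)),
    metrics = lapply(mn, function(m) stop_metric(m, 0.4, 0.6)),
    dependencies = deps
  )
}

# Brute-force feasible-pair oracle: enumerate every axis-adjacent pair of an
# explored grid and keep those whose per-metric value intervals all
# intersect the targets.  Returns a sorted character key per range.
feasible_pairs_oracle <- function(node, group) {
  cands <- node$cands
  m <- node$m
  keys <- character(0)
  idx_of <- function(ii) {
    which(vapply(cands, function(p) identical(p$index, ii), logical(1)))
  }
  for (ci in seq_along(cands)) {
    p <- cands[[ci]]
    for (a in seq_along(p$index)) {
      ii <- p$index
      if (ii[a] >= m) next
      ii[a] <- ii[a] + 1L
      q <- cands[[idx_of(ii)]]
      ok <- all(vapply(names(group$metrics), function(mm) {
        t <- group$metrics[[mm]]
        lo <- min(p$avg[[mm]], q$avg[[mm]])
        hi <- max(p$avg[[mm]], q$avg[[mm]])
        lo <= t[["upper"]] && hi >= t[["lower"]]
      }, logical(1)))
      if (ok) {
        keys <- c(keys, paste(paste(p$index, collapse = ","),
                              paste(q$index, collapse = ","), sep = "|"))
      }
    }
  }
  sort(keys)
}

range_key <- function(range, group, node) {
  # reconstruct the grid-index key of a returned range for oracle comparison
  pn <- names(group$parameters)
  a <- match(range$axis, pn)
  coords_to_index <- function(pos) {
    line <- range$support_pos
    match(TRUE, abs(line - pos) < 1e-12)
  }
  anchor_idx <- vapply(setdiff(pn, range$axis), function(p) {
    d <- group$parameters[[p]]
    ax <- seq(d[["lower"]], d[["upper"]], length.out = node$m)
    match(TRUE, abs(ax - range$anchor[[p]]) < 1e-12)
  }, integer(1))
  make_key <- function(axis_i) {
    ii <- integer(length(pn))
    ii[a] <- axis_i
    ii[setdiff(seq_along(pn), a)] <- anchor_idx
    paste(ii, collapse = ",")
  }
  paste(make_key(coords_to_index(range$lower)),
        make_key(coords_to_index(range$upper)), sep = "|")
}
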