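# Comparison methods: 1-D binary search, the worst-case m-ary iteration
# formula, and a genetic-algorithm search.

#' 1-D binary search for a target range
#'
#' Automates manual move-size tuning under an assumed monotonic
#' parameter-metric relationship: starting from the full input domain, the
#' midpoint is evaluated and half of the range is rejected based on the
#' supplied gradient sign and whether the value overshot or undershot the
#' target range.  One new candidate point is explored per iteration.
#'
#' @param metric_fn scalar function of the parameter.
#' @param target closed target range `c(lower, upper)`.
#' @param domain input domain `c(lower, upper)`.
#' @param gradient `"increasing"` or `"decreasing"`: the assumed sign of the
#'   metric's gradient.  A wrong sign makes the search reject the half
#'   containing the desired range and fail.
#' @param max_iterations iteration cap.
#' @return list with `success`, `x`, `value`, `iterations` and a `trace`
#'   data frame of midpoints.
#' @export
#' @examples
#' binary_search_1d(function(x) x, c(0.49, 0.51), c(0, 1), "increasing")
binary_search_1d <- function(metric_fn, target, domain,
                             gradient = c("increasing", "decreasing"),
                             max_iterations = 100) {
  gradient <- match.arg(gradient)
  a <- target[1]
  b <- target[2]
  lo <- domain[1]
  hi <- domain[2]
  trace <- list()
  for (it in seq_len(max_iterations)) {
    mid <- (lo + hi) / 2
    v <- metric_fn(mid)
    trace[[it]] <- data.frame(iteration = it, x = mid, value = v,
                              lower = lo, upper = hi)
    if (v >= a && v <= b) {
      return(list(success = TRUE, x = mid, value = v, iterations = it,
                  trace = do.call(rbind, trace)))
    }
    overshoot <- v > b
    if (gradient == "increasing") {
      if (overshoot) hi <- mid else lo <- mid
    } else {
      if (overshoot) lo <- mid else hi <- mid
    }
  }
  list(success = FALSE, x = NA_real_, value = NA_real_,
       iterations = max_iterations, trace = do.call(rbind, trace))
}

#' Worst-case iteration count of m-ary search
#'
#' For a nonstochastic, continuous, monotonic 1-D metric whose desired range
#' is `1/r` of the input domain, the number of m-ary iterations needed in
#' the worst case is `log(r/(m-1)) / log(m+1) + 1`: the first iteration
#' rejects `(m-2)/(m-1)` of the domain and each successive iteration rejects
#' `m/(m+1)` of the remaining range.
#'
#' @param r ratio of the input-domain size to the desired-range size,
#'   `r > m - 1`.
#' @param m branching factor, integer `>= 2`.
#' @return the (real-valued) worst-case iteration count.
#' @export
#' @examples
#' worst_case_iterations(8, 3)  # 2
worst_case_iterations <- function(r, m) {
  if (m < 2 || m != round(m)) stop("m must be an integer >= 2")
  if (r <= m - 1) stop("r must exceed m - 1 for the bound to apply")
  log(r / (m - 1)) / log(m + 1) + 1
}

#' Genetic-algorithm configuration
#'
#' @param population candidate points per generation.
#' @param elite_fraction fraction of the fittest points carried forward
#'   unaltered each generation.
#' @param mutant_fraction fraction of the next generation created by
#'   mutating the retained points.
#' @param max_mutation maximum mutation size: each coordinate of a mutant is
#'   perturbed by a uniform draw in `[-max_mutation, +max_mutation]`,
#'   clipped to the input domain.
#' @param crossover_fraction size of the randomly chosen crossover subset,
#'   as a fraction of the population.
#' @param budget maximum number of metric evaluations; the generational loop
#'   runs for `budget %/% population` generations unless a solution is found
#'   earlier.
#' @param seed integer seed for initialization, mutation and crossover.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(population = 5, elite_fraction = 0.25,
                      mutant_fraction = 0.75, max_mutation = 0.1,
                      crossover_fraction = 0.5, budget = 10000, seed = 1) {
  stopifnot(elite_fraction > 0, elite_fraction < 1,
            mutant_fraction > 0, mutant_fraction < 1,
            crossover_fraction > 0, crossover_fraction < 1,
            budget >= population, population >= 2)
  structure(
    list(population = as.integer(population),
         elite_fraction = elite_fraction, mutant_fraction = mutant_fraction,
         max_mutation = max_mutation,
         crossover_fraction = crossover_fraction,
         budget = as.integer(budget), seed = as.integer(seed)),
    class = "ga_config"
  )
}

#' Distance-to-target fitness
#'
#' Fitness of a metric value relative to a target range `[a, b]`: 0 inside
#' the closed range, otherwise the negative absolute distance to the closest
#' edge.  For multiple metrics, fitnesses are summed.
#'
#' @param values named numeric vector of metric values.
#' @param targets named list of target ranges `c(lower, upper)`.
#' @return a single fitness value `<= 0`; 0 iff all metrics are in range.
#' @export
range_fitness <- function(values, targets) {
  sum(vapply(names(targets), function(mname) {
    t <- targets[[mname]]
    v <- values[[mname]]
    if (v >= t[["lower"]] && v <= t[["upper"]]) 0
    else -min(abs(v - t[["lower"]]), abs(v - t[["upper"]]))
  }, numeric(1)))
}

#' Genetic-algorithm search for a target range
#'
#' Generational loop on a continuous landscape: the population is evaluated
#' (stopping as soon as any point's metrics are all inside their target
#' ranges), the fittest `elite_fraction` is retained, the rest of the next
#' generation is filled with mutants of the retained set, and a crossover
#' step swaps one uniformly chosen coordinate within random pairs drawn
#' (without replacement) from a subset half the population size.
#'
#' @param landscape a `stop_landscape` (its `targets` define success).
#' @param config a [ga_config()].
#' @param noise_sd Gaussian noise added per evaluation (0 = noiseless).
#' @return list with `success`, `solution` (named vector or `NULL`),
#'   `values`, `evaluations` (metric evaluations consumed at convergence),
#'   `generations` (generations executed) and `config`.
#' @export
ga_search <- function(landscape, config, noise_sd = 0) {
  pn <- landscape$parameters
  d <- length(pn)
  lower <- vapply(landscape$domains, `[[`, numeric(1), "lower")
  upper <- vapply(landscape$domains, `[[`, numeric(1), "upper")
  pop <- config$population
  gens_max <- config$budget %/% pop
  if (gens_max < 1) stop("budget is smaller than one generation")
  elite_n <- max(1L, as.integer(round(pop * config$elite_fraction)))
  cross_n <- max(0L, as.integer(floor(pop * config$crossover_fraction)))
  eval_point <- function(x) {
    names(x) <- pn
    v <- vapply(names(landscape$metrics),
                function(mn) landscape$metrics[[mn]](x), numeric(1))
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
    v
  }
  with_stream(stream_seed("ga", config$seed), {
    P <- matrix(stats::runif(pop * d, rep(lower, each = pop),
                             rep(upper, each = pop)), pop, d)
    evals <- 0L
    gens <- 0L
    result <- NULL
    for (gen in seq_len(gens_max)) {
      gens <- gen
      fitness <- numeric(pop)
      vals <- vector("list", pop)
      found <- 0L
      for (i in seq_len(pop)) {
        vals[[i]] <- eval_point(P[i, ])
        evals <- evals + 1L
        fitness[i] <- range_fitness(vals[[i]], landscape$targets)
        if (fitness[i] == 0) {
          found <- i
          break
        }
      }
      if (found > 0L) {
        sol <- P[found, ]
        names(sol) <- pn
        result <- list(success = TRUE, solution = sol,
                       values = vals[[found]], evaluations = evals,
                       generations = gens, config = config)
        break
      }
      if (gen == gens_max) break
      ord <- order(fitness, decreasing = TRUE) # stable; ties keep row order
      elite <- P[ord[seq_len(elite_n)], , drop = FALSE]
      n_mut <- pop - elite_n
      parents <- elite[sample.int(elite_n, n_mut, replace = TRUE), ,
                       drop = FALSE]
      noise <- matrix(stats::runif(n_mut * d, -config$max_mutation,
                                   config$max_mutation), n_mut, d)
      mutants <- pmin(pmax(parents + noise,
                           matrix(lower, n_mut, d, byrow = TRUE)),
                      matrix(upper, n_mut, d, byrow = TRUE))
      P <- rbind(elite, mutants)
      if (cross_n >= 2) {
        subset <- sample.int(pop, cross_n) # without replacement
        for (p in seq_len(cross_n %/% 2)) {
          i <- subset[2 * p - 1]
          j <- subset[2 * p]
          coord <- sample.int(d, 1)
          tmp <- P[i, coord]
          P[i, coord] <- P[j, coord]
          P[j, coord] <- tmp
        }
      }
    }
    if (is.null(result)) {
      result <- list(success = FALSE, solution = NULL, values = NULL,
                     evaluations = evals, generations = gens,
                     config = config)
    }
    result
  })
}

#' Benchmark algorithms on a set of landscapes
#'
#' Runs each algorithm on each landscape for each seed and tabulates
#' success and the number of metric function evaluations at convergence.
#'
#' @param landscapes list of `stop_landscape` objects.
#' @param algorithms named list of `function(landscape, seed)` returning
#'   `list(success, evaluations)`; see [benchmark_stop()], [benchmark_ga()].
#' @param seeds integer vector of seeds.
#' @return data frame with columns `landscape`, `algorithm`, `seed`,
#'   `success`, `evaluations`.
#' @seealso [benchmark_summary()]
#' @export
run_benchmark <- function(landscapes, algorithms, seeds) {
  stopifnot(length(landscapes) >= 1, length(algorithms) >= 1)
  rows <- list()
  for (li in seq_along(landscapes)) {
    ls <- landscapes[[li]]
    lname <- ls$name %||% paste0("landscape", li)
    for (aname in names(algorithms)) {
      for (s in seeds) {
        out <- algorithms[[aname]](ls, s)
        rows[[length(rows) + 1L]] <- data.frame(
          landscape = lname, algorithm = aname, seed = s,
          success = isTRUE(out$success),
          evaluations = as.integer(out$evaluations),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize benchmark results
#'
#' @param results data frame from [run_benchmark()].
#' @return data frame per algorithm: success rate and the 10th, 50th and
#'   90th percentiles of the evaluation counts.
#' @export
benchmark_summary <- function(results) {
  do.call(rbind, lapply(split(results, results$algorithm), function(df) {
    q <- stats::quantile(df$evaluations, c(0.1, 0.5, 0.9))
    data.frame(algorithm = df$algorithm[1],
               runs = nrow(df),
               success_rate = mean(df$success),
               p10 = unname(q[1]), p50 = unname(q[2]), p90 = unname(q[3]),
               stringsAsFactors = FALSE)
  }))
}

#' Benchmark adapter: the grid/DFS target-range search
#'
#' @param settings a [search_settings()] template; the benchmark seed
#'   replaces `settings$seed` per run.
#' @param noise_sd evaluation noise.
#' @return `function(landscape, seed)` for [run_benchmark()].
#' @export
benchmark_stop <- function(settings, noise_sd = 0) {
  force(settings); force(noise_sd)
  function(landscape, seed) {
    st <- settings
    st$seed <- as.integer(seed)
    grp <- partition_groups(landscape_problem(landscape))[[1]]
    tree <- run_group_search(grp, synthetic_evaluator(landscape, noise_sd),
                             st)
    list(success = tree$status == "success", evaluations = tree$n_requests)
  }
}

#' Benchmark adapter: the genetic algorithm
#'
#' @param config a [ga_config()] template; the benchmark seed replaces
#'   `config$seed` per run.
#' @param noise_sd evaluation noise.
#' @return `function(landscape, seed)` for [run_benchmark()].
#' @export
benchmark_ga <- function(config, noise_sd = 0) {
  force(config); force(noise_sd)
  function(landscape, seed) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    out <- ga_search(landscape, cfg, noise_sd = noise_sd)
    list(success = out$success, evaluations = out$evaluations)
  }
}
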