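# Optimizer settings: the m(n) table, DFS depth cap, replicates, parallelism.

#' Optimizer settings
#'
#' @param m the m-ary branching factor.  Either a single integer (used for
#'   every dimensionality), a named vector such as `c("1" = 8, "2" = 4)`
#'   giving `m(n)` per group dimensionality `n`, or `"auto"` to use the
#'   default rule (see Details).  All entries must be `>= 2`.
#' @param max_depth maximum DFS depth; the root is depth 0.  Caps runtime and
#'   guards against noise-induced misclassification of feasible ranges.
#' @param replicates number of repeated evaluations per candidate point;
#'   metrics are averaged over replicates, shrinking the noise standard
#'   deviation by `1/sqrt(replicates)`.
#' @param max_processes maximum number of concurrently dispatched
#'   evaluations.
#' @param seed global seed from which all per-candidate random streams are
#'   derived.
#' @param n_interp number of linearly spaced query points per feasible range
#'   used by the spline prioritization heuristic.
#'
#' @details When `m` is `"auto"` (or lacks an entry for some `n`), `m(1)`
#' defaults to 8 and `m(n)` for `n > 1` is the largest integer `q >= 2` with
#' `q^n <= max(m(1)^2, 64)` such that `q^n` is a multiple of `m(1)`, falling
#' back to 2.  The multiplicity keeps parallel block sizes commensurate with
#' `m(1)` so available processes stay busy.
#'
#' @return an object of class `search_settings`.
#' @export
#' @examples
#' search_settings(m = 3, max_depth = 5, replicates = 100, seed = 1)
search_settings <- function(m = "auto", max_depth = 5, replicates = 1,
                            max_processes = 1, seed = 1, n_interp = 100) {
  if (!identical(m, "auto")) {
    mv <- as.numeric(m)
    if (any(!is.finite(mv)) || any(mv < 2) || any(mv != round(mv))) {
      stop("all entries of 'm' must be integers >= 2")
    }
    if (is.null(names(m)) && length(m) == 1) {
      m <- c("*" = mv) # same m for every dimensionality
    } else {
      names(mv) <- names(m)
      m <- mv
    }
  }
  stopifnot(max_depth >= 0, replicates >= 1, max_processes >= 1,
            n_interp >= 2)
  structure(
    list(m = m, max_depth = as.integer(max_depth),
         replicates = as.integer(replicates),
         max_processes = as.integer(max_processes),
         seed = as.integer(seed), n_interp = as.integer(n_interp)),
    class = "search_settings"
  )
}

#' Branching factor for a given dimensionality
#'
#' Resolves `m(n)` from the settings table, applying the default rule for
#' missing entries (see [search_settings()]).
#'
#' @param settings a [search_settings()].
#' @param n group dimensionality (number of parameters varied at the root).
#' @return integer `m(n) >= 2`.
#' @export
m_value <- function(settings, n) {
  m <- settings$m
  if (!identical(m, "auto")) {
    if (!is.null(names(m)) && "*" %in% names(m)) return(as.integer(m[["*"]]))
    key <- as.character(n)
    if (key %in% names(m)) return(as.integer(m[[key]]))
    m1 <- if ("1" %in% names(m)) as.integer(m[["1"]]) else 8L
    return(default_m(n, m1))
  }
  default_m(n, 8L)
}

# Default m(n): largest q >= 2 with q^n <= max(m1^2, 64) and q^n %% m1 == 0;
# fallback 2.
default_m <- function(n, m1) {
  if (n == 1) return(as.integer(m1))
  cap <- max(m1^2, 64)
  best <- 2L
  q <- 2L
  while (q^n <= cap) {
    if (q^n %% m1 == 0) best <- q
    q <- q + 1L
  }
  as.integer(best)
}

#' Check the CPU-economy recommendation for m(n)
#'
#' For full utilization of `max_processes` parallel slots it is recommended
#' that every `m(n_i)^n_i` be a multiple of `m(1)`, that `max_processes` be a
#' multiple of `m(1)`, and that `replicates` be a multiple of the quotient
#' `max_processes / m(1)`.  These are recommendations, not requirements, so
#' violations emit warnings rather than errors.
#'
#' @param settings a [search_settings()].
#' @param group_dims integer vector of group dimensionalities `n_i`.
#' @return invisibly, a character vector of warning messages (empty when the
#'   configuration satisfies the recommendation).
#' @export
check_recommended_m <- function(settings, group_dims) {
  msgs <- character(0)
  m1 <- m_value(settings, 1L)
  for (n in unique(group_dims)) {
    mn <- m_value(settings, n)
    if ((mn^n) %% m1 != 0) {
      msgs <- c(msgs, sprintf(
        "m(%d)^%d = %d is not a multiple of m(1) = %d; some blocks may underfill the process pool",
        n, n, mn^n, m1))
    }
  }
  mp <- settings$max_processes
  if (mp %% m1 != 0 && m1 %% mp != 0) {
    msgs <- c(msgs, sprintf(
      "max_processes = %d is not commensurate with m(1) = %d", mp, m1))
  } else if (mp > m1 && mp %% m1 == 0) {
    quotient <- mp %/% m1
    if (settings$replicates %% quotient != 0) {
      msgs <- c(msgs, sprintf(
        "replicates = %d is not a multiple of max_processes/m(1) = %d",
        settings$replicates, quotient))
    }
  }
  for (msg in msgs) warning(msg, call. = FALSE)
  invisible(msgs)
}

#' @export
print.search_settings <- function(x, ...) {
  mdesc <- if (identical(x$m, "auto")) "auto" else
    paste(sprintf("m(%s)=%d", names(x$m), as.integer(x$m)), collapse = ", ")
  cat(sprintf(
    "<search_settings> m: %s | max_depth: %d | replicates: %d | max_processes: %d | seed: %d\n",
    mdesc, x$max_depth, x$replicates, x$max_processes, x$seed))
  invisible(x)
}
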