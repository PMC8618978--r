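# Deterministic derivation of random streams from structured provenance.
#
# Every stochastic draw in the package is keyed by the tuple that produced it
# (global seed, group key, node id, candidate index, replicate index, metric
# name), so results are reproducible and independent of evaluation order.
# Streams are 31-bit integers obtained by folding the components with a
# multiplicative congruential mixer; all arithmetic stays below 2^53 so it is
# exact in doubles.

.STREAM_MOD <- 2147483647 # 2^31 - 1

mix_component <- function(h, x) {
  x <- as.numeric(x) %% .STREAM_MOD
  ((h * 69069) %% .STREAM_MOD + x + 1) %% .STREAM_MOD
}

fold_component <- function(h, comp) {
  if (is.character(comp)) {
    for (s in comp) {
      for (code in utf8ToInt(s)) h <- mix_component(h, code)
      h <- mix_component(h, 3L) # separator so c("ab","c") != c("a","bc")
    }
  } else {
    for (v in comp) h <- mix_component(h, v)
  }
  h
}

#' Derive a reproducible random stream from provenance components
#'
#' Folds an arbitrary sequence of integers and strings into a single seed in
#' `[0, 2^31 - 2]`, suitable for [set.seed()].  Identical components always
#' yield the identical stream; the order of components matters.
#'
#' @param ... integer or character components (for example the global seed,
#'   a group key, a node id, a candidate index, and a replicate index).
#' @return a single integer seed.
#' @export
stream_seed <- function(...) {
  h <- 7
  for (comp in list(...)) h <- fold_component(h, comp)
  as.integer(h)
}

# Key identifying a group by content (its sorted parameter names), not by its
# position in the problem: a group's streams are then identical whether the
# group is optimized alone or co-scheduled with others.
group_stream_key <- function(group) {
  stream_seed("group", sort(names(group$parameters)))
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_stream <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
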