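# Metric evaluators: in-process synthetic landscapes with Gaussian noise and
# an external-command backend with a JSON file protocol.

#' Evaluate a synthetic landscape with Gaussian noise
#'
#' Computes each metric of the landscape at the full parameter vector and
#' adds a single Gaussian noise draw per metric.  One call models one
#' replicate of an expensive stochastic run (for example one MCMC sampling
#' run whose acceptance rates are read off afterwards); the expected metric
#' is recovered by replicate averaging.
#'
#' @param x named numeric vector with one entry per landscape parameter.
#' @param landscape a `stop_landscape` (see [worked_example()],
#'   [random_landscape()]).
#' @param noise_sd Gaussian noise standard deviation, `>= 0` (0 = noiseless).
#' @param stream optional reproducibility stream: a single integer (combined
#'   with each metric's name so draws are independent per metric), or a named
#'   integer vector with one stream per metric.  When `NULL` and
#'   `noise_sd > 0`, draws come from the ambient RNG.
#' @return named numeric vector of metric values.
#' @export
#' @examples
#' evaluate_synthetic(c(x = 0), worked_example("fig6a"))  # metric1 = 1
evaluate_synthetic <- function(x, landscape, noise_sd = 0, stream = NULL) {
  stopifnot(noise_sd >= 0)
  out <- vapply(names(landscape$metrics), function(mname) {
    v <- landscape$metrics[[mname]](x)
    if (!is.finite(v)) {
      stop("metric '", mname, "' is undefined at the supplied point")
    }
    if (noise_sd > 0) {
      eta <- if (is.null(stream)) {
        stats::rnorm(1, 0, noise_sd)
      } else {
        base <- if (!is.null(names(stream))) stream[[mname]] else stream
        with_stream(stream_seed(base, mname),
                    stats::rnorm(1, 0, noise_sd))
      }
      v <- v + eta
    }
    v
  }, numeric(1))
  out
}

#' In-process evaluator backed by a synthetic landscape
#'
#' @param landscape a `stop_landscape`.
#' @param noise_sd Gaussian noise standard deviation per replicate.
#' @return an evaluator `function(params, stream)` suitable for
#'   [run_group_search()] and [run_optimization()].
#' @export
synthetic_evaluator <- function(landscape, noise_sd = landscape$noise_sd) {
  force(landscape); force(noise_sd)
  function(params, stream = NULL) {
    evaluate_synthetic(params, landscape, noise_sd = noise_sd,
                       stream = stream)
  }
}

#' Average metric values over replicates
#'
#' @param records list of named numeric vectors, one per replicate, all with
#'   the same metric names.
#' @return named numeric vector of arithmetic means per metric.  With `R`
#'   replicates of Gaussian noise with standard deviation `sigma`, the
#'   averaged noise has standard deviation `sigma / sqrt(R)`.
#' @export
#' @examples
#' average_replicates(list(c(a = 0.5), c(a = 0.7)))  # a = 0.6
average_replicates <- function(records) {
  if (length(records) == 0) stop("no replicates to average")
  mat <- do.call(rbind, records)
  colMeans(mat)
}

#' Declare an external evaluation command
#'
#' The command is invoked once per replicate as
#' `<executable> <extra args> <input-path> <output-path>`.  The input file is
#' a JSON object with one key per parameter (plus a reserved `.seed` key
#' carrying the derived replicate stream, when available); the output file
#' must be a JSON object with one numeric value per declared metric.
#'
#' @param executable command to run (for example `"Rscript"` or a script
#'   path).
#' @param args character vector of fixed arguments placed before the input
#'   and output paths.
#' @param metrics character vector of metric names the command must report.
#' @return an object of class `external_command`.
#' @export
external_command <- function(executable, args = character(0), metrics) {
  structure(list(executable = executable, args = args,
                 metrics = as.character(metrics)),
            class = "external_command")
}

#' Evaluate one replicate through an external command
#'
#' @param x named numeric vector of all parameter values.
#' @param command an [external_command()].
#' @param workdir directory for the interchange files.
#' @param stream optional integer stream written as the reserved `.seed`
#'   input key so the external run is reproducible.
#' @return named numeric vector with one value per declared metric.
#'   A nonzero exit status, a missing output file, a missing metric key or a
#'   non-numeric value raise an error (the scheduler retries a failed
#'   evaluation once before aborting).
#' @export
evaluate_external <- function(x, command, workdir = tempdir(),
                              stream = NULL) {
  stopifnot(inherits(command, "external_command"))
  tag <- sprintf("eval-%s", paste(sample(c(letters, 0:9), 10, TRUE),
                                  collapse = ""))
  fin <- file.path(workdir, paste0(tag, "-in.json"))
  fout <- file.path(workdir, paste0(tag, "-out.json"))
  on.exit(unlink(c(fin, fout)), add = TRUE)
  payload <- as.list(x)
  if (!is.null(stream)) {
    payload$.seed <- if (!is.null(names(stream))) {
      as.integer(stream_seed(unname(as.integer(stream))))
    } else {
      as.integer(stream)
    }
  }
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = I(17))
  status <- suppressWarnings(
    system2(command$executable, c(command$args, fin, fout),
            stdout = FALSE, stderr = FALSE))
  if (!identical(status, 0L)) {
    stop("external command '", command$executable,
         "' exited with status ", status)
  }
  if (!file.exists(fout)) {
    stop("external command produced no output file")
  }
  res <- jsonlite::read_json(fout, simplifyVector = TRUE)
  vals <- vapply(command$metrics, function(mname) {
    if (is.null(res[[mname]])) {
      stop("external output is missing metric '", mname, "'")
    }
    v <- res[[mname]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("external output for metric '", mname, "' is not a finite number")
    }
    as.numeric(v)
  }, numeric(1))
  vals
}

#' Evaluator backed by an external command
#'
#' @param command an [external_command()].
#' @param workdir directory for the interchange files.
#' @return an evaluator `function(params, stream)` suitable for
#'   [run_group_search()] and [run_optimization()].
#' @export
external_evaluator <- function(command, workdir = tempdir()) {
  force(command); force(workdir)
  function(params, stream = NULL) {
    evaluate_external(params, command, workdir = workdir, stream = stream)
  }
}

#' Path of the bundled mock-sampler script
#'
#' A small random-walk MCMC sampler (standard normal target) whose proposal
#' acceptance rate decreases monotonically with the proposed move size.  It
#' demonstrates end-to-end tuning of an acceptance-rate metric to a target
#' such as `[0.3, 0.6]` through the external-command protocol: it reads a
#' JSON input with a `move_size` key and writes a JSON output with an
#' `acceptance` key.
#'
#' @return path to the script, to be run as
#'   `Rscript <path> <input.json> <output.json>`.
#' @export
mock_sampler_path <- function() {
  system.file("exec", "mock_sampler.R", package = "stopt", mustWork = TRUE)
}
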