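# Configuration loading and validation (YAML or JSON).

#' Load an optimization configuration file
#'
#' The config declares the problem (parameters with domains, metrics with
#' target ranges, the parameter -> metric dependency mapping), the optimizer
#' settings (`m` table or `"auto"`, `max_depth`, `replicates`,
#' `max_processes`, `seed`) and the evaluator (a named synthetic landscape,
#' a seeded random landscape, or an external command).  YAML and JSON are
#' both accepted (JSON is detected by the `.json` extension).
#'
#' All structural violations are reported at once; the CPU-economy
#' recommendation for `m(n)` is checked and violations emit warnings, not
#' errors.
#'
#' @param path path to a YAML or JSON configuration file.
#' @return an object of class `stop_config` with elements `problem`,
#'   `settings`, `evaluator_spec` and `output`.
#' @export
#' @examples
#' cfg <- load_config(system.file("extdata", "fig6a.yaml", package = "stopt"))
#' m_value(cfg$settings, 1)  # 3
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (req in c("parameters", "metrics", "dependencies")) {
    if (is.null(raw[[req]])) stop("config is missing the '", req, "' section")
  }
  parameters <- lapply(names(raw$parameters), function(p) {
    d <- raw$parameters[[p]]$domain
    if (length(d) != 2) stop("parameter '", p, "' needs a 2-element domain")
    stop_parameter(p, d[1], d[2])
  })
  metrics <- lapply(names(raw$metrics), function(m) {
    t <- raw$metrics[[m]]$target
    if (length(t) != 2) stop("metric '", m, "' needs a 2-element target")
    stop_metric(m, t[1], t[2])
  })
  problem <- stop_problem(parameters, metrics,
                          lapply(raw$dependencies, unlist))
  viol <- validate_problem(problem)
  if (length(viol)) {
    stop("invalid configuration:\n", paste("-", viol, collapse = "\n"))
  }
  m <- raw$m %||% "auto"
  if (is.list(m)) m <- unlist(m)
  settings <- search_settings(
    m = m,
    max_depth = raw$max_depth %||% 5,
    replicates = raw$replicates %||% 1,
    max_processes = raw$max_processes %||% 1,
    seed = raw$seed %||% 1,
    n_interp = raw$n_interp %||% 100
  )
  dims <- vapply(partition_groups(problem), `[[`, integer(1), "n")
  check_recommended_m(settings, dims)
  structure(
    list(problem = problem, settings = settings,
         evaluator_spec = raw$evaluator, output = raw$output %||% "."),
    class = "stop_config"
  )
}

#' Build an evaluator from a config's evaluator spec
#'
#' @param config a `stop_config` from [load_config()].
#' @param workdir working directory for external-command interchange files.
#' @return an evaluator `function(params, streams)`.
#' @export
build_evaluator <- function(config, workdir = tempdir()) {
  spec <- config$evaluator_spec
  if (is.null(spec) || is.null(spec$type)) {
    stop("config declares no evaluator")
  }
  if (spec$type == "synthetic") {
    landscape <- if (identical(spec$landscape, "random")) {
      random_landscape(spec$dimension %||% 2, spec$h %||% 5,
                       spec$seed %||% config$settings$seed)
    } else {
      worked_example(spec$landscape)
    }
    synthetic_evaluator(landscape, noise_sd = spec$noise_sd %||%
                                     landscape$noise_sd)
  } else if (spec$type == "external") {
    if (is.null(spec$executable)) stop("external evaluator needs 'executable'")
    cmd <- external_command(spec$executable,
                            args = unlist(spec$args) %||% character(0),
                            metrics = names(config$problem$metrics))
    external_evaluator(cmd, workdir = workdir)
  } else {
    stop("unknown evaluator type: '", spec$type, "'")
  }
}

#' Run the optimization described by a config
#'
#' @param config a `stop_config` (or a path to one).
#' @param workdir working directory for external evaluators.
#' @return an `optimization_report`.
#' @export
run_config <- function(config, workdir = tempdir()) {
  if (is.character(config)) config <- load_config(config)
  run_optimization(config$problem, build_evaluator(config, workdir),
                   config$settings)
}
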