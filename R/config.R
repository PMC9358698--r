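# Plain-text (YAML) configuration files.
#
# A config file holds any subset of the model's knobs in named sections;
# everything left unspecified falls back to the package defaults.  Unknown
# keys are rejected rather than silently ignored, so a typo cannot
# masquerade as a default.

.config_sections <- c("params", "initial", "forcing", "solver", "simulation",
                      "arrhenius_exclusions")
.solver_keys <- c("method", "rtol", "atol")
.simulation_keys <- c("t_end", "output_step")

#' Load a simulation configuration from a YAML file
#'
#' Recognised sections: \code{params} (any ecosystem parameter by name),
#' \code{initial} (any of the 13 state variables), \code{forcing} (any
#' seasonal forcing parameter), \code{solver} (\code{method},
#' \code{rtol}, \code{atol}), \code{simulation} (\code{t_end},
#' \code{output_step}) and \code{arrhenius_exclusions} (a list of rate
#' parameter names exempted from temperature correction).  An empty file
#' yields the full default configuration; an unknown section or key is a
#' validation error naming it.
#'
#' @param path Path to a YAML config file.
#' @return A [simulation_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(cfg), .config_sections)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  params <- do.call(default_ecosystem_params,
                    as.list(cfg$params %||% list()))
  if (!is.null(cfg$forcing)) {
    fdef <- forcing_params()
    unknown <- setdiff(names(cfg$forcing), names(fdef))
    if (length(unknown))
      stop("unknown forcing key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    params$forcing <- do.call(forcing_params, cfg$forcing)
  }
  if (!is.null(cfg$arrhenius_exclusions)) {
    params$arrhenius_exclusions <- as.character(cfg$arrhenius_exclusions)
    validate_ecosystem_params(params)
  }
  initial <- do.call(default_initial_state,
                     as.list(cfg$initial %||% list()))

  solver <- cfg$solver %||% list()
  unknown <- setdiff(names(solver), .solver_keys)
  if (length(unknown))
    stop("unknown solver key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sim <- cfg$simulation %||% list()
  unknown <- setdiff(names(sim), .simulation_keys)
  if (length(unknown))
    stop("unknown simulation key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  simulation_config(params = params, initial_state = initial,
                    t_end = sim$t_end %||% 1825,
                    output_step = sim$output_step %||% 1,
                    method = solver$method %||% "lsoda",
                    rtol = solver$rtol %||% 1e-8,
                    atol = solver$atol %||% 1e-10)
}

#' Write a simulation configuration to a YAML file
#'
#' Serialises every parameter, initial value, forcing constant and solver
#' setting explicitly, so the file documents the run completely and
#' re-loads to an identical configuration.
#'
#' @param config A [simulation_config()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  p <- config$params
  scalar_params <- p[setdiff(names(p), c("forcing", "arrhenius_exclusions"))]
  yaml::write_yaml(list(
    params = scalar_params,
    forcing = unclass(p$forcing),
    arrhenius_exclusions = as.list(p$arrhenius_exclusions),
    initial = as.list(config$initial_state),
    solver = list(method = config$method, rtol = config$rtol,
                  atol = config$atol),
    simulation = list(t_end = config$t_end,
                      output_step = config$output_step)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
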