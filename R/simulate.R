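# Integration driver, configuration and trajectory I/O.

#' Simulation configuration
#'
#' Bundles everything a run needs: the parameter record, the initial
#' state, the time horizon and output step, and the solver settings.  The
#' system is stiff — the decomposer conductance (14.5/d) coexists with
#' slowly turning-over detritus pools — so the default solver is the
#' adaptive stiff-capable \code{lsoda} at tight tolerances.
#'
#' @param params An \code{"ecosystem_params"} record.
#' @param initial_state Named 13-component state vector.
#' @param t_end End time (days), \code{> 0}.
#' @param output_step Output sampling interval (days), \code{> 0};
#'   peak detection needs 1-day sampling or finer.
#' @param method deSolve integration method name.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @return A list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(params = default_ecosystem_params(),
                              initial_state = default_initial_state(),
                              t_end = 1825, output_step = 1,
                              method = "lsoda",
                              rtol = 1e-8, atol = 1e-10) {
  validate_ecosystem_params(params)
  if (length(initial_state) != 13L ||
      !identical(names(initial_state), .state_names))
    stop("`initial_state` must be named over ecosystem_state_names()",
         call. = FALSE)
  if (any(initial_state < 0))
    stop("initial state must be non-negative", call. = FALSE)
  if (t_end < 0) stop("`t_end` must be >= 0", call. = FALSE)
  if (output_step <= 0) stop("`output_step` must be > 0", call. = FALSE)
  if (rtol <= 0 || atol <= 0) stop("tolerances must be > 0", call. = FALSE)
  structure(list(params = params, initial_state = initial_state,
                 t_end = t_end, output_step = output_step,
                 method = method, rtol = rtol, atol = atol),
            class = "simulation_config")
}

#' Run the ecosystem simulation
#'
#' Integrates [ecosystem_derivatives()] from time 0 to \code{t_end} with
#' deSolve, recording the state at every multiple of \code{output_step}
#' and the conserved carbon and nitrogen totals per row.  The right-hand
#' side is evaluated on the state floored at zero; if the solver ever
#' presents a material pool below \code{-1e-9} times the initial
#' total-carbon scale the run is aborted with the failing time and state
#' rather than silently clipped.  The ammonia balance \code{M_N} is
#' exempt from the abort: the stoichiometric closure can demand more
#' nitrogen than the free pool holds (consumers assimilating
#' nitrogen-poor food into nitrogen-bearing reserve draw on ammonia with
#' no saturation in \code{M_N}), so \code{M_N} may run a transient
#' bookkeeping deficit, during which nitrogen-reserve synthesis sees
#' zero ammonia.  Conservation of total nitrogen is unaffected.
#' Identical configurations give identical output: nothing in
#' the model is stochastic.
#'
#' @param config A [simulation_config()].
#' @return A data frame of class \code{"eco_trajectory"} with columns
#'   \code{time}, the 13 state variables, \code{total_C} and
#'   \code{total_N}; the configuration is attached as attribute
#'   \code{"config"}.
#' @export
run_simulation <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  p <- config$params
  y0 <- config$initial_state
  floor_tol <- 1e-9 * conserved_totals(y0, p)[["total_C"]]
  material <- seq_len(12L)   # all pools except the ammonia balance
  rhs <- function(t, y, parms) {
    if (any(y[material] < -floor_tol)) {
      bad <- .state_names[material][y[material] < -floor_tol]
      stop("state went negative beyond the floor at t = ", signif(t, 8),
           ": ", paste(bad, collapse = ", "), call. = FALSE)
    }
    list(ecosystem_derivatives(t, pmax(y, 0), parms))
  }
  times <- seq(0, config$t_end, by = config$output_step)
  if (config$t_end == 0) {
    out <- matrix(c(0, y0), nrow = 1,
                  dimnames = list(NULL, c("time", .state_names)))
  } else {
    sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = p,
                        method = config$method,
                        rtol = config$rtol, atol = config$atol)
    if (attr(sol, "istate")[1] < 0)
      stop("solver failed at t = ", max(sol[, 1]), call. = FALSE)
    out <- unclass(sol)
    colnames(out) <- c("time", .state_names)
  }
  traj <- as.data.frame(out)
  pools <- as.matrix(traj[.state_names[1:11]])
  traj$total_C <- rowSums(pools) + traj$M_C
  traj$total_N <- as.vector(pools %*% .n_N_vector(p)) + traj$M_N
  structure(traj, config = config,
            class = c("eco_trajectory", "data.frame"))
}

#' @export
print.eco_trajectory <- function(x, ...) {
  cat(sprintf("Ecosystem trajectory: %d samples over %g days\n",
              nrow(x), max(x$time)))
  drift <- function(v) max(abs(v - v[1])) / abs(v[1])
  cat(sprintf("  carbon drift %.2e, nitrogen drift %.2e (relative)\n",
              drift(x$total_C), drift(x$total_N)))
  cat("  final state:\n")
  print(signif(unlist(x[nrow(x), .state_names]), 4))
  invisible(x)
}

#' Detect prominent annual peaks in a trajectory variable
#'
#' Local maxima of the sampled series within a time window, filtered by
#' topographic prominence: a maximum counts as a peak only if it stands
#' above its connecting saddles by at least \code{prominence} times the
#' range of the series in the window.  With the default 5 percent
#' threshold the two seasonal producer blooms are robustly separated from
#' numerical ripple.
#'
#' @param traj An \code{"eco_trajectory"} (or data frame with a
#'   \code{time} column).
#' @param variable Column name to analyse, e.g. \code{"M_VP"}.
#' @param window Length-2 numeric, time window \code{[t0, t1]} within the
#'   trajectory span.
#' @param prominence Minimum prominence as a fraction of the window's
#'   (max - min).
#' @return List with \code{count}, \code{times} (peak times, days),
#'   \code{values}, and \code{day_of_year} (\code{times mod 365}).
#' @export
detect_annual_peaks <- function(traj, variable, window,
                                prominence = 0.05) {
  if (!variable %in% names(traj))
    stop("unknown variable `", variable, "`", call. = FALSE)
  if (length(window) != 2L || window[2] <= window[1])
    stop("`window` must be an increasing [t0, t1] pair", call. = FALSE)
  sel <- traj$time >= window[1] & traj$time <= window[2]
  if (!any(sel)) stop("`window` lies outside the trajectory", call. = FALSE)
  tt <- traj$time[sel]
  y <- traj[[variable]][sel]
  n <- length(y)
  rng <- max(y) - min(y)
  if (rng == 0 || n < 3L)
    return(list(count = 0L, times = numeric(0), values = numeric(0),
                day_of_year = numeric(0)))
  is_max <- which(diff(sign(diff(y))) < 0) + 1L
  keep <- logical(length(is_max))
  for (j in seq_along(is_max)) {
    i <- is_max[j]
    # saddle depth towards the nearest higher ground (or window edge)
    left <- y[seq_len(i - 1L)]
    higher_l <- which(left > y[i])
    base_l <- if (length(higher_l)) min(left[max(higher_l):(i - 1L)])
              else min(left)
    right <- y[(i + 1L):n]
    higher_r <- which(right > y[i])
    base_r <- if (length(higher_r)) min(right[1:min(higher_r)])
              else min(right)
    keep[j] <- (y[i] - max(base_l, base_r)) >= prominence * rng
  }
  pk <- is_max[keep]
  list(count = length(pk), times = tt[pk], values = y[pk],
       day_of_year = tt[pk] %% 365)
}

#' Write and read a trajectory as CSV
#'
#' Writes \code{time}, the 13 state variables and the conserved totals as
#' a 16-column CSV at full double precision (17 significant digits), so a
#' write-read round trip is bit-exact.
#'
#' @param traj An \code{"eco_trajectory"}.
#' @param path Output file path.
#' @return \code{write_trajectory}: \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  cols <- c("time", .state_names, "total_C", "total_N")
  header <- paste(cols, collapse = ",")
  body <- do.call(paste, c(lapply(traj[cols], function(v)
    sprintf("%.17g", v)), sep = ","))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @return \code{read_trajectory}: the trajectory data frame.
#' @export
read_trajectory <- function(path) {
  traj <- utils::read.csv(path, check.names = FALSE,
                          colClasses = "numeric")
  structure(traj, class = c("eco_trajectory", "data.frame"))
}
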