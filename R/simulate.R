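# integrator noise tolerance: components in (-.NEG_CLIP_TOL, 0) are clipped
# to zero in post-processing; anything more negative is a model/solver error
.NEG_CLIP_TOL <- 1e-9

# deSolve-facing wrapper around the bare right-hand side
.desolve_func <- function(t, y, p) {
  if (any(!is.finite(y)))
    stop("non-finite state at t = ", t, " for: ",
         paste(metabolite_names()[!is.finite(y)], collapse = ", "),
         call. = FALSE)
  list(.rhs_unchecked(y, p))
}

# clip tiny negative integrator noise, error on anything substantial
.clip_states <- function(states) {
  neg <- states < 0
  if (any(neg)) {
    worst <- min(states[neg])
    if (worst <= -.NEG_CLIP_TOL)
      stop(sprintf(paste0("negative concentration %.3e beyond the noise ",
                          "tolerance %.0e; integration is not trustworthy"),
                   worst, .NEG_CLIP_TOL), call. = FALSE)
    states[neg] <- 0
  }
  list(states = states, clipped = sum(neg))
}

#' Integrate the metabolic model
#'
#' Solves the 11-dimensional system with a stiff-capable adaptive solver
#' (lsoda, which switches between Adams and BDF methods as stiffness
#' demands) and returns the solution on a regular output grid. Output is
#' deterministic: identical inputs give bit-identical trajectories.
#'
#' Two flow-direction diagnostics are tracked: the gradients `G - g_E` and
#' `g_E - g_r` are expected to remain positive (glucose flows choroid to
#' RPE to rods). A violation is flagged in the diagnostics, never silently
#' altered. Components a rounding error below zero (within 1e-9 mM) are
#' clipped to zero and counted; more negative values raise an error.
#'
#' @param params A `rpe_params` object.
#' @param init Initial state (defaults to [default_initial_state()]).
#' @param duration Integration horizon in minutes, > 0.
#' @param output_step Output grid spacing in minutes, > 0 (default 1).
#' @param rtol,atol Solver relative/absolute error tolerances.
#' @return A `rpe_trajectory` object: list with `times` (min), `states`
#'   (matrix, one row per time, columns [metabolite_names()]), `params`,
#'   and `diagnostics` (`solver_ok`, `clipped`, `gradient_G_gE_ok`,
#'   `gradient_gE_gr_ok`).
#' @export
#' @examples
#' tr <- integrate_model(default_parameters(), duration = 10)
#' tail(tr$states[, "g_E"], 3)
integrate_model <- function(params, init = default_initial_state(),
                            duration, output_step = 1,
                            rtol = 1e-8, atol = 1e-10) {
  params <- validate_parameters(params)
  init <- validate_state(init)
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration)
      || duration <= 0)
    stop("duration must be a positive number of minutes", call. = FALSE)
  if (!is.numeric(output_step) || output_step <= 0)
    stop("output_step must be positive", call. = FALSE)
  times <- seq(0, duration, by = output_step)
  if (times[length(times)] < duration) times <- c(times, duration)

  out <- deSolve::ode(y = unname(init), times = times, func = .desolve_func,
                      parms = params, method = "lsoda",
                      rtol = rtol, atol = atol)
  istate <- attr(out, "istate")[1L]
  solver_ok <- !is.null(istate) && istate >= 0 && nrow(out) == length(times)
  if (!solver_ok) {
    last <- out[nrow(out), ]
    stop(sprintf("solver failed at t = %.6g min; last state: %s",
                 last[1L],
                 paste(sprintf("%s=%.4g", metabolite_names(), last[-1L]),
                       collapse = ", ")), call. = FALSE)
  }
  states <- out[, -1L, drop = FALSE]
  colnames(states) <- metabolite_names()
  cl <- .clip_states(states)
  states <- cl$states

  structure(list(
    times = times,
    states = states,
    params = params,
    diagnostics = list(
      solver_ok = TRUE,
      clipped = cl$clipped,
      gradient_G_gE_ok = all(params$G - states[, "g_E"] > 0),
      gradient_gE_gr_ok = all(states[, "g_E"] - states[, "g_r"] > 0))),
    class = "rpe_trajectory")
}

#' @export
print.rpe_trajectory <- function(x, ...) {
  cat(sprintf("Metabolic trajectory: %d time points over %.6g min\n",
              length(x$times), x$times[length(x$times)]))
  cat(sprintf("  GLUT1 = %g, clipped points = %d, gradients ok = %s/%s\n",
              x$params$GLUT1, x$diagnostics$clipped,
              x$diagnostics$gradient_G_gE_ok,
              x$diagnostics$gradient_gE_gr_ok))
  cat("  terminal state (mM):\n")
  print(signif(x$states[nrow(x$states), ], 5))
  invisible(x)
}

#' Convert a trajectory to a data frame
#'
#' @param x A `rpe_trajectory`.
#' @param row.names,optional Ignored (S3 signature compatibility).
#' @param format `"tidy"` (columns `time_min`, `metabolite`,
#'   `concentration_mM`) or `"wide"` (one column per metabolite).
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.rpe_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE,
                                         format = c("tidy", "wide"), ...) {
  format <- match.arg(format)
  if (format == "wide")
    return(data.frame(time_min = x$times, x$states, check.names = FALSE))
  nm <- colnames(x$states)
  data.frame(
    time_min = rep(x$times, times = length(nm)),
    metabolite = rep(nm, each = length(x$times)),
    concentration_mM = as.vector(x$states))
}

#' Write a trajectory to CSV
#'
#' @param x A `rpe_trajectory`.
#' @param path Output path.
#' @param format `"tidy"` or `"wide"`; see [as.data.frame.rpe_trajectory()].
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(x, path, format = c("tidy", "wide")) {
  utils::write.csv(as.data.frame(x, format = match.arg(format)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Integrate to a steady state
#'
#' Integrates in check windows (default 100 min) up to `horizon` and
#' declares convergence when both criteria hold at a window boundary:
#' the residual `max |d state / dt|` is below `tol * max(1, max(state))`
#' and the relative change of every component over the last window is
#' below `drift_tol`. With `early_stop = TRUE` (the default) the
#' integration stops at the first window that satisfies both, so a state
#' that is already a fixed point returns after one window; with
#' `early_stop = FALSE` the full horizon is always integrated (this is
#' what the stepped GLUT1 sweep protocol uses, so every step advances the
#' same model time). The terminal state is returned even when not
#' converged.
#'
#' Terminal states are read from the solver's own step at the window
#' boundary, not interpolated from a dense grid.
#'
#' @param params A `rpe_params` object.
#' @param init Initial state.
#' @param horizon Maximum model time in minutes (default 1500).
#' @param tol Residual tolerance in mM/min, scaled by
#'   `max(1, max(abs(state)))` (default 1e-8).
#' @param drift_tol Maximum relative drift per component over the final
#'   check window (default 1e-3, i.e. 0.1%).
#' @param window Check-window length in minutes (default 100).
#' @param early_stop Stop at the first converged window?
#' @param rtol,atol Solver tolerances, as in [integrate_model()].
#' @return A `rpe_steady_state` object: list with `state`, `residual`
#'   (mM/min), `converged`, `horizon_used` (min), `drift`, `params`.
#' @export
find_steady_state <- function(params, init = default_initial_state(),
                              horizon = 1500, tol = 1e-8, drift_tol = 1e-3,
                              window = 100, early_stop = TRUE,
                              rtol = 1e-8, atol = 1e-10) {
  params <- validate_parameters(params)
  y <- validate_state(init)
  if (!is.numeric(horizon) || horizon <= 0)
    stop("horizon must be a positive number of minutes", call. = FALSE)
  if (window > horizon) window <- horizon

  t_now <- 0
  prev <- unname(y)
  converged <- FALSE
  residual <- NA_real_
  drift <- NA_real_
  if (!early_stop) {
    # fixed-horizon protocol: single solver run, criteria checked over the
    # final window only
    times <- if (horizon > window) c(0, horizon - window, horizon)
             else c(0, horizon)
    out <- deSolve::ode(y = prev, times = times, func = .desolve_func,
                        parms = params, method = "lsoda",
                        rtol = rtol, atol = atol)
    if (attr(out, "istate")[1L] < 0 || nrow(out) < length(times))
      stop("solver failed in steady-state search", call. = FALSE)
    cur <- out[nrow(out), -1L]
    before <- out[nrow(out) - 1L, -1L]
    residual <- max(abs(.rhs_unchecked(cur, params)))
    drift <- max(abs(cur - before) / pmax(abs(before), .NEG_CLIP_TOL))
    converged <- residual < tol * max(1, max(abs(cur))) && drift < drift_tol
    cl <- .clip_states(matrix(cur, nrow = 1L))
    state <- cl$states[1L, ]
    names(state) <- metabolite_names()
    return(structure(list(state = state, residual = residual,
                          converged = converged, horizon_used = horizon,
                          drift = drift, params = params),
                     class = "rpe_steady_state"))
  }
  repeat {
    step <- min(window, horizon - t_now)
    out <- deSolve::ode(y = prev, times = c(0, step), func = .desolve_func,
                        parms = params, method = "lsoda",
                        rtol = rtol, atol = atol)
    if (attr(out, "istate")[1L] < 0 || nrow(out) < 2L)
      stop(sprintf("solver failed near t = %.6g min in steady-state search",
                   t_now), call. = FALSE)
    cur <- out[2L, -1L]
    t_now <- t_now + step
    residual <- max(abs(.rhs_unchecked(cur, params)))
    drift <- max(abs(cur - prev) / pmax(abs(prev), .NEG_CLIP_TOL))
    ok <- residual < tol * max(1, max(abs(cur))) && drift < drift_tol
    prev <- cur
    converged <- ok  # status of the most recent check window
    if ((ok && early_stop) || t_now >= horizon) break
  }
  cl <- .clip_states(matrix(prev, nrow = 1L))
  state <- cl$states[1L, ]
  names(state) <- metabolite_names()
  structure(list(state = state, residual = residual,
                 converged = converged, horizon_used = t_now,
                 drift = drift, params = params),
            class = "rpe_steady_state")
}

#' @export
print.rpe_steady_state <- function(x, ...) {
  cat(sprintf(
    "Steady-state search: converged = %s (residual %.3e mM/min, drift %.3e, %g min)\n",
    x$converged, x$residual, x$drift, x$horizon_used))
  print(signif(x$state, 5))
  invisible(x)
}

#' Serialize a steady-state result to JSON
#'
#' @param x A `rpe_steady_state`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_steady_state_json <- function(x, path) {
  jsonlite::write_json(
    list(state = as.list(x$state), residual = x$residual,
         converged = x$converged, horizon_used = x$horizon_used,
         drift = x$drift),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
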