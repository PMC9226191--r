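# baseline steady-state values below this are treated as zero for
# normalization; relative values for such metabolites are NA, never Inf
.ZERO_BASELINE_TOL <- 1e-12

#' Healthy baseline protocol
#'
#' Runs the nominal 500-min trajectory from the shipped initial conditions
#' and then searches for the steady state that serves as the "healthy
#' concentration" baseline against which all relative (percent-of-nominal)
#' results are normalized. If the steady-state criteria are not met within
#' the horizon a warning is emitted and the result is returned with
#' `converged = FALSE`.
#'
#' @param params A `rpe_params` object.
#' @param duration Trajectory length in minutes (default 500).
#' @param horizon Steady-state search horizon in minutes (default 1500).
#' @return List with elements `trajectory` ([integrate_model()] result) and
#'   `steady_state` ([find_steady_state()] result).
#' @export
run_baseline <- function(params = default_parameters(), duration = 500,
                         horizon = 1500) {
  params <- validate_parameters(params)
  trajectory <- integrate_model(params, duration = duration)
  steady <- find_steady_state(params, horizon = horizon)
  if (!steady$converged)
    warning(sprintf(
      "baseline did not meet the steady-state criteria within %g min (residual %.3e, drift %.3e)",
      horizon, steady$residual, steady$drift), call. = FALSE)
  list(trajectory = trajectory, steady_state = steady)
}

#' Stepped GLUT1 modulation sweep
#'
#' Reproduces the transporter-deprivation protocol: the relative GLUT1
#' level is lowered along a strictly decreasing grid (default 1.00, 0.99,
#' ..., 0.00), the system is integrated for `horizon` minutes at each
#' level, and the terminal state is recorded. In `"continuation"` mode
#' (the default, matching the stated stepped protocol) each level starts
#' from the previous level's terminal state; in `"cold_start"` mode every
#' level starts from `init`.
#'
#' Each metabolite is also reported relative to the first grid point
#' (nominally GLUT1 = 1), scaled so that the nominal steady state is 100.
#' Metabolites whose baseline is below 1e-12 mM get `NA` relative values
#' rather than a division by (near) zero, and are flagged.
#'
#' @param params A `rpe_params` object (its `GLUT1` entry is overridden by
#'   the grid).
#' @param grid Strictly decreasing GLUT1 levels in \[0, 1\].
#' @param mode `"continuation"` or `"cold_start"`.
#' @param horizon Minutes integrated per grid point (default 1500).
#' @param init Initial state for the first step (continuation) or every
#'   step (cold start).
#' @return A `glut1_sweep` object: list with `glut1`, `states` (matrix,
#'   one row per level), `relative` (same shape, percent of nominal),
#'   `converged` (logical per level), `residuals`, `mode`, `horizon`,
#'   `zero_baseline` (metabolites with undefined relative values), and
#'   `params`.
#' @export
glut1_sweep <- function(params = default_parameters(),
                        grid = seq(1, 0, by = -0.01),
                        mode = c("continuation", "cold_start"),
                        horizon = 1500,
                        init = default_initial_state()) {
  params <- validate_parameters(params)
  mode <- match.arg(mode)
  init <- validate_state(init)
  if (length(grid) < 1L || any(!is.finite(grid)) ||
      any(grid < 0) || any(grid > 1))
    stop("grid must lie within [0, 1]", call. = FALSE)
  if (length(grid) > 1L && any(diff(grid) >= 0))
    stop("grid must be strictly decreasing", call. = FALSE)

  n <- length(grid)
  nm <- metabolite_names()
  states <- matrix(NA_real_, n, 11L, dimnames = list(NULL, nm))
  converged <- logical(n)
  residuals <- numeric(n)
  y <- init
  for (i in seq_len(n)) {
    p_i <- params
    p_i$GLUT1 <- grid[i]
    ss <- find_steady_state(p_i, init = y, horizon = horizon,
                            early_stop = FALSE)
    states[i, ] <- ss$state
    converged[i] <- ss$converged
    residuals[i] <- ss$residual
    if (mode == "continuation") y <- ss$state else y <- init
  }
  baseline <- states[1L, ]
  zero_baseline <- nm[baseline < .ZERO_BASELINE_TOL]
  relative <- sweep(states, 2L, baseline, "/") * 100
  relative[, zero_baseline] <- NA_real_

  structure(list(glut1 = grid, states = states, relative = relative,
                 converged = converged, residuals = residuals,
                 mode = mode, horizon = horizon,
                 zero_baseline = zero_baseline, params = params),
            class = "glut1_sweep")
}

#' @export
print.glut1_sweep <- function(x, ...) {
  cat(sprintf(
    "GLUT1 sweep (%s): %d levels from %.2f to %.2f, %g min per level\n",
    x$mode, length(x$glut1), x$glut1[1L], x$glut1[length(x$glut1)],
    x$horizon))
  cat(sprintf("  levels not meeting steady-state criteria: %d\n",
              sum(!x$converged)))
  if (length(x$zero_baseline))
    cat("  zero-baseline metabolites:",
        paste(x$zero_baseline, collapse = ", "), "\n")
  invisible(x)
}

#' Convert a sweep to a tidy data frame
#'
#' @param x A `glut1_sweep`.
#' @param row.names,optional,... Ignored (S3 signature compatibility).
#' @return Data frame with columns `glut1`, `metabolite`, `absolute_mM`,
#'   `relative`, `converged`.
#' @export
as.data.frame.glut1_sweep <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  nm <- colnames(x$states)
  data.frame(
    glut1 = rep(x$glut1, times = length(nm)),
    metabolite = rep(nm, each = length(x$glut1)),
    absolute_mM = as.vector(x$states),
    relative = as.vector(x$relative),
    converged = rep(x$converged, times = length(nm)))
}

#' Write a sweep as tidy CSV
#'
#' @param x A `glut1_sweep`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

# locate a GLUT1 level on the sweep grid, within tolerance
.grid_index <- function(sweep, level, tol = 1e-8) {
  i <- which(abs(sweep$glut1 - level) < tol)
  if (!length(i))
    stop(sprintf("GLUT1 level %.4g is not on the sweep grid", level),
         call. = FALSE)
  i[1L]
}

#' Match relative metabolite targets to a GLUT1 level
#'
#' Given target relative concentrations (on the 0--100 percent-of-control
#' scale, e.g. group medians of relative metabolite intensities from a
#' knockout cohort), finds the sweep grid point whose relative steady
#' state minimizes the Euclidean distance over the selected metabolites.
#' By default the two rod metabolites a transporter-knockout experiment
#' measures, glucose (`g_r`) and lactate (`LACT_r`), are used. Ties are
#' broken towards the larger GLUT1 level, i.e. the least-perturbed
#' interpretation.
#'
#' @param sweep A `glut1_sweep`.
#' @param targets Named numeric vector of target relative values; must
#'   contain every name in `metabolites`.
#' @param metabolites Metabolites entering the distance (non-empty).
#' @return A `glut1_match` object: list with `best_glut1`, `distance`, and
#'   `per_metabolite_residuals` (sweep minus target at the optimum).
#' @export
match_glut1 <- function(sweep, targets,
                        metabolites = c("g_r", "LACT_r")) {
  if (!inherits(sweep, "glut1_sweep"))
    stop("sweep must be a glut1_sweep object", call. = FALSE)
  if (length(metabolites) == 0L)
    stop("at least one metabolite must be selected for matching",
         call. = FALSE)
  bad <- setdiff(metabolites, colnames(sweep$relative))
  if (length(bad))
    stop("unknown metabolite(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(names(targets)) || !all(metabolites %in% names(targets)))
    stop("targets must be named and cover: ",
         paste(metabolites, collapse = ", "), call. = FALSE)
  tg <- as.numeric(targets[metabolites])
  rel <- sweep$relative[, metabolites, drop = FALSE]
  if (anyNA(rel))
    stop("selected metabolites include undefined (zero-baseline) relative values",
         call. = FALSE)
  d2 <- rowSums((rel - matrix(tg, nrow(rel), length(tg), byrow = TRUE))^2)
  # grid is strictly decreasing, so the first minimum is the largest GLUT1
  best <- which.min(d2)
  structure(list(
    best_glut1 = sweep$glut1[best],
    distance = sqrt(d2[best]),
    per_metabolite_residuals =
      stats::setNames(rel[best, ] - tg, metabolites),
    metabolites = metabolites), class = "glut1_match")
}

#' @export
print.glut1_match <- function(x, ...) {
  cat(sprintf("Best-matching GLUT1 level: %.2f (distance %.4g)\n",
              x$best_glut1, x$distance))
  print(signif(x$per_metabolite_residuals, 4))
  invisible(x)
}

#' One-at-a-time parameter sensitivity
#'
#' Scales a single parameter by each multiplier, holds everything else at
#' its nominal value, and records the resulting steady state (cold start
#' from `init`, fixed `horizon` per run, the same protocol as a cold-start
#' sweep step). All perturbed parameter sets are validated before any
#' integration starts, so an out-of-range perturbation (e.g. pushing
#' `rho_r` above 1) fails fast. Results are reported both in absolute mM
#' and relative to the unperturbed (multiplier 1) steady state, which is
#' computed whether or not 1 is among the multipliers.
#'
#' @param params A `rpe_params` object.
#' @param parameter_name Name of the parameter to perturb.
#' @param multipliers Positive multiplicative perturbations.
#' @param horizon Minutes integrated per run (default 1500).
#' @param init Initial state for every run.
#' @return An `oat_sensitivity` object: list with `parameter`,
#'   `multipliers`, `values`, `states`, `relative` (percent of
#'   unperturbed), `converged`.
#' @export
oat_sensitivity <- function(params = default_parameters(), parameter_name,
                            multipliers, horizon = 1500,
                            init = default_initial_state()) {
  params <- validate_parameters(params)
  if (!is.character(parameter_name) || length(parameter_name) != 1L ||
      !(parameter_name %in% .param_fields))
    stop("parameter_name must be one of the model parameter fields",
         call. = FALSE)
  if (!is.numeric(multipliers) || !length(multipliers) ||
      any(!is.finite(multipliers)) || any(multipliers <= 0))
    stop("multipliers must be positive numbers", call. = FALSE)

  # validate every perturbed set before integrating anything
  perturbed <- lapply(multipliers, function(m) {
    p <- params
    p[[parameter_name]] <- p[[parameter_name]] * m
    validate_parameters(p)
  })
  base_p <- params  # multiplier 1 reference

  run_one <- function(p) find_steady_state(p, init = init,
                                           horizon = horizon,
                                           early_stop = FALSE)
  base_ss <- run_one(base_p)
  nm <- metabolite_names()
  states <- matrix(NA_real_, length(multipliers), 11L,
                   dimnames = list(NULL, nm))
  converged <- logical(length(multipliers))
  for (i in seq_along(multipliers)) {
    ss <- if (multipliers[i] == 1) base_ss else run_one(perturbed[[i]])
    states[i, ] <- ss$state
    converged[i] <- ss$converged
  }
  baseline <- base_ss$state
  relative <- sweep(states, 2L, baseline, "/") * 100
  relative[, baseline < .ZERO_BASELINE_TOL] <- NA_real_

  structure(list(parameter = parameter_name, multipliers = multipliers,
                 values = params[[parameter_name]] * multipliers,
                 states = states, relative = relative,
                 converged = converged),
            class = "oat_sensitivity")
}

#' @export
print.oat_sensitivity <- function(x, ...) {
  cat(sprintf("One-at-a-time sensitivity of '%s' (%d multipliers)\n",
              x$parameter, length(x$multipliers)))
  print(signif(x$relative, 4))
  invisible(x)
}

#' Convert a sensitivity scan to a tidy data frame
#'
#' @param x An `oat_sensitivity`.
#' @param row.names,optional,... Ignored (S3 signature compatibility).
#' @return Data frame with columns `parameter`, `multiplier`, `value`,
#'   `metabolite`, `absolute_mM`, `relative`.
#' @export
as.data.frame.oat_sensitivity <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  nm <- colnames(x$states)
  data.frame(
    parameter = x$parameter,
    multiplier = rep(x$multipliers, times = length(nm)),
    value = rep(x$values, times = length(nm)),
    metabolite = rep(nm, each = length(x$multipliers)),
    absolute_mM = as.vector(x$states),
    relative = as.vector(x$relative))
}
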