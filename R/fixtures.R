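# run a generator body under a fixed seed without disturbing the caller's
# RNG stream
.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single number", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# multiplicative Gaussian noise with coefficient of variation cv, floored
# at zero so concentrations stay physical
.noisy <- function(truth, cv, n) {
  pmax(truth * (1 + cv * stats::rnorm(n)), 0)
}

#' Synthetic replicate metabolite time series
#'
#' Generates a pseudo-experimental dataset with the structure of a
#' metabolic labeling time course: the model trajectory is sampled at a
#' handful of time points and each sample is replicated with independent
#' multiplicative Gaussian noise (coefficient of variation `noise_cv`,
#' values floored at 0). The default design is 6 time points spanning the
#' initial transient with n = 3 replicates each, for rod lactate, rod
#' pyruvate and RPE pyruvate. With `noise_cv = 0` the replicates collapse
#' exactly onto the simulator output.
#'
#' @param params A `rpe_params` object.
#' @param timepoints Sampling times in minutes, non-negative.
#' @param n_reps Replicates per time point (default 3).
#' @param noise_cv Coefficient of variation of the noise (default 0.15).
#' @param seed RNG seed; regeneration with the same seed is bit-identical.
#' @param metabolites Metabolites to report.
#' @param init Initial state for the underlying simulation.
#' @return A `synthetic_cohort` object with `design = "timeseries"`:
#'   `data` (tidy data frame: `metabolite`, `time_min`, `replicate`,
#'   `value_mM`), `summary` (per-point mean, standard error and the
#'   noiseless truth), and `generating` (parameters, noise model, seed).
#' @export
synth_timeseries <- function(params = default_parameters(),
                             timepoints = c(0, 5, 15, 30, 60, 120),
                             n_reps = 3, noise_cv = 0.15, seed = 1,
                             metabolites = c("LACT_r", "PYR_r", "PYR_E"),
                             init = default_initial_state()) {
  params <- validate_parameters(params)
  init <- validate_state(init)
  if (!length(timepoints) || any(!is.finite(timepoints)) ||
      any(timepoints < 0))
    stop("timepoints must be non-negative and non-empty", call. = FALSE)
  if (!is.numeric(noise_cv) || length(noise_cv) != 1L || noise_cv < 0)
    stop("noise_cv must be >= 0", call. = FALSE)
  if (!is.numeric(n_reps) || n_reps < 1)
    stop("n_reps must be at least 1", call. = FALSE)
  bad <- setdiff(metabolites, metabolite_names())
  if (length(bad))
    stop("unknown metabolite(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  tp <- sort(unique(timepoints))
  times <- sort(unique(c(0, tp)))
  out <- deSolve::ode(y = unname(init), times = times,
                      func = .desolve_func, parms = params,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  truth <- out[match(tp, times), -1L, drop = FALSE]
  colnames(truth) <- metabolite_names()

  rows <- .with_seed(seed, {
    do.call(rbind, lapply(metabolites, function(m) {
      do.call(rbind, lapply(seq_along(tp), function(i) {
        data.frame(metabolite = m, time_min = tp[i],
                   replicate = seq_len(n_reps),
                   value_mM = .noisy(truth[i, m], noise_cv, n_reps))
      }))
    }))
  })
  agg <- do.call(rbind, lapply(split(rows, rows[c("metabolite", "time_min")],
                                     drop = TRUE), function(d) {
    data.frame(metabolite = d$metabolite[1L], time_min = d$time_min[1L],
               mean_mM = mean(d$value_mM),
               se_mM = stats::sd(d$value_mM) / sqrt(nrow(d)))
  }))
  agg <- agg[order(match(agg$metabolite, metabolites), agg$time_min), ]
  agg$truth_mM <- mapply(function(t, m) truth[match(t, tp), m],
                         agg$time_min, agg$metabolite)
  rownames(agg) <- NULL

  structure(list(design = "timeseries", data = rows, summary = agg,
                 generating = list(params = params, timepoints = tp,
                                   n_reps = n_reps, noise_cv = noise_cv,
                                   seed = seed, metabolites = metabolites)),
            class = "synthetic_cohort")
}

#' Scale measurements to the control-group median
#'
#' The relative-intensity normalization used for knockout cohorts: every
#' value is divided by the median of the control observations and
#' multiplied by 100, so the control median becomes exactly 100. The
#' operation is idempotent.
#'
#' @param values Numeric measurements (one metabolite).
#' @param is_control Logical mask of control observations.
#' @return Rescaled values.
#' @export
scale_by_control_median <- function(values, is_control) {
  if (length(values) != length(is_control))
    stop("values and is_control must have equal length", call. = FALSE)
  m <- stats::median(values[is_control])
  if (!is.finite(m) || m <= 0)
    stop("control median must be strictly positive", call. = FALSE)
  values / m * 100
}

#' Synthetic knockout cohort of relative metabolite intensities
#'
#' Emulates a transporter-knockout experiment read out by relative mass
#' spectrometry intensities: rod glucose and lactate steady states are
#' computed at a small set of GLUT1 levels (control plus knockouts) along
#' the stepped continuation sweep, each specimen receives independent
#' multiplicative noise, and all values are scaled so the control-group
#' median is exactly 100 per metabolite. The default design is three
#' groups of 6/4/6 specimens at GLUT1 levels 1.0 (control), 0.44 (medium
#' knockout) and 0.18 (high knockout).
#'
#' The first level is the control group. Levels must lie on the sweep
#' grid implied by `grid_step`.
#'
#' @param params A `rpe_params` object.
#' @param glut1_levels GLUT1 level per group; first entry is the control.
#' @param group_sizes Specimens per group.
#' @param noise_cv Coefficient of variation of the per-specimen noise.
#' @param seed RNG seed.
#' @param metabolites Metabolites measured (default rod glucose/lactate).
#' @param grid_step Sweep grid resolution (default 0.01).
#' @param horizon Minutes per sweep step (default 1500).
#' @param sweep Optionally, a precomputed continuation [glut1_sweep()]
#'   covering all levels, to avoid recomputing it.
#' @return A `synthetic_cohort` object with `design = "knockout"`:
#'   `data` (tidy data frame: `group`, `glut1`, `specimen`, `metabolite`,
#'   `value`, `relative`), `group_medians` (relative medians per group and
#'   metabolite), `sweep` (the sweep used), and `generating`.
#' @export
synth_knockout_cohort <- function(params = default_parameters(),
                                  glut1_levels = c(1.0, 0.44, 0.18),
                                  group_sizes = c(6, 4, 6),
                                  noise_cv = 0.15, seed = 1,
                                  metabolites = c("g_r", "LACT_r"),
                                  grid_step = 0.01, horizon = 1500,
                                  sweep = NULL) {
  params <- validate_parameters(params)
  if (length(glut1_levels) != length(group_sizes))
    stop("glut1_levels and group_sizes must have equal length",
         call. = FALSE)
  if (any(glut1_levels < 0 | glut1_levels > 1))
    stop("glut1_levels must lie in [0, 1]", call. = FALSE)
  if (any(group_sizes < 1))
    stop("group_sizes must be positive", call. = FALSE)
  if (!is.numeric(noise_cv) || noise_cv < 0)
    stop("noise_cv must be >= 0", call. = FALSE)

  if (is.null(sweep)) {
    grid <- seq(1, min(glut1_levels), by = -grid_step)
    sweep <- glut1_sweep(params, grid = grid, mode = "continuation",
                         horizon = horizon)
  }
  idx <- vapply(glut1_levels, function(l) .grid_index(sweep, l), integer(1))
  truth <- sweep$states[idx, metabolites, drop = FALSE]

  raw <- .with_seed(seed, {
    do.call(rbind, lapply(seq_along(glut1_levels), function(k) {
      n <- group_sizes[k]
      do.call(rbind, lapply(metabolites, function(m) {
        data.frame(group = k, glut1 = glut1_levels[k],
                   specimen = seq_len(n), metabolite = m,
                   value = .noisy(truth[k, m], noise_cv, n))
      }))
    }))
  })
  raw$relative <- NA_real_
  for (m in metabolites) {
    sel <- raw$metabolite == m
    raw$relative[sel] <- scale_by_control_median(raw$value[sel],
                                                 raw$group[sel] == 1L)
  }
  med <- do.call(rbind, lapply(seq_along(glut1_levels), function(k) {
    vals <- vapply(metabolites, function(m)
      stats::median(raw$relative[raw$group == k & raw$metabolite == m]),
      numeric(1))
    data.frame(group = k, glut1 = glut1_levels[k], t(vals))
  }))

  structure(list(design = "knockout", data = raw, group_medians = med,
                 sweep = sweep,
                 generating = list(params = params,
                                   glut1_levels = glut1_levels,
                                   group_sizes = group_sizes,
                                   noise_cv = noise_cv, seed = seed,
                                   metabolites = metabolites,
                                   grid_step = grid_step,
                                   horizon = horizon)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort (%s design), %d observations, seed %g, cv %g\n",
              x$design, nrow(x$data), x$generating$seed,
              x$generating$noise_cv))
  if (x$design == "knockout") print(x$group_medians)
  invisible(x)
}

#' Write a synthetic cohort to CSV with a JSON sidecar
#'
#' The tidy observation table goes to `path`; the generating parameters,
#' noise model and seed go to a `.json` sidecar next to it so the cohort
#' can be regenerated exactly.
#'
#' @param x A `synthetic_cohort`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(x, path) {
  utils::write.csv(x$data, path, row.names = FALSE)
  gen <- x$generating
  gen$params <- unclass(gen$params)
  jsonlite::write_json(c(list(design = x$design), gen),
                       paste0(sub("\\.csv$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Convert a protein-normalized intensity to a molar concentration
#'
#' Converts a metabolite amount expressed per unit protein (pmol per
#' microgram of protein) into a tissue concentration (mM), assuming a
#' homogenate protein concentration in mg/ml. The dimensional chain:
#' pmol/ug-protein equals nmol/mg-protein; multiplying by the protein
#' concentration (mg/ml) gives nmol/ml = umol/l; dividing by 1000
#' converts to mmol/l = mM. At the default 20 mg/ml the factor is
#' `20 * 1e-3 = 0.02` mM per (pmol/ug).
#'
#' @param value Intensity in pmol per microgram protein, >= 0.
#' @param protein_conc Assumed protein concentration in mg/ml, > 0
#'   (default 20).
#' @return Concentration in mM.
#' @export
#' @examples
#' convert_intensity(50)  # 1 mM
convert_intensity <- function(value, protein_conc = 20) {
  if (!is.numeric(protein_conc) || length(protein_conc) != 1L ||
      !is.finite(protein_conc) || protein_conc <= 0)
    stop("protein_conc must be strictly positive", call. = FALSE)
  if (any(!is.finite(value)) || any(value < 0))
    stop("value must be non-negative", call. = FALSE)
  value * protein_conc * 1e-3
}
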