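#' Metabolite names, in state-vector order
#'
#' The model tracks 11 metabolite concentrations: four in the retinal
#' pigment epithelium (RPE, suffix `_E`) and seven in the rod
#' photoreceptors (suffix `_r`). The ordering is fixed; every state vector,
#' trajectory column and right-hand-side component in the package uses it,
#' so component `i` of the derivative corresponds to metabolite `i` here.
#'
#' @return Character vector of length 11.
#' @export
#' @examples
#' metabolite_names()
metabolite_names <- function() {
  c("g_E", "G6P_E", "F16BP_E", "PYR_E",
    "g_r", "G6P_r", "NADPH_r", "F16BP_r", "G3P_r", "PYR_r", "LACT_r")
}

# field order used for parameter objects and parameter files
.param_fields <- c(
  "G", "GLUT1", "c_M1",
  "lambda_E", "lambda_r", "lambda_LACT_Ex",
  "Vmax_g_E", "Km_g_E", "Vmax_G6P_E", "Km_G6P_E",
  "Vmax_F16BP_E", "Km_F16BP_E", "Vmax_PYR_E", "Km_PYR_E",
  "Vmax_PYR_rE", "Km_PYR_rE",
  "Vmax_g_r", "Km_g_r", "Vmax_G6P_r", "Km_G6P_r",
  "Vmax_NADPH_r", "Km_NADPH_r", "Vmax_F16BP_r", "Km_F16BP_r",
  "Vmax_PYR_r", "Km_PYR_r", "Vmax_G3P_r", "Km_G3P_r",
  "Vmax_LACT_r", "Km_LACT_r",
  "psi_PYR_E", "psi_NADPH_r", "psi_LACT_r", "psi_G3P_r",
  "PYR_E_star", "PEP_star", "q_r", "rho_r", "R_p", "delta_r")

#' Default (healthy, nominal) model parameters
#'
#' Returns the shipped nominal parameter set describing the healthy
#' RPE--rod unit: external choroidal glucose held at 5 mM, full relative
#' GLUT1 and MCT1 expression, and the kinetic constants of every lumped
#' reaction step. The same values are stored as a flat YAML file at
#' `system.file("extdata", "params_healthy.yaml", package = "rpemetab")`;
#' [load_parameters()] on that file reproduces this object exactly.
#'
#' Units: `Vmax_*` are mM/min, `Km_*`, `G`, `PYR_E_star`, `PEP_star` are mM,
#' `psi_*` are 1/min, `lambda_*` are 1/mM; `GLUT1`, `c_M1`, `q_r`, `rho_r`,
#' `R_p` and `delta_r` are dimensionless.
#'
#' Two entries deserve a note. `R_p` multiplies the linear clearance of
#' rod G3P; it has no tabulated nominal value, defaults to 1, and any
#' constant choice cancels out of steady-state ratios normalized to the
#' nominal state. `delta_r` is carried for fidelity to the nominal
#' parameter table but is referenced by no rate law; it is inert.
#'
#' @return A `rpe_params` object (named list of 40 numeric scalars).
#' @seealso [model_parameters()], [load_parameters()]
#' @export
default_parameters <- function() {
  p <- list(
    G = 5, GLUT1 = 1, c_M1 = 1,
    lambda_E = 0.8, lambda_r = 21.7e-3, lambda_LACT_Ex = 480,
    Vmax_g_E = 1.2, Km_g_E = 9,
    Vmax_G6P_E = 0.00738, Km_G6P_E = 0.002844,
    Vmax_F16BP_E = 1.2285, Km_F16BP_E = 0.1106,
    Vmax_PYR_E = 0.00783, Km_PYR_E = 0.17,
    Vmax_PYR_rE = 14, Km_PYR_rE = 0.125,
    Vmax_g_r = 0.8, Km_g_r = 8,
    Vmax_G6P_r = 0.1845, Km_G6P_r = 0.09,
    Vmax_NADPH_r = 0.228, Km_NADPH_r = 0.45,
    Vmax_F16BP_r = 1.365, Km_F16BP_r = 3.5,
    Vmax_PYR_r = 0.3915, Km_PYR_r = 0.06,
    Vmax_G3P_r = 0.15, Km_G3P_r = 0.143,
    Vmax_LACT_r = 0.14, Km_LACT_r = 1.25e-5,
    psi_PYR_E = 710, psi_NADPH_r = 15e2, psi_LACT_r = 96e2, psi_G3P_r = 0.02,
    PYR_E_star = 4.6e-5, PEP_star = 1.65e-13,
    q_r = 0.18, rho_r = 1e-3, R_p = 1.0, delta_r = 13e8)
  structure(p[.param_fields], class = "rpe_params")
}

#' Construct a validated parameter set
#'
#' Starts from [default_parameters()] and applies the supplied overrides,
#' then validates every invariant. Unknown names are rejected.
#'
#' @param ... Named numeric overrides, e.g. `GLUT1 = 0.5`.
#' @param base Parameter set to start from (default the shipped nominal set).
#' @return A validated `rpe_params` object.
#' @export
#' @examples
#' p <- model_parameters(GLUT1 = 0.5)
#' p$GLUT1
model_parameters <- function(..., base = default_parameters()) {
  overrides <- list(...)
  if (length(overrides)) {
    nms <- names(overrides)
    if (is.null(nms) || any(nms == ""))
      stop("all parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(nms, .param_fields)
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    base[nms] <- overrides
  }
  validate_parameters(base)
}

#' Validate a parameter set
#'
#' Checks that all 40 fields are present, numeric, finite scalars and that
#' the model invariants hold: `GLUT1` and `c_M1` in \[0, 1\], `q_r` strictly
#' inside (0, 1), `rho_r` in \[0, 1\], and every `Vmax_*`, `Km_*`, `psi_*`,
#' `lambda_*`, `G`, `PYR_E_star`, `PEP_star`, `R_p` strictly positive.
#' All violations are collected and reported in a single error.
#'
#' @param params A named list of parameter values.
#' @return The validated `rpe_params` object, fields in canonical order.
#' @export
validate_parameters <- function(params) {
  problems <- character()
  missing <- setdiff(.param_fields, names(params))
  if (length(missing))
    problems <- c(problems,
                  paste0("missing parameter(s): ",
                         paste(missing, collapse = ", ")))
  unknown <- setdiff(names(params), .param_fields)
  if (length(unknown))
    problems <- c(problems,
                  paste0("unknown parameter(s): ",
                         paste(unknown, collapse = ", ")))
  present <- intersect(.param_fields, names(params))
  for (f in present) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      problems <- c(problems,
                    paste0(f, " must be a finite numeric scalar"))
    }
  }
  ok_num <- function(f) {
    f %in% present && is.numeric(params[[f]]) &&
      length(params[[f]]) == 1L && is.finite(params[[f]])
  }
  positive <- c("G", "lambda_E", "lambda_r", "lambda_LACT_Ex",
                grep("^(Vmax|Km|psi)_", .param_fields, value = TRUE),
                "PYR_E_star", "PEP_star", "R_p")
  for (f in positive)
    if (ok_num(f) && params[[f]] <= 0)
      problems <- c(problems, paste0(f, " must be strictly positive"))
  for (f in c("GLUT1", "c_M1"))
    if (ok_num(f) && (params[[f]] < 0 || params[[f]] > 1))
      problems <- c(problems, paste0(f, " must lie in [0, 1]"))
  if (ok_num("q_r") && (params$q_r <= 0 || params$q_r >= 1))
    problems <- c(problems, "q_r must lie strictly inside (0, 1)")
  if (ok_num("rho_r") && (params$rho_r < 0 || params$rho_r > 1))
    problems <- c(problems, "rho_r must lie in [0, 1]")
  if (length(problems))
    stop("invalid model parameters:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(params[.param_fields], class = "rpe_params")
}

#' @export
print.rpe_params <- function(x, ...) {
  cat("RPE-rod metabolic model parameters\n")
  cat(sprintf("  external glucose G = %g mM, GLUT1 = %g, c_M1 = %g\n",
              x$G, x$GLUT1, x$c_M1))
  tab <- data.frame(value = unlist(x))
  print(format(tab, digits = 6), ...)
  invisible(x)
}

#' Nominal initial metabolite concentrations
#'
#' The initial conditions of the healthy baseline run, in mM, in the fixed
#' state order of [metabolite_names()]. Also shipped as
#' `extdata/init_healthy.yaml`.
#'
#' @return Named numeric vector of length 11.
#' @export
default_initial_state <- function() {
  c(g_E = 3, G6P_E = 5e-3, F16BP_E = 0.13, PYR_E = 0,
    g_r = 0.1, G6P_r = 0.45, NADPH_r = 0.1e-8, F16BP_r = 0.06,
    G3P_r = 2.5e-6, PYR_r = 0, LACT_r = 1e-4)
}

#' Validate a metabolite state vector
#'
#' A state must be a numeric vector of length 11 with all components
#' non-negative and finite. Unnamed vectors are accepted and named in the
#' canonical order; named vectors are reordered.
#'
#' @param state Numeric vector of 11 concentrations (mM).
#' @return Named numeric vector in canonical order.
#' @export
validate_state <- function(state) {
  nm <- metabolite_names()
  if (!is.numeric(state) || length(state) != 11L)
    stop("state must be a numeric vector of length 11", call. = FALSE)
  if (!is.null(names(state))) {
    if (!setequal(names(state), nm))
      stop("state names must be exactly: ", paste(nm, collapse = ", "),
           call. = FALSE)
    state <- state[nm]
  } else {
    names(state) <- nm
  }
  bad <- !is.finite(state)
  if (any(bad))
    stop("non-finite concentration for: ",
         paste(nm[bad], collapse = ", "), call. = FALSE)
  neg <- state < 0
  if (any(neg))
    stop("negative concentration for: ",
         paste(nm[neg], collapse = ", "), call. = FALSE)
  state
}

# coerce a parsed YAML scalar to numeric; bare scalars like "96e2" are typed
# as strings by YAML 1.1, so accept string scientific notation too
.as_param_number <- function(x, key) {
  if (is.numeric(x) && length(x) == 1L) return(as.numeric(x))
  if (is.character(x) && length(x) == 1L) {
    v <- suppressWarnings(as.numeric(x))
    if (!is.na(v)) return(v)
  }
  stop("value of '", key, "' is not a number: ", deparse(x), call. = FALSE)
}

#' Read a parameter file
#'
#' Parameter files are flat YAML key/value maps whose keys are exactly the
#' field names of [default_parameters()], with values in model units.
#' Scientific notation is accepted both as YAML floats (`4.6e-5`) and as
#' bare scalars (`96e2`). Unknown or missing keys and invariant violations
#' are all reported in one validation error.
#'
#' @param path Path to a YAML parameter file.
#' @return A validated `rpe_params` object.
#' @seealso [save_parameters()]; the shipped nominal file is at
#'   `system.file("extdata", "params_healthy.yaml", package = "rpemetab")`.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path))
    stop("parameter file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw)))
    stop("parameter file must be a flat key/value map: ", path,
         call. = FALSE)
  vals <- lapply(names(raw), function(k) .as_param_number(raw[[k]], k))
  names(vals) <- names(raw)
  validate_parameters(vals)
}

#' Write a parameter file
#'
#' Serializes a parameter set as a flat YAML map readable by
#' [load_parameters()]. The round trip load(save(p)) is the identity.
#'
#' @param params A `rpe_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_parameters <- function(params, path) {
  params <- validate_parameters(params)
  txt <- vapply(.param_fields, function(f)
    sprintf("%s: %s", f, format(params[[f]], digits = 17, scientific = NA)),
    character(1))
  writeLines(txt, path)
  invisible(path)
}

#' Read an initial-condition file
#'
#' Same flat YAML format as [load_parameters()], keyed by
#' [metabolite_names()].
#'
#' @param path Path to a YAML file of 11 concentrations in mM.
#' @return Named numeric state vector.
#' @export
load_initial_state <- function(path) {
  if (!file.exists(path))
    stop("initial-condition file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  vals <- vapply(names(raw), function(k) .as_param_number(raw[[k]], k),
                 numeric(1))
  validate_state(vals)
}
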