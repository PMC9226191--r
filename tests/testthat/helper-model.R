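# shared fixtures: cached expensive runs and an independent oracle

.test_cache <- new.env(parent = emptyenv())

# the default stepped sweep (101 levels x 1500 min, continuation); computed
# once per test run
cached_default_sweep <- function() {
  if (is.null(.test_cache$sweep))
    .test_cache$sweep <- glut1_sweep(default_parameters())
  .test_cache$sweep
}

sweep_row <- function(sw, level) which(abs(sw$glut1 - level) < 1e-9)

# Independent "naive transcription" of the model equations: every rate and
# every balance is written out as a formula string and evaluated in an
# environment holding the parameters and the state. This path shares no
# code with the package right-hand side.
naive_rhs <- function(state, params) {
  env <- list2env(c(unclass(params), as.list(state)))
  ev <- function(s) eval(parse(text = s), envir = env)
  env$omega_E <- ev("PYR_E_star^4 / (PYR_E_star^4 + PYR_E^4)")
  env$phi_E <- ev("1 - omega_E")
  env$phi_r <- ev("PYR_r^4 / (PEP_star^4 + PYR_r^4)")
  env$omega_r <- ev("1 - phi_r")
  env$nu_g_E <- ev("lambda_E * GLUT1 * (G - g_E) * Vmax_g_E * G^2 / (Km_g_E^2 + G^2)")
  env$nu_G6P_E <- ev("Vmax_G6P_E * g_E^2 / (Km_G6P_E^2 + g_E^2) * omega_E")
  env$nu_F16BP_E <- ev("Vmax_F16BP_E * G6P_E^2 / (Km_F16BP_E^2 + G6P_E^2)")
  env$nu_PYR_E <- ev("Vmax_PYR_E * F16BP_E^2 / (Km_PYR_E^2 + F16BP_E^2)")
  env$nu_g_r <- ev("lambda_r * GLUT1 * (g_E - g_r) * Vmax_g_r * g_E^2 / ((Km_g_r / phi_E)^2 + g_E^2)")
  env$nu_G6P_r <- ev("Vmax_G6P_r * g_r^2 / (Km_G6P_r^2 + g_r^2)")
  env$nu_F16BP_r <- ev("Vmax_F16BP_r * G6P_r^2 / (Km_F16BP_r^2 + G6P_r^2) * omega_r")
  env$nu_NADPH_r <- ev("Vmax_NADPH_r * G6P_r^2 / (Km_NADPH_r^2 + G6P_r^2) * phi_r")
  env$nu_PYR_r <- ev("Vmax_PYR_r * F16BP_r^2 / (Km_PYR_r^2 + F16BP_r^2) * (1 - q_r)")
  env$nu_G3P_r <- ev("Vmax_G3P_r * F16BP_r^2 / (Km_G3P_r^2 + F16BP_r^2) * q_r")
  env$nu_LACT_r <- ev("Vmax_LACT_r * PYR_r^2 / (Km_LACT_r^2 + PYR_r^2) * (1 - rho_r)")
  env$MCT1 <- ev("c_M1 * LACT_r")
  env$LACT_Ex <- ev("lambda_LACT_Ex * MCT1 * LACT_r")
  env$nu_PYR_rE <- ev("Vmax_PYR_rE * LACT_Ex^2 / (Km_PYR_rE^2 + LACT_Ex^2)")
  c(g_E = ev("nu_g_E - nu_G6P_E - nu_g_r"),
    G6P_E = ev("nu_G6P_E - nu_F16BP_E"),
    F16BP_E = ev("nu_F16BP_E - nu_PYR_E"),
    PYR_E = ev("nu_PYR_E + nu_PYR_rE - psi_PYR_E * PYR_E"),
    g_r = ev("nu_g_r - nu_G6P_r"),
    G6P_r = ev("nu_G6P_r - nu_F16BP_r - nu_NADPH_r"),
    NADPH_r = ev("nu_NADPH_r - psi_NADPH_r * NADPH_r"),
    F16BP_r = ev("nu_F16BP_r - nu_PYR_r - nu_G3P_r"),
    G3P_r = ev("nu_G3P_r - psi_G3P_r * R_p * G3P_r"),
    PYR_r = ev("nu_PYR_r - nu_LACT_r"),
    LACT_r = ev("nu_LACT_r - psi_LACT_r * MCT1 * LACT_r"))
}

# random positive states spanning several orders of magnitude; PYR_E is kept
# above 1e-6 mM so the Phi_E underflow guard (asserted separately) stays
# inactive and the naive oracle applies verbatim
random_state <- function() {
  s <- 10^stats::runif(11, -6, 0.5)
  names(s) <- metabolite_names()
  s
}

zero_state <- function() {
  stats::setNames(rep(0, 11), metabolite_names())
}

rel_diff <- function(a, b, floor = 1e-30) {
  max(abs(a - b) / pmax(abs(a), abs(b), floor))
}
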