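# Hill/Holling type III saturating rate: V s^2 / (K^2 + s^2)
.hill2 <- function(V, K, s) V * s^2 / (K^2 + s^2)

# Phi_E values below this are treated as full inhibition of rod glucose
# uptake: the (Km/Phi_E)^2 denominator term diverges and the rate limit is 0,
# which is substituted directly instead of being computed through overflow.
.PHI_E_GUARD <- 1e-12

#' Regulatory switch values
#'
#' The model partitions glucose flux with two complementary pairs of
#' fourth-power Hill switches. On the RPE side, `omega_E` rises towards 1
#' when RPE pyruvate falls below its requirement `PYR_E_star`, activating
#' RPE glycolysis; its complement `phi_E = 1 - omega_E` gates the passage
#' of glucose to the rods. On the rod side, `phi_r` rises towards 1 when
#' rod pyruvate (a proxy for phosphoenolpyruvate) exceeds the critical
#' level `PEP_star`, diverting G6P into the pentose phosphate pathway;
#' its complement `omega_r` is the share continuing down glycolysis.
#' The fourth power approximates a step function while staying smooth.
#'
#' @param PYR_E RPE pyruvate concentration (mM), non-negative.
#' @param PYR_r Rod pyruvate concentration (mM), non-negative.
#' @param params A `rpe_params` object.
#' @return Named list with `omega_E`, `phi_E`, `phi_r`, `omega_r`, each in
#'   \[0, 1\]; the complements sum to 1 exactly.
#' @export
#' @examples
#' p <- default_parameters()
#' regulators(p$PYR_E_star, p$PEP_star, p)  # both switches at 1/2
regulators <- function(PYR_E, PYR_r, params) {
  if (!is.finite(PYR_E) || PYR_E < 0)
    stop("PYR_E must be a non-negative concentration", call. = FALSE)
  if (!is.finite(PYR_r) || PYR_r < 0)
    stop("PYR_r must be a non-negative concentration", call. = FALSE)
  omega_E <- params$PYR_E_star^4 / (params$PYR_E_star^4 + PYR_E^4)
  phi_r <- PYR_r^4 / (params$PEP_star^4 + PYR_r^4)
  list(omega_E = omega_E, phi_E = 1 - omega_E,
       phi_r = phi_r, omega_r = 1 - phi_r)
}

# rate kernel on a bare positional state vector, no validation -- shared by
# the public accessor and the ODE right-hand side (where the integrator may
# probe states a rounding error below zero)
.rates_unchecked <- function(s, p) {
  omega_E <- p$PYR_E_star^4 / (p$PYR_E_star^4 + s[4]^4)
  phi_E <- 1 - omega_E
  phi_r <- s[10]^4 / (p$PEP_star^4 + s[10]^4)
  omega_r <- 1 - phi_r

  nu_g_E <- p$lambda_E * p$GLUT1 * (p$G - s[1]) *
    .hill2(p$Vmax_g_E, p$Km_g_E, p$G)
  nu_G6P_E <- .hill2(p$Vmax_G6P_E, p$Km_G6P_E, s[1]) * omega_E
  nu_F16BP_E <- .hill2(p$Vmax_F16BP_E, p$Km_F16BP_E, s[2])
  nu_PYR_E <- .hill2(p$Vmax_PYR_E, p$Km_PYR_E, s[3])

  nu_g_r <- if (phi_E < .PHI_E_GUARD) 0 else
    p$lambda_r * p$GLUT1 * (s[1] - s[5]) *
      p$Vmax_g_r * s[1]^2 / ((p$Km_g_r / phi_E)^2 + s[1]^2)
  nu_G6P_r <- .hill2(p$Vmax_G6P_r, p$Km_G6P_r, s[5])
  nu_F16BP_r <- .hill2(p$Vmax_F16BP_r, p$Km_F16BP_r, s[6]) * omega_r
  nu_NADPH_r <- .hill2(p$Vmax_NADPH_r, p$Km_NADPH_r, s[6]) * phi_r
  nu_PYR_r <- .hill2(p$Vmax_PYR_r, p$Km_PYR_r, s[8]) * (1 - p$q_r)
  nu_G3P_r <- .hill2(p$Vmax_G3P_r, p$Km_G3P_r, s[8]) * p$q_r
  nu_LACT_r <- .hill2(p$Vmax_LACT_r, p$Km_LACT_r, s[10]) * (1 - p$rho_r)

  MCT1 <- p$c_M1 * s[11]
  LACT_Ex <- p$lambda_LACT_Ex * MCT1 * s[11]
  nu_PYR_rE <- .hill2(p$Vmax_PYR_rE, p$Km_PYR_rE, LACT_Ex)

  c(nu_g_E = nu_g_E, nu_G6P_E = nu_G6P_E, nu_F16BP_E = nu_F16BP_E,
    nu_PYR_E = nu_PYR_E, nu_PYR_rE = nu_PYR_rE,
    nu_g_r = nu_g_r, nu_G6P_r = nu_G6P_r, nu_NADPH_r = nu_NADPH_r,
    nu_F16BP_r = nu_F16BP_r, nu_PYR_r = nu_PYR_r, nu_G3P_r = nu_G3P_r,
    nu_LACT_r = nu_LACT_r, MCT1 = MCT1, LACT_Ex = LACT_Ex)
}

#' Kinetic rates of every reaction step
#'
#' Evaluates all twelve kinetic rates of the model at a given state, plus
#' the two algebraic transporter quantities: `MCT1 = c_M1 * LACT_r` (MCT1
#' abundance is taken proportional to rod lactate) and
#' `LACT_Ex = lambda_LACT_Ex * MCT1 * LACT_r`, the rod-supplied external
#' lactate available to the RPE.
#'
#' Every enzymatic step is a Holling type III response,
#' `V s^2 / (K^2 + s^2)`. The two glucose uptake steps additionally scale
#' with the relative transporter level `GLUT1`, a `lambda` factor and the
#' signed concentration gradient, so they follow the gradient direction
#' and vanish when `GLUT1 = 0`. Rod uptake is inhibited through its
#' half-saturation constant, which is inflated to `Km_g_r / phi_E`; when
#' `phi_E` underflows the guard threshold the rate is set to its limit, 0.
#'
#' @param state Named state vector (see [metabolite_names()]), all
#'   components non-negative.
#' @param params A `rpe_params` object.
#' @return Named numeric vector with elements `nu_g_E`, `nu_G6P_E`,
#'   `nu_F16BP_E`, `nu_PYR_E`, `nu_PYR_rE`, `nu_g_r`, `nu_G6P_r`,
#'   `nu_NADPH_r`, `nu_F16BP_r`, `nu_PYR_r`, `nu_G3P_r`, `nu_LACT_r`
#'   (mM/min), plus `MCT1` (mM) and `LACT_Ex` (mM).
#' @export
reaction_rates <- function(state, params) {
  s <- validate_state(state)
  .rates_unchecked(unname(s), params)
}

# bare right-hand side on a positional vector; no validation
.rhs_unchecked <- function(s, p) {
  nu <- .rates_unchecked(s, p)
  c(nu[[1L]] - nu[[2L]] - nu[[6L]],                      # g_E
    nu[[2L]] - nu[[3L]],                                 # G6P_E
    nu[[3L]] - nu[[4L]],                                 # F16BP_E
    nu[[4L]] + nu[[5L]] - p$psi_PYR_E * s[4],            # PYR_E
    nu[[6L]] - nu[[7L]],                                 # g_r
    nu[[7L]] - nu[[9L]] - nu[[8L]],                      # G6P_r
    nu[[8L]] - p$psi_NADPH_r * s[7],                     # NADPH_r
    nu[[9L]] - nu[[10L]] - nu[[11L]],                    # F16BP_r
    nu[[11L]] - p$psi_G3P_r * p$R_p * s[9],              # G3P_r
    nu[[10L]] - nu[[12L]],                               # PYR_r
    nu[[12L]] - p$psi_LACT_r * nu[[13L]] * s[11])        # LACT_r
}

#' Time derivative of the metabolite state
#'
#' The 11-dimensional right-hand side of the model. Interior nodes balance
#' their production rate against the rates of the steps that consume them;
#' the four end nodes carry clearance sinks: RPE pyruvate is oxidized at
#' `psi_PYR_E * PYR_E`, rod NADPH is consumed at `psi_NADPH_r * NADPH_r`,
#' rod G3P is drained by outer-segment renewal at
#' `psi_G3P_r * R_p * G3P_r`, and rod lactate is cleared at
#' `psi_LACT_r * MCT1 * LACT_r` (quadratic in `LACT_r`, since MCT1
#' abundance itself scales with rod lactate).
#'
#' The system is autonomous: `t` is accepted for solver compatibility but
#' unused.
#'
#' @param t Time (min); ignored.
#' @param state Named state vector, all components finite.
#' @param params A `rpe_params` object.
#' @return Named numeric vector of d(state)/dt in mM/min, in the order of
#'   [metabolite_names()].
#' @export
metabolite_rhs <- function(t, state, params) {
  bad <- !is.finite(state)
  if (any(bad))
    stop("non-finite state during integration for: ",
         paste(metabolite_names()[bad], collapse = ", "), call. = FALSE)
  d <- .rhs_unchecked(unname(state), params)
  names(d) <- metabolite_names()
  d
}
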