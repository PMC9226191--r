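p_default <- default_parameters()

test_that("regulator switches hit their landmark values", {
  p <- p_default
  # half-activation exactly at the pyruvate requirement
  r <- regulators(p$PYR_E_star, p$PEP_star, p)
  expect_identical(r$omega_E, 0.5)
  expect_identical(r$phi_E, 0.5)
  expect_identical(r$phi_r, 0.5)
  expect_identical(r$omega_r, 0.5)
  # exhausted RPE pyruvate fully activates RPE glycolysis
  r0 <- regulators(0, 0, p)
  expect_identical(r0$omega_E, 1)
  expect_identical(r0$phi_E, 0)
  expect_identical(r0$phi_r, 0)
  # doubling the pyruvate level: fourth-power Hill gives 1/(1 + 2^4)
  r2 <- regulators(2 * p$PYR_E_star, p$PEP_star, p)
  expect_equal(r2$omega_E, 1 / 17, tolerance = 1e-14)
})

test_that("regulator complements sum to one and respond monotonically", {
  p <- p_default
  set.seed(11)
  eps <- .Machine$double.eps
  for (i in 1:1000) {
    r <- regulators(10^runif(1, -8, 1), 10^runif(1, -16, 1), p)
    expect_lte(abs(r$omega_E + r$phi_E - 1), 2 * eps)
    expect_lte(abs(r$phi_r + r$omega_r - 1), 2 * eps)
    expect_true(r$omega_E >= 0 && r$omega_E <= 1)
    expect_true(r$phi_r >= 0 && r$phi_r <= 1)
  }
  # sample around each switch's threshold so the fourth-power response is
  # resolvable in double precision (far above it the switch saturates at 1)
  pyr_E_grid <- sort(10^runif(50, -7, 0))
  om <- vapply(pyr_E_grid, function(x) regulators(x, 0, p)$omega_E,
               numeric(1))
  expect_true(all(diff(om) < 0))
  pyr_r_grid <- sort(10^runif(50, -16, -11))
  ph <- vapply(pyr_r_grid, function(x) regulators(0, x, p)$phi_r,
               numeric(1))
  expect_true(all(diff(ph) > 0))
})

test_that("regulators reject negative concentrations by name", {
  expect_error(regulators(-1, 0, p_default), "PYR_E")
  expect_error(regulators(0, -1, p_default), "PYR_r")
})

test_that("kinetic rates reproduce hand-computed values at the nominal state", {
  r <- reaction_rates(default_initial_state(), p_default)
  # RPE glucose uptake: 0.8 * 1 * (5 - 3) * 1.2 * 25 / (81 + 25)
  expect_equal(r[["nu_g_E"]], 0.8 * 2 * 1.2 * 25 / 106, tolerance = 1e-12)
  expect_equal(r[["nu_g_E"]], 0.452830, tolerance = 1e-6)
  # rod G6P production at g_r = 0.1: 0.1845 * 0.01 / (0.09^2 + 0.01)
  expect_equal(r[["nu_G6P_r"]], 0.1845 * 0.01 / (0.09^2 + 0.01),
               tolerance = 1e-12)
  expect_equal(r[["nu_G6P_r"]], 0.101934, tolerance = 1e-5)
})

test_that("the MCT1 coupling is algebraic and quadratic in rod lactate", {
  s <- default_initial_state()
  s[["LACT_r"]] <- 1e-4
  r <- reaction_rates(s, p_default)
  expect_identical(r[["MCT1"]], 1e-4)
  expect_equal(r[["LACT_Ex"]], 480 * 1e-4 * 1e-4, tolerance = 1e-14)
})

test_that("zero substrates annihilate all rates except glucose import", {
  r <- reaction_rates(zero_state(), p_default)
  p <- p_default
  expected_uptake <- p$lambda_E * p$GLUT1 * p$G *
    p$Vmax_g_E * p$G^2 / (p$Km_g_E^2 + p$G^2)
  expect_equal(r[["nu_g_E"]], expected_uptake, tolerance = 1e-14)
  others <- setdiff(names(r), "nu_g_E")
  expect_true(all(r[others] == 0))
})

test_that("transporter knockouts annihilate the coupled rates for any state", {
  set.seed(21)
  p0 <- model_parameters(GLUT1 = 0)
  pc <- model_parameters(c_M1 = 0)
  for (i in 1:20) {
    s <- random_state()
    r0 <- reaction_rates(s, p0)
    expect_identical(r0[["nu_g_E"]], 0)
    expect_identical(r0[["nu_g_r"]], 0)
    rc <- reaction_rates(s, pc)
    expect_identical(rc[["LACT_Ex"]], 0)
    expect_identical(rc[["nu_PYR_rE"]], 0)
  }
})

test_that("saturating rates are bounded by Vmax and reach it in the substrate limit", {
  p <- p_default
  set.seed(31)
  # bounds on random states (uptake rates scale with the gradient and are
  # excluded; their sign is checked instead)
  for (i in 1:50) {
    s <- random_state()
    r <- reaction_rates(s, p)
    expect_lte(r[["nu_G6P_E"]], p$Vmax_G6P_E)
    expect_lte(r[["nu_F16BP_E"]], p$Vmax_F16BP_E)
    expect_lte(r[["nu_PYR_E"]], p$Vmax_PYR_E)
    expect_lte(r[["nu_G6P_r"]], p$Vmax_G6P_r)
    expect_lte(r[["nu_F16BP_r"]], p$Vmax_F16BP_r)
    expect_lte(r[["nu_NADPH_r"]], p$Vmax_NADPH_r)
    expect_lte(r[["nu_PYR_r"]], p$Vmax_PYR_r * (1 - p$q_r))
    expect_lte(r[["nu_G3P_r"]], p$Vmax_G3P_r * p$q_r)
    expect_lte(r[["nu_LACT_r"]], p$Vmax_LACT_r * (1 - p$rho_r))
    expect_lte(r[["nu_PYR_rE"]], p$Vmax_PYR_rE)
    # uptake rates follow their gradient's sign; all other rates are
    # non-negative
    expect_identical(sign(r[["nu_g_E"]]), sign(p$G - s[["g_E"]]))
    expect_identical(sign(r[["nu_g_r"]]), sign(s[["g_E"]] - s[["g_r"]]))
    expect_true(all(r[setdiff(names(r), c("nu_g_E", "nu_g_r"))] >= 0))
  }
  # substrate -> infinity: the Hill factor approaches 1
  s_big <- zero_state()
  s_big[["G6P_E"]] <- 1e9
  r_big <- reaction_rates(s_big, p)
  expect_equal(r_big[["nu_F16BP_E"]], p$Vmax_F16BP_E, tolerance = 1e-10)
  # substrate = 0: the rate is 0
  expect_identical(reaction_rates(zero_state(), p)[["nu_F16BP_E"]], 0)
})

test_that("vanishing phi_E inhibits rod uptake without a numerical fault", {
  # PYR_E far below its requirement drives phi_E under the guard threshold
  s <- default_initial_state()
  s[["PYR_E"]] <- 1e-9
  r <- reaction_rates(s, p_default)
  expect_identical(r[["nu_g_r"]], 0)
  expect_true(all(is.finite(r)))
})
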