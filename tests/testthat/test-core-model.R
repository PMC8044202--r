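cond_10uM0 <- motor_condition(0, 10)

test_that("frozen values at saturating ATP, no load", {
  expect_equal(binding_probability(kip3, 0), 0.7502601, tolerance = 1e-6)
  r <- atpase_rates(kip3, cond_sat0)
  expect_equal(r$k_T, 21.71357, tolerance = 1e-6)
  expect_equal(r$k_L, 41.5859, tolerance = 1e-6)
  expect_equal(total_atpase_rate(kip3, cond_sat0), r$k_T + r$k_L)
  expect_equal(velocity_no_slip(kip3, cond_sat0), 47.24134, tolerance = 1e-6)
  expect_equal(period2_probability(kip3, 0), 0.06436768, tolerance = 1e-6)
  # at saturating ATP the lifetime fraction coincides with the probability
  expect_identical(period2_fraction(kip3, cond_sat0),
                   period2_probability(kip3, 0))
})

test_that("frozen values at 10 uM ATP, no load", {
  r <- atpase_rates(kip3, cond_10uM0)
  expect_equal(r$k_T, 6.845988, tolerance = 1e-6)
  expect_equal(r$k_L, 8.058775, tolerance = 1e-6)
  v10 <- velocity_no_slip(kip3, cond_10uM0)
  expect_equal(v10, 24.98939, tolerance = 1e-6)
  expect_equal(v10 / velocity_no_slip(kip3, cond_sat0), 0.5289731,
               tolerance = 1e-6)
  # correctly evaluated weak-binding lifetime fraction at 10 uM
  expect_equal(period2_fraction(kip3, cond_10uM0), 0.01768313,
               tolerance = 1e-5)
})

test_that("slip velocity: frozen value, odd symmetry, zero at no load", {
  expect_equal(slip_velocity(kip3, 1), 819.2959, tolerance = 1e-6)
  expect_identical(slip_velocity(kip3, 0), 0)
  f <- c(0.3, 1, 2.7, 5)
  expect_equal(slip_velocity(kip3, -f), -slip_velocity(kip3, f))
})

test_that("slipping time: limit, finite-ATP value, and divergence guards", {
  expect_identical(slipping_time(kip3, "saturating"), 1 / 400)
  expect_identical(slipping_time(kip3, Inf), 1 / 400)
  expect_equal(slipping_time(kip3, 1000), (400 + 1000) / (400 * 1000))
  expect_error(slipping_time(kip3, 0), "slip-only")
  # ADP rebinding prolongs the episode when k_bD > 0
  p <- kip3
  p$k_bD <- 0.5
  expect_equal(slipping_time(p, 1000, adp = 100),
               (400 + 0.5 * 100 + 1000) / (400 * 1000))
})

test_that("stepping ratios: frozen values and structural identities", {
  expect_equal(stepping_ratio_no_slip(kip3, 0), 1.568589, tolerance = 1e-6)
  expect_equal(stepping_ratio_with_slip(kip3, 0), 1.558561, tolerance = 1e-6)
  expect_equal(stepping_ratio_adp_only(kip3, 1), 7.037264, tolerance = 1e-6)
  expect_identical(stepping_ratio_adp_only(kip3, 0), 1)
  # pure Boltzmann ratio obeys detailed balance under load reversal
  f <- c(0.5, 1, 2)
  expect_equal(stepping_ratio_adp_only(kip3, f) *
                 stepping_ratio_adp_only(kip3, -f), rep(1, 3))
  # with no slip capacity, the two walking ratios coincide
  p <- kip3
  p$v_II0 <- 0
  expect_equal(stepping_ratio_with_slip(p, c(-1, 0, 1)),
               stepping_ratio_no_slip(p, c(-1, 0, 1)))
})

test_that("total velocity composes walking and slip fluxes", {
  cond <- motor_condition(-1, "saturating")
  res <- total_velocity(kip3, cond)
  expect_s3_class(res, "velocity_result")
  expect_equal(res$v0, velocity_no_slip(kip3, cond))
  w <- period2_probability(kip3, -1) * period2_fraction(kip3, cond)
  expect_equal(res$v_slip, w * slip_velocity(kip3, -1))
  expect_equal(res$v_total, res$v0 + res$v_slip)
  # independent spot check composed from scratch at F = -1 pN
  P_E <- stats::plogis(1.1 + (-1) * 1.7 / 4.1)
  k_T <- 22 * P_E + (400 * 22 / 422) * (1 - P_E)
  k_L <- (400 * 45 / 445) * P_E + 45 * (1 - P_E)
  v0 <- (P_E * k_T - (1 - P_E) * k_L) * 8
  P_II <- P_E * 22 / 422 + (1 - P_E) * 45 / 445
  F_II <- P_II # lifetime fraction equals the probability at saturating ATP
  vII <- 45 * (exp(-4 / 4.1) - exp(4 / 4.1)) * 8
  expect_equal(res$v_total, v0 + P_II * F_II * vII, tolerance = 1e-12)
})

test_that("stall forces: frozen values, closed-form seed, error paths", {
  expect_equal(stall_force(kip3), 1.050586, tolerance = 1e-5)
  expect_equal(stall_force_closed_form(kip3), 0.927034, tolerance = 1e-6)
  expect_equal(stall_force(kip3, include_slip = TRUE), 0.9745021,
               tolerance = 1e-5)
  expect_equal(simple_form_r0(kip3), 1.468703, tolerance = 1e-6)
  # a motor with no backward bias anywhere cannot be bracketed
  p_fast <- motor_parameters(k_D = 400, k_plus = 45, k_minus = 45, E_NL = 20,
                             d_plus = 0.01)
  expect_error(stall_force(p_fast), "no sign change")
  # a motor that runs backward at no load has no stall in this sense
  p_back <- motor_parameters(k_D = 400, k_plus = 10, k_minus = 45, E_NL = 0.1,
                             d_plus = 1.7)
  expect_error(stall_force(p_back), "not positive")
})

test_that("simplified force-velocity relation: frozen values and stall zero", {
  sp <- simple_velocity_preset("kip3_simple_fit")
  v0 <- velocity_no_slip_simple(sp$r0, sp$F_S, sp$k_plus, sp$k_minus, 0)
  expect_equal(v0, 47.55056, tolerance = 1e-6)
  expect_equal(velocity_no_slip_simple(sp$r0, sp$F_S, sp$k_plus, sp$k_minus,
                                       -sp$F_S), 0)
  # forward plateau is k_plus * d
  expect_equal(velocity_no_slip_simple(sp$r0, sp$F_S, sp$k_plus, sp$k_minus,
                                       500), sp$k_plus * 8, tolerance = 1e-6)
})

test_that("simple and full descriptions agree within 5 nm/s near stall", {
  sp <- simple_velocity_preset("kip3_simple_fit")
  f <- seq(-2, 2, by = 0.05)
  v_simple <- velocity_no_slip_simple(sp$r0, sp$F_S, sp$k_plus, sp$k_minus, f)
  v_full <- velocity_no_slip(kip3, motor_condition(f, "saturating"))
  expect_lt(max(abs(v_simple - v_full)), 5)
})

test_that("finite-ATP forms converge to the saturating forms", {
  f <- seq(-3, 3, by = 0.5)
  hi <- motor_condition(f, 1e9)
  sat <- motor_condition(f, "saturating")
  r_hi <- atpase_rates(kip3, hi)
  r_sat <- atpase_rates(kip3, sat)
  expect_equal(r_hi$k_T, r_sat$k_T, tolerance = 1e-3)
  expect_equal(r_hi$k_L, r_sat$k_L, tolerance = 1e-3)
  expect_equal(period2_fraction(kip3, hi), period2_fraction(kip3, sat),
               tolerance = 1e-3)
  expect_equal(slipping_time(kip3, 1e9), slipping_time(kip3, "saturating"),
               tolerance = 1e-3)
})

test_that("overflow safety and monotonicity of the binding probability", {
  expect_identical(binding_probability(kip3, 1000), 1)
  expect_lt(binding_probability(kip3, -1000), 1e-100)
  expect_false(any(is.nan(velocity_no_slip(
    kip3, motor_condition(c(-1000, 1000), "saturating")))))
  p <- binding_probability(kip3, seq(-3, 3, by = 0.1))
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("velocity sign and stepping ratio are coherent", {
  f <- seq(-3, 3, by = 0.25)
  v0 <- velocity_no_slip(kip3, motor_condition(f, "saturating"))
  r0 <- stepping_ratio_no_slip(kip3, f)
  expect_equal(v0 > 0, r0 > 1)
  expect_true(all(diff(v0) > 0)) # monotone increasing in load
})

test_that("asymptotic plateaus of the walking velocity", {
  v_fwd <- velocity_no_slip(kip3, motor_condition(10, "saturating"))
  expect_lt(abs(v_fwd / kip3$d - kip3$k_plus) / kip3$k_plus, 0.05)
  v_bwd <- velocity_no_slip(kip3, motor_condition(-15, "saturating"))
  expect_lt(abs(abs(v_bwd) / kip3$d - kip3$k_minus) / kip3$k_minus, 0.05)
})

test_that("weak-binding probability stays strictly inside (0, 1)", {
  f <- c(-50, -1, 0, 1, 50)
  p2 <- period2_probability(kip3, f)
  expect_true(all(p2 > 0 & p2 < 1))
  # even with very fast ADP release the probability remains positive
  p <- kip3
  p$k_D <- 1e9
  expect_true(all(period2_probability(p, f) > 0))
})

test_that("slip diffusion constant uses the conventional one-hop relation", {
  expect_equal(slip_diffusion_constant(kip3), 1440)
  expect_equal(slip_diffusion_constant(kip3), kip3$v_II0 * kip3$d^2 / 2)
})

test_that("rate breakdown collects all intermediates consistently", {
  br <- rate_breakdown(kip3, cond_sat0)
  expect_s3_class(br, "rate_breakdown")
  expect_equal(br$k_total, br$k_T + br$k_L)
  expect_equal(br$P_E, binding_probability(kip3, 0))
  expect_equal(br$P_II, period2_probability(kip3, 0))
  expect_equal(br$F_II, period2_fraction(kip3, cond_sat0))
})
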