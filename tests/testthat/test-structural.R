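test_that("allometric scaling uses exponents 0.75 and 1 and composes", {
  p <- structural_params()
  expect_equal(allometric_scale(p, 70), p)
  s <- allometric_scale(p, 13.5)
  expect_equal(s$CL, 400 * (13.5 / 70)^0.75, tolerance = 1e-12)
  expect_equal(s$Q, 160 * (13.5 / 70)^0.75, tolerance = 1e-12)
  expect_equal(s$V_c, 10.6 * 13.5 / 70, tolerance = 1e-12)
  expect_equal(s$V_p, 124 * 13.5 / 70, tolerance = 1e-12)
  expect_equal(s$Km, p$Km)
  expect_equal(s$Vmax, p$Vmax)
  # power-law composition: scaling to w1 then re-referencing to w2 equals
  # direct scaling by (w1/w2)
  s2 <- allometric_scale(allometric_scale(p, 20), 10, ref_weight = 20)
  expect_equal(s2$CL, allometric_scale(p, 10)$CL, tolerance = 1e-12)
  expect_error(allometric_scale(p, -5), "positive")
})

test_that("dose conversion uses the hydrocortisone molar mass", {
  expect_equal(dose_to_nmol(0), 0)
  expect_equal(dose_to_nmol(7), 7e6 / 362.46, tolerance = 1e-12)
  expect_equal(dose_to_nmol(7), 19313, tolerance = 1e-4)
  expect_equal(dose_to_nmol(0.5), 1379.5, tolerance = 1e-4)
  expect_error(dose_to_nmol(-1), "nonnegative")
})

test_that("ODE right-hand side matches its defining equations", {
  p <- allometric_scale(structural_params(), 13.5)
  b <- binding_params()
  g <- typical_geometry("children_infants")
  expect_equal(ode_rhs(0, c(0, 0, 0, 0), p, b, g)[[1]], rep(0, 4))
  # half-saturation: absorption rate Vmax/2 when depot equals Km
  d <- ode_rhs(0, c(p$Km, 0, 0, 0), p, b, g)[[1]]
  expect_equal(-d[1], p$Vmax / 2, tolerance = 1e-12)
  expect_equal(p$Vmax / 2, 21388 / 2)
})

test_that("compiled solver agrees with the reference R right-hand side", {
  p <- allometric_scale(structural_params(), 13.5)
  b <- binding_params()
  g <- typical_geometry("children_infants")
  times <- seq(0, 6, by = 0.5)
  prof <- simulate_profile(dose_events(0, 7), p, b, g, times)
  r_out <- deSolve::lsoda(
    c(dose_to_nmol(7), 0, 0, 0), times,
    function(t, y, parms) ode_rhs(t, y, p, b, g), NULL,
    rtol = 1e-8, atol = 1e-10)
  expect_equal(prof$A_central, unname(r_out[, 3]), tolerance = 1e-6)
  expect_equal(prof$A_depot, unname(r_out[, 2]), tolerance = 1e-6)
})

test_that("mass balance holds along simulated profiles", {
  p <- allometric_scale(structural_params(), 13.5)
  b <- binding_params()
  g <- typical_geometry("children_infants")
  prof <- simulate_profile(dose_events(0, 7), p, b, g, seq(0, 12, 0.25))
  total <- prof$A_depot + prof$A_central + prof$A_per + prof$A_elim
  expect_equal(total, rep(dose_to_nmol(7), nrow(prof)),
               tolerance = 1e-6)
  expect_true(all(prof$C_pla >= 0) && all(prof$C_DBS >= 0))
})

test_that("first-order limit reproduces the analytic linear model", {
  # Km >> depot with Vmax/Km = ka fixed, and linear binding only
  ka <- 1.5
  Km_big <- 1e9
  p <- structural_params(CL = 110, V_c = 2, Q = 45, V_p = 24,
                         Km = Km_big, Vmax = ka * Km_big)
  b <- binding_params(Bmax = 0, KR = 0.9)
  g <- blood_geometry(V_c = 2, V_delta = 11, weight = 13.5,
                      age_group = "children_infants")
  times <- seq(0, 8, by = 0.25)
  prof <- simulate_profile(dose_events(0, 5), p, b, g, times)
  L <- g$V_c * (1 + b$NS_Alb + b$KR)
  ora <- linear_model_traj(dose_to_nmol(5), ka, p$CL, p$Q, p$V_p, L,
                           times)
  expect_equal(prof$A_central[-1], ora[-1, 2], tolerance = 1e-3)
})

test_that("zero dose yields a flat profile at the baselines", {
  p <- allometric_scale(structural_params(BASE_pla = 9.41,
                                          BASE_DBS = 4.22), 13.5)
  b <- binding_params()
  g <- typical_geometry("children_infants")
  prof <- simulate_profile(dose_events(0, 0), p, b, g, seq(0, 6, 1))
  expect_equal(prof$C_pla, rep(9.41, nrow(prof)), tolerance = 1e-10)
  expect_equal(prof$C_DBS, rep(4.22, nrow(prof)), tolerance = 1e-10)
})

test_that("exposure is nondecreasing in dose", {
  p <- allometric_scale(structural_params(), 13.5)
  b <- binding_params()
  g <- typical_geometry("children_infants")
  times <- seq(0, 6, by = 0.05)
  res <- vapply(c(0.5, 1, 2, 4, 7, 12, 20), function(d) {
    prof <- simulate_profile(dose_events(0, d), p, b, g, times)
    c(max(prof$C_DBS), sum(prof$C_DBS) * 0.05)
  }, numeric(2))
  expect_true(all(diff(res[1, ]) > 0))
  expect_true(all(diff(res[2, ]) > 0))
})

test_that("superposition holds in the fully linear limit", {
  Km_big <- 1e10
  p <- structural_params(CL = 110, V_c = 2, Q = 45, V_p = 24,
                         Km = Km_big, Vmax = 2 * Km_big)
  b <- binding_params(Bmax = 0, KR = 0.9)
  g <- blood_geometry(V_c = 2, V_delta = 11, weight = 13.5,
                      age_group = "children_infants")
  times <- seq(0.25, 8, by = 0.25)
  c1 <- simulate_profile(dose_events(0, 2), p, b, g, times)$C_DBS
  c2 <- simulate_profile(dose_events(0, 4), p, b, g, times)$C_DBS
  expect_equal(c2, 2 * c1, tolerance = 1e-3)
})

test_that("profile ratio obeys the binding identity at every time", {
  p <- allometric_scale(structural_params(), 3.6)
  b <- binding_params()
  g <- typical_geometry("neonate")
  prof <- simulate_profile(dose_events(0, 4), p, b, g, seq(0.1, 6, 0.1))
  fr <- species_fractions(prof$C_DBS, b, g)
  expect_equal(prof$C_pla / prof$C_DBS,
               (1 + g$V_delta / g$V_c) * (1 - fr$f_RBC),
               tolerance = 1e-6)
})

test_that("later dose events enter the depot at their times", {
  p <- allometric_scale(structural_params(), 70)
  b <- binding_params(Bmax = 500, KR = 0)
  g <- blood_geometry(V_c = p$V_c, V_delta = 0, age_group = "adult")
  prof <- simulate_profile(dose_events(c(0, 6), c(5, 5)), p, b, g,
                           seq(0, 12, 0.25))
  before <- prof$C_pla[prof$time == 6]
  after <- prof$C_pla[prof$time == 7]
  expect_gt(after, before)  # second absorption wave
  total <- prof$A_depot + prof$A_central + prof$A_per + prof$A_elim
  expect_equal(total[prof$time > 6], rep(2 * dose_to_nmol(5),
                                         sum(prof$time > 6)),
               tolerance = 1e-6)
})
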