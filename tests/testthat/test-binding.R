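test_that("partition handles the zero and saturation limits", {
  p <- binding_params(Bmax = 500, KR = 0.9)
  g <- typical_geometry("children_infants")
  sp0 <- partition_from_unbound(0, p, g)
  expect_true(all(unlist(sp0[c("A_u", "A_CBG", "A_Alb", "A_RBC")]) == 0))
  expect_equal(sp0$C_pla, 0)
  expect_equal(sp0$C_DBS, 0)
  # CBG pool per litre plasma approaches Bmax as Cu grows
  sp_hi <- partition_from_unbound(1e9, p, g)
  expect_equal(sp_hi$A_CBG / g$V_c, p$Bmax, tolerance = 1e-6)
  expect_error(partition_from_unbound(-1, p, g), "nonnegative")
})

test_that("mass is conserved and concentrations follow their definitions", {
  p <- binding_params(Bmax = 547, KR = 0.92)
  g <- typical_geometry("neonate")
  for (cu in c(0.1, 1, 10, 100, 1000)) {
    sp <- partition_from_unbound(cu, p, g)
    expect_equal(sp$A_u + sp$A_CBG + sp$A_Alb + sp$A_RBC, sp$A_total,
                 tolerance = 1e-9)
    expect_equal(sp$C_pla, (sp$A_u + sp$A_CBG + sp$A_Alb) / g$V_c,
                 tolerance = 1e-12)
    expect_equal(sp$C_DBS, sp$A_total / (g$V_c + g$V_delta),
                 tolerance = 1e-12)
  }
})

test_that("closed-form inversion matches round-trip and bisection oracle", {
  p <- binding_params(Bmax = 547, KR = 0.92)
  g <- typical_geometry("children_infants")
  expect_equal(unbound_from_total(0, p, g), 0)
  for (cu in c(0.1, 1, 10, 100, 1000)) {
    tot <- partition_from_unbound(cu, p, g)$A_total
    expect_equal(unbound_from_total(tot, p, g), cu, tolerance = 1e-8)
  }
  set.seed(401)
  for (i in 1:100) {
    inst <- random_binding_instance()
    A <- stats::runif(1, 1e-3, 5e4)
    expect_equal(unbound_from_total(A, inst$p, inst$g),
                 bisect_unbound(A, inst$p, inst$g),
                 tolerance = 1e-8)
  }
})

test_that("inversion is continuous and strictly increasing in total amount", {
  p <- binding_params(Bmax = 547, KR = 0.92)
  g <- typical_geometry("children_infants")
  A <- seq(0, 5000, length.out = 400)
  cu <- unbound_from_total(A, p, g)
  expect_true(all(diff(cu) > 0))
  expect_true(max(abs(diff(cu))) < 2 * (max(cu) / 50))  # no jumps
})

test_that("species fractions are normalised with the linear-pool couplings", {
  p <- binding_params(Bmax = 547, KR = 0.92)
  for (grp in c("children_infants", "neonate")) {
    g <- typical_geometry(grp)
    fr <- species_fractions(c(1.8, 20, 180, 820), p, g)
    expect_equal(fr$f_u + fr$f_Alb + fr$f_CBG + fr$f_RBC,
                 rep(1, nrow(fr)), tolerance = 1e-9)
    expect_equal(fr$f_Alb / fr$f_u, rep(p$NS_Alb, nrow(fr)),
                 tolerance = 1e-12)
    expect_equal(fr$f_RBC / fr$f_u, rep(p$KR, nrow(fr)),
                 tolerance = 1e-12)
  }
  expect_error(species_fractions(-5, p, typical_geometry("neonate")),
               "nonnegative")
})

test_that("CBG fraction falls and the other fractions rise with concentration", {
  p <- binding_params()
  g <- typical_geometry("children_infants")
  fr <- species_fractions(exp(seq(log(1.8), log(800), length.out = 60)),
                          p, g)
  expect_true(all(diff(fr$f_CBG) < 0))
  expect_true(all(diff(fr$f_u) > 0))
  expect_true(all(diff(fr$f_Alb) > 0))
  expect_true(all(diff(fr$f_RBC) > 0))
})

test_that("plasma/DBS ratio obeys its algebraic identity and bounds", {
  p <- binding_params()
  for (grp in c("children_infants", "neonate")) {
    g <- typical_geometry(grp)
    cb <- exp(seq(log(1.8), log(800), length.out = 40))
    r <- plasma_dbs_ratio(cb, p, g)
    fr <- species_fractions(cb, p, g)
    expect_equal(r, (1 + g$V_delta / g$V_c) * (1 - fr$f_RBC),
                 tolerance = 1e-10)
    expect_true(all(diff(r) < 0))              # saturation lowers the ratio
    expect_true(all(r < 1 + g$V_delta / g$V_c))
    expect_true(all(r > (1 + g$V_delta / g$V_c) * (1 - max(fr$f_RBC))
                    - 1e-12))
  }
  # no RBC phase: plasma and whole blood coincide
  g0 <- blood_geometry(V_c = 2, V_delta = 0, weight = 13.5,
                       age_group = "children_infants")
  p0 <- binding_params(Bmax = 500, KR = 0)
  expect_equal(plasma_dbs_ratio(c(1, 10, 100), p0, g0), rep(1, 3),
               tolerance = 1e-12)
  expect_error(plasma_dbs_ratio(0, p, g0), "positive")
})

test_that("calibration recovers known parameters from perfect anchors", {
  p_true <- binding_params(Bmax = 700, KR = 0.5)
  mk <- function(grp, cb, sp) {
    fr <- species_fractions(cb, p_true, typical_geometry(grp))
    data.frame(age_group = grp, C_blood = cb, species = sp,
               fraction = fr[[sp]])
  }
  anchors <- rbind(mk("children_infants", 2, "f_CBG"),
                   mk("children_infants", 150, "f_u"),
                   mk("children_infants", 150, "f_RBC"),
                   mk("neonate", 700, "f_RBC"))
  cal <- calibrate_binding(anchors)
  expect_equal(cal$Bmax, p_true$Bmax, tolerance = 1e-4)
  expect_equal(cal$KR, p_true$KR, tolerance = 1e-4)
})

test_that("calibration rejects an unidentifiable anchor set", {
  bad <- data.frame(age_group = "neonate", C_blood = 100,
                    species = "f_u", fraction = c(0.1, 0.1))
  expect_error(calibrate_binding(bad), "unidentifiable")
})

test_that("default calibration lands at the published-ratio couplings", {
  cal <- calibrate_binding()
  # saturated-end RBC:unbound ratios imply a coupling near 0.92
  expect_equal(cal$KR, 0.92, tolerance = 0.02)
  # CBG capacity of a few hundred nmol/L explains the 90% low-end binding
  expect_gt(cal$Bmax, 200)
  expect_lt(cal$Bmax, 2000)
})
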