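test_that("individual draws respect the IIV model", {
  pop <- population_params()
  cov1 <- data.frame(weight = c(70, 13.5, 3.6),
                     age_group = c("adult", "children_infants",
                                   "neonate"))
  # zero variability: individuals equal the (weight-scaled) typical subject
  pop0 <- population_params(omega_cv = c(CL = 0, Km = 0, Vmax = 0, F = 0,
                                         V_delta = 0, BASE_adult = 0,
                                         BASE_child = 0))
  ind0 <- draw_individual(pop0, cov1, seed = 1)
  expect_equal(ind0$CL, 400 * (cov1$weight / 70)^0.75, tolerance = 1e-12)
  expect_equal(ind0$V_delta, c(0, 11.1, 1.05))
  expect_equal(ind0$BASE_pla, c(15.2, 9.41, 9.41))
  # determinism
  i1 <- draw_individual(pop, cov1, seed = 33)
  i2 <- draw_individual(pop, cov1, seed = 33)
  expect_identical(i1, i2)
  expect_false(isTRUE(all.equal(i1$CL,
                                draw_individual(pop, cov1,
                                                seed = 34)$CL)))
  expect_error(draw_individual(pop, data.frame(weight = 10,
                                               age_group = "toddler")),
               "age group")
})

test_that("large-sample parameter CVs match the stated IIV", {
  pop <- population_params()
  covs <- data.frame(weight = rep(70, 10000), age_group = "adult")
  ind <- draw_individual(pop, covs, seed = 99)
  cv_cl <- 100 * stats::sd(ind$CL) / mean(ind$CL)
  expect_equal(cv_cl, 25.8, tolerance = 1 / 25.8)  # within one CV point
  covs_p <- data.frame(weight = rep(13.5, 10000),
                       age_group = "children_infants")
  ind_p <- draw_individual(pop, covs_p, seed = 100)
  cv_vd <- 100 * stats::sd(ind_p$V_delta) / mean(ind_p$V_delta)
  expect_equal(cv_vd, 43.4, tolerance = 1.5 / 43.4)
  # the two pediatric baselines share one eta
  expect_equal(ind_p$BASE_pla / ind_p$BASE_DBS,
               rep(9.41 / 4.22, nrow(ind_p)), tolerance = 1e-12)
})

test_that("residual error is exponential with the stated magnitude", {
  expect_equal(apply_residual(c(5, 50), sigma = 0), c(5, 50))
  set.seed(7)
  pred <- rep(100, 20000)
  obs <- apply_residual(pred, seed = 12)
  cv <- 100 * stats::sd(obs / pred) / mean(obs / pred)
  expect_equal(cv, 14.4, tolerance = 1.5 / 14.4)
  ks <- stats::ks.test(log(obs / pred) / cv_to_sdlog(14.4), "pnorm")
  expect_gt(ks$p.value, 0.01)
  expect_error(apply_residual(c(1, -2)), "positive")
})

test_that("BLQ filtering discards flagged records and reports counts", {
  ds <- data.frame(ID = c(1, 1, 1, 1, 2, 2, 2),
                   TIME = c(0, 0, 1, 1, 0, 1, 1),
                   EVID = c(1, 0, 0, 0, 1, 0, 0),
                   AMT = c(1000, 0, 0, 0, 1000, 0, 0),
                   DV = c(NA, 5, 60, 20, NA, 80, 1.2),
                   DVID = c(0, 1, 1, 2, 0, 1, 2),
                   MDV = c(1, 0, 0, 0, 1, 0, 0),
                   WT = 13, AGEGRP = "children_infants",
                   LLOQ = c(NA, 14.1, 14.1, 1.8, NA, 14.1, 1.8),
                   BLQ = c(0, 1, 0, 0, 0, 0, 1))
  out <- filter_blq(ds)
  expect_equal(sum(out$data$EVID == 0), 3)
  expect_equal(unname(out$n_discarded), c(1, 1))
  expect_equal(out$predose_blq$ID, 1)  # pre-dose plasma was BLQ
  clean <- ds[ds$BLQ == 0, ]
  expect_identical(filter_blq(clean)$data, clean)
})

test_that("zero-residual likelihood equals the Gaussian constant term", {
  ex <- exact_adult_dataset()
  v <- neg2ll(ex$pop, ex$ds)
  n <- length(ex$pred)
  expect_equal(as.numeric(v), n * log(2 * pi * ex$pop$sigma^2),
               tolerance = 1e-6)
})

test_that("likelihood prefers the generating residual magnitude", {
  pop <- population_params()
  ds <- generate_adult_study(adult_design(n = 12), pop, seed = 55)
  prep_val <- function(sig) {
    as.numeric(neg2ll(cortdbs:::set_params(pop, c(sigma = sig)), ds))
  }
  vals <- vapply(c(7, 14.4, 30), prep_val, numeric(1))
  expect_lt(vals[2], vals[1])
  expect_lt(vals[2], vals[3])
})

test_that("likelihood prefers the generating clearance", {
  pop <- population_params()
  ds <- generate_adult_study(adult_design(n = 12), pop, seed = 56)
  val_cl <- function(cl) {
    as.numeric(neg2ll(cortdbs:::set_params(pop, c(CL = cl)), ds))
  }
  vals <- vapply(c(250, 400, 640), val_cl, numeric(1))
  expect_lt(vals[2], vals[1])
  expect_lt(vals[2], vals[3])
})
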