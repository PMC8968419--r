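test_that("pediatric generator reproduces the sparse paired design", {
  ds <- generate_pediatric_study(seed = 42)
  expect_equal(length(unique(ds$ID)), 24)
  obs <- ds[ds$EVID == 0, ]
  # paired sampling: every plasma record has a DBS record at the same time
  pla <- obs[obs$DVID == 1, c("ID", "TIME")]
  dbs <- obs[obs$DVID == 2, c("ID", "TIME")]
  expect_equal(nrow(pla), nrow(dbs))
  expect_equal(nrow(merge(pla, dbs)), nrow(pla))
  # about a hundred paired samples, as in the source design
  expect_gt(nrow(pla), 95)
  expect_lt(nrow(pla), 120)
  expect_true(all(obs$LLOQ[obs$DVID == 1] == 14.1))
  expect_true(all(obs$LLOQ[obs$DVID == 2] == 1.8))
  # every subject doses once at time zero
  expect_equal(sum(ds$EVID == 1), 24)
  expect_true(all(ds$TIME[ds$EVID == 1] == 0))
  expect_true(all(ds$AMT[ds$EVID == 1] >= dose_to_nmol(1) - 1e-9 &
                    ds$AMT[ds$EVID == 1] <= dose_to_nmol(4) + 1e-9))
})

test_that("generators are seed-deterministic down to the written file", {
  d1 <- generate_pediatric_study(seed = 5)
  d2 <- generate_pediatric_study(seed = 5)
  expect_identical(d1, d2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_dataset(d1, f1); write_dataset(d2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false(identical(d1$DV, generate_pediatric_study(seed = 6)$DV))
})

test_that("without variability observations equal typical predictions", {
  pop0 <- population_params(
    omega_cv = c(CL = 0, Km = 0, Vmax = 0, F = 0, V_delta = 0,
                 BASE_adult = 0, BASE_child = 0),
    sigma_cv = 1e-9,
    BASE_child_pla = 0, BASE_child_DBS = 0)
  ds <- generate_pediatric_study(seed = 9, pop = pop0)
  tr <- attr(ds, "truth")
  i <- which(tr$covariates$cohort == "neonates")[1]
  sub <- ds[ds$ID == i & ds$EVID == 0 & ds$DVID == 2, ]
  g <- blood_geometry(V_c = 10.6 * tr$covariates$weight[i] / 70,
                      V_delta = 1.05, weight = tr$covariates$weight[i],
                      age_group = "neonate")
  prof <- simulate_profile(dose_events(0, tr$dose_mg[i]),
                           allometric_scale(pop0$structural,
                                            tr$covariates$weight[i]),
                           pop0$binding, g, times = sort(unique(sub$TIME)))
  expect_equal(sub$DV, prof$C_DBS[match(sub$TIME, prof$time)],
               tolerance = 1e-5)
})

test_that("pre-residual pairs obey the ratio identity per subject", {
  pop0 <- population_params(sigma_cv = 1e-9, BASE_child_pla = 0,
                            BASE_child_DBS = 0)
  ds <- generate_pediatric_study(seed = 11, pop = pop0)
  tr <- attr(ds, "truth")
  obs <- ds[ds$EVID == 0 & ds$TIME > 0, ]
  pla <- obs[obs$DVID == 1, ]; dbs <- obs[obs$DVID == 2, ]
  m <- merge(pla[, c("ID", "TIME", "DV")], dbs[, c("ID", "TIME", "DV")],
             by = c("ID", "TIME"), suffixes = c("_pla", "_dbs"))
  ind <- tr$individuals
  for (r in seq_len(nrow(m))) {
    i <- m$ID[r]
    bi <- pop0$binding
    gi <- blood_geometry(V_c = ind$V_c[i], V_delta = ind$V_delta[i],
                         weight = ind$weight[i],
                         age_group = ind$age_group[i])
    fr <- species_fractions(m$DV_dbs[r], bi, gi)
    expect_equal(m$DV_pla[r] / m$DV_dbs[r],
                 (1 + gi$V_delta / gi$V_c) * (1 - fr$f_RBC),
                 tolerance = 1e-4)
  }
})

test_that("concentration and censoring structure mirrors the source study", {
  ds <- generate_pediatric_study(seed = 42)
  obs <- ds[ds$EVID == 0, ]
  dbs <- obs[obs$DVID == 2, ]
  rate_hi <- tapply(dbs$DV > 200, dbs$AGEGRP == "neonate", mean)
  # concentrations above 200 nmol/L are concentrated in neonates, who
  # receive the relatively highest mg/kg dose
  expect_gt(rate_hi[["TRUE"]], 0.3)
  expect_lt(rate_hi[["FALSE"]], 0.1)
  expect_gt(rate_hi[["TRUE"]], 5 * rate_hi[["FALSE"]])
  # plasma censoring dominates DBS censoring (higher LLOQ)
  blq_rate <- tapply(obs$BLQ, obs$DVID, mean)
  expect_gt(blq_rate[["1"]], blq_rate[["2"]])
})

test_that("adult study follows its rich plasma-only design", {
  ds <- generate_adult_study(seed = 43)
  expect_equal(length(unique(ds$ID)), 30)
  obs <- ds[ds$EVID == 0, ]
  expect_true(all(obs$DVID == 1))
  expect_equal(as.vector(table(obs$ID)), rep(12L, 30))
  dose_mg <- attr(ds, "truth")$dose_mg
  expect_true(all(c(0.5, 20) %in% dose_mg))
  expect_true(all(obs$TIME > 0))
  # deterministic subject: all predictions clear the assay floor
  pop0 <- population_params(
    omega_cv = c(CL = 0, Km = 0, Vmax = 0, F = 0, V_delta = 0,
                 BASE_adult = 0, BASE_child = 0), sigma_cv = 1e-9)
  ds0 <- generate_adult_study(pop = pop0, seed = 44)
  expect_true(all(ds0$DV[ds0$EVID == 0] > 14.1))
})

test_that("truth records serialise and reload the generating parameters", {
  recs <- lapply(c(3, 4, 5), function(s)
    truth_record(generate_pediatric_study(seed = s)))
  expect_equal(recs[[1]]$seed, 3)
  expect_false(identical(recs[[1]]$individuals$CL,
                         recs[[2]]$individuals$CL))
  f <- tempfile(fileext = ".json")
  ds <- generate_pediatric_study(seed = 3)
  truth_record(ds, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$individuals$CL,
               attr(ds, "truth")$individuals$CL, tolerance = 1e-12)
  expect_equal(back$binding$Bmax, population_params()$binding$Bmax,
               tolerance = 1e-12)
})
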