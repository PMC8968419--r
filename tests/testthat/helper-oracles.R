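# Independent oracles used across the suite.

# brute-force inversion of the binding equilibrium by bisection on Cu;
# deliberately ignorant of the closed-form quadratic
bisect_unbound <- function(A_total, p, g, tol = 1e-12) {
  if (A_total == 0) return(0)
  total_at <- function(cu) {
    cu * g$V_c * (1 + p$NS_Alb + p$KR) +
      g$V_c * p$Bmax * cu / (p$Kd + cu)
  }
  lo <- 0
  hi <- A_total / g$V_c  # Cu cannot exceed total/V_c
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (total_at(mid) < A_total) lo <- mid else hi <- mid
    if (hi - lo < tol * max(1, hi)) break
  }
  (lo + hi) / 2
}

# analytic trajectory of the fully linear model (first-order absorption,
# linear binding) via eigen-decomposition of the 3x3 rate matrix;
# states (depot, central total, peripheral), unbound Cu = Ac / L
linear_model_traj <- function(dose, ka, CL, Q, Vp, L, times) {
  A <- rbind(c(-ka, 0, 0),
             c(ka, -(CL + Q) / L, Q / Vp),
             c(0, Q / L, -Q / Vp))
  e <- eigen(A)
  c0 <- solve(e$vectors, c(dose, 0, 0))
  t(vapply(times, function(t)
    Re(e$vectors %*% (c0 * exp(e$values * t))), numeric(3)))
}

# random yet physically plausible binding parameters/geometry
random_binding_instance <- function() {
  p <- binding_params(Kd = stats::runif(1, 1, 50),
                      Bmax = stats::runif(1, 0, 2000),
                      NS_Alb = stats::runif(1, 0, 10),
                      KR = stats::runif(1, 0, 3))
  g <- blood_geometry(V_c = stats::runif(1, 0.5, 15),
                      V_delta = stats::runif(1, 0, 12),
                      weight = 20, age_group = "children_infants")
  list(p = p, g = g)
}

# small deterministic dataset builder: one adult subject whose
# observations equal the model predictions exactly
exact_adult_dataset <- function(dose_mg = 5, times = c(1, 2, 4, 8),
                                weight = 70) {
  pop <- population_params(
    omega_cv = c(CL = 0, Km = 0, Vmax = 0, F = 0, V_delta = 0,
                 BASE_adult = 0, BASE_child = 0))
  st <- allometric_scale(pop$structural, weight)
  st$BASE_pla <- pop$BASE_adult
  g <- blood_geometry(V_c = st$V_c, V_delta = 0, weight = weight,
                      age_group = "adult")
  prof <- simulate_profile(dose_events(0, dose_mg), st, pop$binding, g,
                           times = c(0, times))
  dv <- prof$C_pla[match(times, prof$time)]
  ds <- rbind(
    data.frame(ID = 1, TIME = 0, EVID = 1, AMT = dose_to_nmol(dose_mg),
               DV = NA_real_, DVID = 0, MDV = 1, WT = weight,
               AGEGRP = "adult", LLOQ = NA_real_, BLQ = 0),
    data.frame(ID = 1, TIME = times, EVID = 0, AMT = 0, DV = dv,
               DVID = 1, MDV = 0, WT = weight, AGEGRP = "adult",
               LLOQ = 14.1, BLQ = 0))
  list(ds = ds, pop = pop, pred = dv)
}
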