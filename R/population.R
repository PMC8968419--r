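#' Population parameters
#'
#' Typical values, interindividual variability (IIV) and residual error of
#' the joint adult/pediatric model.  IIV is log-normal; `omega_cv` holds
#' coefficients of variation in percent, converted internally to log-scale
#' standard deviations via `sqrt(log(1 + (cv/100)^2))`, so that the CV of
#' the resulting log-normal equals the stated value exactly.  Residual
#' error is additive on the log scale (exponential error), with a single
#' variance shared by all observation types.
#'
#' The defaults are the estimates of the joint model: unbound clearance
#' 400 L/h, central volume 10.6 L, intercompartmental clearance 160 L/h,
#' peripheral volume 124 L (all referenced to 70 kg), Km 4810 nmol,
#' Vmax 21388 nmol/h, F 1; apparent RBC volume 11.1 L (children/infants)
#' and 1.05 L (neonates); baselines 15.2 (adult plasma), 9.41 (pediatric
#' plasma) and 4.22 nmol/L (pediatric DBS); IIV CVs 25.8 (CL), 55.7 (Km),
#' 46.5 (Vmax), 36.1 (F), 43.4 (V_delta), 35.3 (adult baseline) and 131.1%
#' (shared pediatric baseline); residual CV 14.4%.
#'
#' @param structural [structural_params()] at the 70 kg reference (without
#'   baselines; baselines are population-level fields here).
#' @param binding [binding_params()].
#' @param V_delta named vector of apparent RBC volumes per pediatric age
#'   group, L.
#' @param BASE_adult,BASE_child_pla,BASE_child_DBS baselines, nmol/L.
#' @param omega_cv named vector of IIV CVs in percent for
#'   `CL`, `Km`, `Vmax`, `F`, `V_delta`, `BASE_adult`, `BASE_child`.
#' @param sigma_cv residual CV in percent.
#' @return An object of class `"population_params"`.
#' @export
population_params <- function(structural = structural_params(),
                              binding = binding_params(),
                              V_delta = c(children_infants = 11.1,
                                          neonate = 1.05),
                              BASE_adult = 15.2,
                              BASE_child_pla = 9.41,
                              BASE_child_DBS = 4.22,
                              omega_cv = c(CL = 25.8, Km = 55.7,
                                           Vmax = 46.5, F = 36.1,
                                           V_delta = 43.4,
                                           BASE_adult = 35.3,
                                           BASE_child = 131.1),
                              sigma_cv = 14.4) {
  stopifnot(inherits(structural, "structural_params"),
            inherits(binding, "binding_params"),
            all(c("children_infants", "neonate") %in% names(V_delta)),
            all(V_delta >= 0), all(omega_cv >= 0), sigma_cv > 0)
  full_omega <- c(CL = 0, Km = 0, Vmax = 0, F = 0, V_delta = 0,
                  BASE_adult = 0, BASE_child = 0)
  full_omega[names(omega_cv)] <- omega_cv
  structure(list(structural = structural, binding = binding,
                 V_delta = V_delta, BASE_adult = BASE_adult,
                 BASE_child_pla = BASE_child_pla,
                 BASE_child_DBS = BASE_child_DBS,
                 omega_cv = full_omega,
                 omega = cv_to_sdlog(full_omega),
                 sigma_cv = sigma_cv,
                 sigma = cv_to_sdlog(sigma_cv)),
            class = "population_params")
}

# CV (percent) of a log-normal -> SD of the underlying normal
cv_to_sdlog <- function(cv) sqrt(log(1 + (cv / 100)^2))
sdlog_to_cv <- function(sd) 100 * sqrt(exp(sd^2) - 1)

#' @export
print.population_params <- function(x, ...) {
  cat("Population PK parameters (cortisol plasma + DBS model)\n")
  print(x$structural)
  print(x$binding)
  cat(sprintf("  V_delta: children/infants %.3g L, neonates %.3g L\n",
              x$V_delta[["children_infants"]], x$V_delta[["neonate"]]))
  cat(sprintf("  baselines: adult pla %.3g, child pla %.3g, child DBS %.3g nmol/L\n",
              x$BASE_adult, x$BASE_child_pla, x$BASE_child_DBS))
  cat("  IIV (%CV):",
      paste(sprintf("%s %.3g", names(x$omega_cv), x$omega_cv),
            collapse = ", "), "\n")
  cat(sprintf("  residual error: %.3g %%CV (log-additive)\n", x$sigma_cv))
  invisible(x)
}

# run an expression under a seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# eta layout shared by simulation and estimation
ETA_NAMES <- c("CL", "Km", "Vmax", "F", "V_delta", "BASE")

# map population params + covariates + eta matrix to individual parameters;
# covariates: data.frame(weight, age_group); eta: matrix n x 6 (ETA_NAMES)
individual_params <- function(pop, covariates, eta = NULL) {
  n <- nrow(covariates)
  if (is.null(eta)) eta <- matrix(0, n, length(ETA_NAMES),
                                  dimnames = list(NULL, ETA_NAMES))
  th <- pop$structural
  w <- covariates$weight
  ag <- as.character(covariates$age_group)
  f_cl <- (w / 70)^0.75
  f_v <- w / 70
  ped <- ag != "adult"
  Vd <- ifelse(ped, pop$V_delta[ifelse(ag == "neonate", "neonate",
                                       "children_infants")], 0)
  out <- data.frame(
    weight = w, age_group = ag,
    CL = th$CL * f_cl * exp(eta[, "CL"]),
    Q = th$Q * f_cl,
    V_c = th$V_c * f_v,
    V_p = th$V_p * f_v,
    Km = th$Km * exp(eta[, "Km"]),
    Vmax = th$Vmax * exp(eta[, "Vmax"]),
    F = th$F * exp(eta[, "F"]),
    V_delta = Vd * exp(ifelse(ped, eta[, "V_delta"], 0)),
    KR = ifelse(ped, pop$binding$KR, 0),
    BASE_pla = ifelse(ped, pop$BASE_child_pla * exp(eta[, "BASE"]),
                      pop$BASE_adult * exp(eta[, "BASE"])),
    BASE_DBS = ifelse(ped, pop$BASE_child_DBS * exp(eta[, "BASE"]), 0),
    stringsAsFactors = FALSE)
  attr(out, "eta") <- eta
  out
}

#' Draw individual parameters from the population model
#'
#' Samples per-subject structural parameters: typical value, allometric
#' weight scaling, then a log-normal individual deviation
#' `exp(eta)`, `eta ~ N(0, omega^2)` per parameter with IIV.  The apparent
#' RBC volume is selected by age group before its own eta is applied, and
#' the two pediatric baselines (plasma and DBS) share a single eta, as in
#' the source model.  Adults carry no RBC pool (`V_delta = 0`, `KR = 0`).
#'
#' @param pop [population_params()].
#' @param covariates data.frame with columns `weight` (kg) and `age_group`
#'   (`"adult"`, `"children_infants"`, `"neonate"`).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return data.frame of individual parameters (one row per subject) with
#'   the eta matrix in attribute `"eta"`.
#' @export
draw_individual <- function(pop, covariates, seed = NULL) {
  stopifnot(inherits(pop, "population_params"),
            all(c("weight", "age_group") %in% names(covariates)))
  if (!all(covariates$age_group %in%
           c("adult", "children_infants", "neonate")))
    stop("unknown age group")
  n <- nrow(covariates)
  with_seed(seed, {
    eta <- matrix(0, n, length(ETA_NAMES),
                  dimnames = list(NULL, ETA_NAMES))
    om <- pop$omega
    ped <- covariates$age_group != "adult"
    for (k in c("CL", "Km", "Vmax", "F")) {
      if (om[[k]] > 0) eta[, k] <- stats::rnorm(n, 0, om[[k]])
    }
    if (om[["V_delta"]] > 0 && any(ped))
      eta[ped, "V_delta"] <- stats::rnorm(sum(ped), 0, om[["V_delta"]])
    if (om[["BASE_adult"]] > 0 && any(!ped))
      eta[!ped, "BASE"] <- stats::rnorm(sum(!ped), 0, om[["BASE_adult"]])
    if (om[["BASE_child"]] > 0 && any(ped))
      eta[ped, "BASE"] <- stats::rnorm(sum(ped), 0, om[["BASE_child"]])
    individual_params(pop, covariates, eta)
  })
}

#' Apply residual error to model predictions
#'
#' Exponential residual error: `observed = pred * exp(eps)` with
#' `eps ~ N(0, sigma^2)`, i.e. additive error on the log scale.
#'
#' @param pred predicted concentrations, nmol/L (> 0).
#' @param sigma log-scale residual SD; defaults to the model value
#'   (14.4% CV).
#' @param seed optional seed.
#' @return perturbed observations, same length as `pred`.
#' @export
apply_residual <- function(pred, sigma = cv_to_sdlog(14.4), seed = NULL) {
  if (any(!is.finite(pred)) || any(pred <= 0))
    stop("'pred' must be positive")
  stopifnot(sigma >= 0)
  with_seed(seed, pred * exp(stats::rnorm(length(pred), 0, sigma)))
}

#' Discard observations below the limit of quantification
#'
#' Removes observation records flagged below the LLOQ (M1 handling, as in
#' the source analysis where all BLQ observations were discarded).
#' Subjects whose pre-dose observation was discarded are flagged so that
#' their baseline is estimated rather than anchored to the pre-dose value.
#'
#' @param ds study dataset (see [read_dataset()] for the column contract).
#' @return list with elements `data` (filtered dataset), `n_discarded`
#'   (named count per observation type) and `predose_blq` (data.frame of
#'   subject/type pairs whose pre-dose record was discarded).
#' @export
filter_blq <- function(ds) {
  obs <- ds$EVID == 0
  blq <- obs & ds$BLQ == 1
  n_disc <- c(plasma = sum(blq & ds$DVID == 1),
              DBS = sum(blq & ds$DVID == 2))
  predose <- ds[blq & ds$TIME == 0, c("ID", "DVID"), drop = FALSE]
  list(data = ds[!blq, , drop = FALSE],
       n_discarded = n_disc,
       predose_blq = predose)
}
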