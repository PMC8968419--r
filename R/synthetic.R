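#' Pediatric study design
#'
#' Design emulating the sparse pediatric study: three cohorts (young
#' children n = 12, 2-6 y; infants n = 6, 28 d-2 y; term neonates n = 6,
#' 0-28 d), each subject receiving a single morning dose of 1-4 mg with
#' paired plasma and DBS samples pre-dose and 1 and 4 h post-dose.
#' Children additionally contribute two samples between 0.5 and 1.5 h and
#' one late sample near the trough.  (The source protocol's "30 and 90"
#' window for the extra samples is interpreted in minutes: with a cortisol
#' half-life of 1-2 h a 30-90 hour window would sample nothing but
#' baseline.)  LLOQ is 14.1 nmol/L for plasma and 1.8 nmol/L for DBS.
#'
#' @param n_children,n_infants,n_neonates cohort sizes.
#' @param extra_child_times extra sampling times for children, h.
#' @return list of class `"study_design"`.
#' @export
pediatric_design <- function(n_children = 12, n_infants = 6,
                             n_neonates = 6,
                             extra_child_times = c(0.5, 1.5, 6)) {
  structure(list(
    type = "pediatric",
    arms = list(
      children = list(n = n_children, age_range_y = c(2, 6),
                      weight_range = c(10, 22),
                      times = sort(c(0, 1, 4, extra_child_times))),
      infants = list(n = n_infants, age_range_y = c(28 / 365, 2),
                     weight_range = c(4, 11), times = c(0, 1, 4)),
      neonates = list(n = n_neonates, age_range_y = c(0, 28 / 365),
                      weight_range = c(2.5, 4.5), times = c(0, 1, 4))),
    lloq = c(plasma = 14.1, DBS = 1.8)),
    class = "study_design")
}

#' Adult study design
#'
#' Design emulating the rich adult study: 30 dexamethasone-suppressed
#' healthy adults, single doses spanning 0.5-20 mg, plasma-only sampling
#' at 12 times over 12 h.
#'
#' @param n number of subjects.
#' @param doses_mg dose ladder recycled over subjects; spans 0.5-20 mg.
#' @param times sampling times, h.
#' @return list of class `"study_design"`.
#' @export
adult_design <- function(n = 30,
                         doses_mg = c(0.5, 1, 2, 3, 5, 7.5, 10, 12, 15,
                                      20),
                         times = c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6,
                                   8, 10, 12)) {
  structure(list(type = "adult", n = n, doses_mg = doses_mg,
                 times = times, weight_mean = 75, weight_sd = 10,
                 weight_range = c(55, 100),
                 lloq = c(plasma = 14.1, DBS = 1.8)),
            class = "study_design")
}

# deterministic dose rule: mg in {1..4}, highest mg/kg in neonates
pediatric_dose_mg <- function(weight, arm) {
  switch(arm,
         neonates = ifelse(weight >= 3, 4, 3),
         infants = pmin(4, pmax(1, round(0.35 * weight))),
         children = pmin(4, pmax(2, round(0.2 * weight))))
}

# simulate subjects' observations given individual params and a schedule;
# returns long data.frame of observation rows (EVID 0)
simulate_observations <- function(ind, doses_nmol, schedule, pop,
                                  residual = TRUE) {
  n <- nrow(ind)
  pars <- cbind(ind$CL, ind$Q, ind$V_c, ind$V_p, ind$Km, ind$Vmax,
                pop$binding$Bmax, ind$KR, pop$binding$Kd,
                pop$binding$NS_Alb)
  y0 <- cbind(ind$F * doses_nmol, 0, 0, 0)
  all_times <- sort(unique(c(0, unlist(lapply(schedule, `[[`, "times")))))
  arr <- cort_solve(pars, y0, all_times)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ti <- schedule[[i]]$times
    types <- schedule[[i]]$types           # subset of c("plasma","DBS")
    idx <- match(ti, all_times)
    Ac <- pmax(arr[idx, "A_central", i], 0)
    Cu <- cu_solve(Ac, ind$V_c[i], pop$binding$Bmax, ind$KR[i],
                   pop$binding$Kd, pop$binding$NS_Alb)
    A_RBC <- ind$KR[i] * Cu * ind$V_c[i]
    pred_pla <- (Ac - A_RBC) / ind$V_c[i] + ind$BASE_pla[i]
    pred_dbs <- Ac / (ind$V_c[i] + ind$V_delta[i]) + ind$BASE_DBS[i]
    sub <- list()
    if ("plasma" %in% types)
      sub$pla <- data.frame(TIME = ti, DVID = 1, PRED = pred_pla)
    if ("DBS" %in% types)
      sub$dbs <- data.frame(TIME = ti, DVID = 2, PRED = pred_dbs)
    d <- do.call(rbind, sub)
    d$ID <- i
    rows[[i]] <- d
  }
  obs <- do.call(rbind, rows)
  obs$DV <- obs$PRED
  if (residual && pop$sigma > 0)
    obs$DV <- obs$DV * exp(stats::rnorm(nrow(obs), 0, pop$sigma))
  obs
}

# vectorised binding inversion with per-element parameters
cu_solve <- function(Ac, Vc, Bmax, KR, Kd, NS) {
  L <- Vc * (1 + NS + KR)
  b <- L * Kd + Bmax * Vc - Ac
  disc <- sqrt(b * b + 4 * L * Ac * Kd)
  ifelse(b >= 0, ifelse(Ac <= 0, 0, 2 * Ac * Kd / (b + disc)),
         (-b + disc) / (2 * L))
}

# assemble dose + observation rows into the NONMEM-like dataset layout
assemble_dataset <- function(obs, ind, doses_nmol, lloq_map) {
  n <- nrow(ind)
  dose_rows <- data.frame(ID = seq_len(n), TIME = 0, EVID = 1,
                          AMT = doses_nmol, DV = NA_real_, DVID = 0,
                          MDV = 1, WT = ind$weight,
                          AGEGRP = ind$age_group, LLOQ = NA_real_,
                          BLQ = 0)
  obs$LLOQ <- unname(lloq_map[ifelse(obs$DVID == 1, "plasma", "DBS")])
  obs$BLQ <- as.integer(obs$DV < obs$LLOQ)
  obs_rows <- data.frame(ID = obs$ID, TIME = obs$TIME, EVID = 0,
                         AMT = 0, DV = obs$DV, DVID = obs$DVID, MDV = 0,
                         WT = ind$weight[obs$ID],
                         AGEGRP = ind$age_group[obs$ID], LLOQ = obs$LLOQ,
                         BLQ = obs$BLQ)
  ds <- rbind(dose_rows, obs_rows)
  ds <- ds[order(ds$ID, ds$TIME, ds$EVID == 0, ds$DVID), ]
  rownames(ds) <- NULL
  ds
}

#' Generate a synthetic pediatric study
#'
#' Draws ages and weights per cohort (weights interpolated across the age
#' band with log-normal noise), assigns doses by the deterministic
#' weight-band rule (neonates receive the relatively highest mg/kg),
#' simulates paired plasma and DBS concentrations under the population
#' model, applies exponential residual error and flags observations below
#' the LLOQ.  The exact generating parameters are attached as attribute
#' `"truth"` for parameter-recovery experiments.
#'
#' @param design [pediatric_design()].
#' @param pop [population_params()].
#' @param seed integer seed (byte-identical output for equal seeds).
#' @return NONMEM-like data.frame with columns `ID`, `TIME`, `EVID`,
#'   `AMT`, `DV`, `DVID`, `MDV`, `WT`, `AGEGRP`, `LLOQ`, `BLQ`.
#' @export
generate_pediatric_study <- function(design = pediatric_design(),
                                     pop = population_params(),
                                     seed = NULL) {
  stopifnot(inherits(design, "study_design"), design$type == "pediatric")
  with_seed(seed, {
    cov_list <- list(); sched <- list(); dose_mg <- numeric(0)
    for (arm in names(design$arms)) {
      a <- design$arms[[arm]]
      if (a$n == 0L) next
      age <- stats::runif(a$n, a$age_range_y[1], a$age_range_y[2])
      rel <- (age - a$age_range_y[1]) / diff(a$age_range_y)
      w_mid <- a$weight_range[1] + rel * diff(a$weight_range)
      w <- pmin(a$weight_range[2],
                pmax(a$weight_range[1], w_mid * exp(stats::rnorm(a$n, 0, 0.1))))
      grp <- if (arm == "neonates") "neonate" else "children_infants"
      cov_list[[arm]] <- data.frame(weight = w, age_group = grp,
                                    cohort = arm, age_y = age)
      dose_mg <- c(dose_mg, pediatric_dose_mg(w, arm))
      sched <- c(sched, rep(list(list(times = a$times,
                                      types = c("plasma", "DBS"))), a$n))
    }
    covariates <- do.call(rbind, cov_list)
    rownames(covariates) <- NULL
    ind <- draw_individual(pop, covariates)
    obs <- simulate_observations(ind, dose_to_nmol(dose_mg), sched, pop)
    ds <- assemble_dataset(obs, ind, dose_to_nmol(dose_mg), design$lloq)
    attr(ds, "truth") <- list(pop = pop, individuals = ind,
                              covariates = covariates,
                              dose_mg = dose_mg, seed = seed)
    ds
  })
}

#' Generate a synthetic adult study
#'
#' 30 dexamethasone-suppressed adults with a constant (suppressed) plasma
#' baseline, single doses recycled over a 0.5-20 mg ladder, truncated
#' normal weights, rich plasma-only sampling.
#'
#' @param design [adult_design()].
#' @param pop [population_params()].
#' @param seed integer seed.
#' @return dataset as in [generate_pediatric_study()].
#' @export
generate_adult_study <- function(design = adult_design(),
                                 pop = population_params(),
                                 seed = NULL) {
  stopifnot(inherits(design, "study_design"), design$type == "adult")
  with_seed(seed, {
    n <- design$n
    w <- stats::rnorm(n, design$weight_mean, design$weight_sd)
    w <- pmin(design$weight_range[2], pmax(design$weight_range[1], w))
    dose_mg <- rep_len(design$doses_mg, n)
    covariates <- data.frame(weight = w, age_group = "adult",
                             cohort = "adult", age_y = NA_real_)
    ind <- draw_individual(pop, covariates)
    sched <- rep(list(list(times = design$times, types = "plasma")), n)
    obs <- simulate_observations(ind, dose_to_nmol(dose_mg), sched, pop)
    ds <- assemble_dataset(obs, ind, dose_to_nmol(dose_mg), design$lloq)
    attr(ds, "truth") <- list(pop = pop, individuals = ind,
                              covariates = covariates,
                              dose_mg = dose_mg, seed = seed)
    ds
  })
}

#' Combined recovery dataset
#'
#' A rich design for parameter-recovery experiments: adult subjects with
#' 12 plasma samples each plus pediatric subjects (children/infants and
#' neonates) with paired plasma/DBS samples, all generated at the model's
#' default parameter values so the truth is known by construction.
#'
#' @param n_adult,n_children,n_neonates subject counts (default 26/12/12,
#'   i.e. 50 subjects).
#' @param pop [population_params()].
#' @param seed integer seed.
#' @param ped_times pediatric sampling times, h.
#' @return dataset with `"truth"` attribute.
#' @export
generate_recovery_study <- function(n_adult = 26, n_children = 12,
                                    n_neonates = 12,
                                    pop = population_params(),
                                    seed = NULL,
                                    ped_times = c(0, 0.5, 1, 2, 4, 6)) {
  with_seed(seed, {
    s1 <- if (is.null(seed)) NULL else seed + 1L
    s2 <- if (is.null(seed)) NULL else seed + 2L
    ad <- generate_adult_study(adult_design(n = n_adult), pop, seed = s1)
    des <- pediatric_design(n_children = n_children, n_infants = 0,
                            n_neonates = n_neonates,
                            extra_child_times = setdiff(ped_times,
                                                        c(0, 1, 4)))
    des$arms$neonates$times <- sort(unique(ped_times))  # richer than sparse study
    pd <- generate_pediatric_study(des, pop, seed = s2)
    pd$ID <- pd$ID + n_adult
    ds <- rbind(ad, pd)
    tr_a <- attr(ad, "truth"); tr_p <- attr(pd, "truth")
    attr(ds, "truth") <- list(
      pop = pop,
      individuals = rbind(tr_a$individuals, tr_p$individuals),
      covariates = rbind(tr_a$covariates, tr_p$covariates),
      dose_mg = c(tr_a$dose_mg, tr_p$dose_mg), seed = seed)
    ds
  })
}

#' Serialize the generating truth of a synthetic dataset
#'
#' Writes (or returns) the exact population and individual parameters used
#' to generate a dataset, so estimation results can be compared against a
#' known truth and draws can be reproduced from the stored seed.
#'
#' @param ds dataset produced by one of the generators.
#' @param path optional JSON path; if given, the record is written there.
#' @return the truth record (list), invisibly when written to `path`.
#' @export
truth_record <- function(ds, path = NULL) {
  tr <- attr(ds, "truth")
  if (is.null(tr)) stop("dataset carries no generating truth")
  rec <- list(seed = tr$seed,
              theta = unclass(tr$pop$structural)[
                c("CL", "V_c", "Q", "V_p", "Km", "Vmax", "F")],
              binding = unclass(tr$pop$binding)[
                c("Kd", "Bmax", "NS_Alb", "KR")],
              V_delta = as.list(tr$pop$V_delta),
              baselines = list(adult_pla = tr$pop$BASE_adult,
                               child_pla = tr$pop$BASE_child_pla,
                               child_DBS = tr$pop$BASE_child_DBS),
              omega_cv = as.list(tr$pop$omega_cv),
              sigma_cv = tr$pop$sigma_cv,
              dose_mg = tr$dose_mg,
              individuals = tr$individuals)
  if (!is.null(path)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    return(invisible(rec))
  }
  rec
}
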