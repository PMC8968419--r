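# Marginal likelihood machinery.
#
# The marginal -2 log-likelihood is computed by a Laplace-type
# approximation: per-subject empirical-Bayes modes of the log-normal
# random effects are located by a damped Gauss-Newton search, and the
# curvature term uses the Gauss-Newton Hessian J'J/sigma^2 + Omega^-1 on
# the log-prediction scale (the model has log-additive residual error, so
# residuals and Jacobians live on the log scale throughout).
#
# All subjects are integrated in ONE stacked ODE call per function or
# finite-difference evaluation: subjects are independent, so perturbing
# the same eta coordinate in every subject simultaneously yields all
# per-subject directional derivatives from a single solve.  This is what
# makes likelihood evaluation fast enough for sampling importance
# resampling.

# precompute everything the likelihood needs from a dataset
ll_prepare <- function(ds) {
  req <- c("ID", "TIME", "EVID", "AMT", "DV", "DVID", "MDV", "WT",
           "AGEGRP", "LLOQ", "BLQ")
  miss <- setdiff(req, names(ds))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "))
  fb <- filter_blq(ds)
  d <- fb$data
  ids <- unique(d$ID)
  N <- length(ids)
  first <- match(ids, d$ID)
  covariates <- data.frame(weight = d$WT[first],
                           age_group = as.character(d$AGEGRP[first]),
                           stringsAsFactors = FALSE)
  ped <- covariates$age_group != "adult"

  dr <- d[d$EVID == 1, , drop = FALSE]
  if (any(dr$TIME > 0))
    stop("the likelihood supports a single dose administration at time 0")
  dose_nmol <- as.numeric(tapply(dr$AMT, factor(dr$ID, levels = ids),
                                 sum, default = 0))
  dose_nmol[is.na(dose_nmol)] <- 0

  obs <- d[d$EVID == 0 & d$MDV == 0 & !is.na(d$DV), , drop = FALSE]
  si <- match(obs$ID, ids)

  # pediatric pre-dose observations anchor the subject's baseline and are
  # removed from the residual likelihood
  anch_pla <- rep(NA_real_, N)
  anch_dbs <- rep(NA_real_, N)
  is_anchor <- obs$TIME == 0 & ped[si]
  a_pla <- is_anchor & obs$DVID == 1
  a_dbs <- is_anchor & obs$DVID == 2
  anch_pla[si[a_pla]] <- obs$DV[a_pla]
  anch_dbs[si[a_dbs]] <- obs$DV[a_dbs]
  obs <- obs[!is_anchor, , drop = FALSE]
  si <- si[!is_anchor]

  times <- sort(unique(c(0, obs$TIME)))
  structure(list(
    ids = ids, N = N, covariates = covariates, ped = ped,
    dose_nmol = dose_nmol,
    obs_subj = si, obs_tidx = match(obs$TIME, times),
    obs_dvid = obs$DVID, log_dv = log(obs$DV), times = times,
    anch_pla = anch_pla, anch_dbs = anch_dbs,
    has_pla = as.logical(tapply(obs$DVID == 1,
                                factor(si, levels = seq_len(N)), any,
                                default = FALSE)),
    has_dbs = as.logical(tapply(obs$DVID == 2,
                                factor(si, levels = seq_len(N)), any,
                                default = FALSE)),
    n_obs = as.integer(tapply(rep(1L, length(si)),
                              factor(si, levels = seq_len(N)), sum,
                              default = 0L)),
    n_discarded = fb$n_discarded),
    class = "ll_prep")
}

# log-predictions at all retained observations for a given eta matrix
ll_logpred <- function(pop, prep, eta, rtol = 1e-6, atol = 1e-8) {
  ind <- individual_params(pop, prep$covariates, eta)
  fx_p <- !is.na(prep$anch_pla)
  fx_d <- !is.na(prep$anch_dbs)
  ind$BASE_pla[fx_p] <- prep$anch_pla[fx_p]
  ind$BASE_DBS[fx_d] <- prep$anch_dbs[fx_d]
  b <- pop$binding
  pars <- cbind(ind$CL, ind$Q, ind$V_c, ind$V_p, ind$Km, ind$Vmax,
                b$Bmax, ind$KR, b$Kd, b$NS_Alb)
  y0 <- cbind(ind$F * prep$dose_nmol, 0, 0, 0)
  arr <- cort_solve(pars, y0, prep$times, rtol = rtol, atol = atol)
  Ac_mat <- matrix(pmax(arr[, "A_central", ], 0),
                   nrow = length(prep$times))
  s <- prep$obs_subj
  Ac <- Ac_mat[cbind(prep$obs_tidx, s)]
  Cu <- cu_solve(Ac, ind$V_c[s], b$Bmax, ind$KR[s], b$Kd, b$NS_Alb)
  A_RBC <- ind$KR[s] * Cu * ind$V_c[s]
  pred <- ifelse(prep$obs_dvid == 1,
                 (Ac - A_RBC) / ind$V_c[s] + ind$BASE_pla[s],
                 Ac / (ind$V_c[s] + ind$V_delta[s]) + ind$BASE_DBS[s])
  log(pmax(pred, 1e-12))
}

# which etas are active (carry IIV and are informed by data) per subject,
# and the per-subject log-scale SD of each active eta
ll_eta_layout <- function(pop, prep) {
  N <- prep$N
  om <- pop$omega
  act <- matrix(FALSE, N, length(ETA_NAMES),
                dimnames = list(NULL, ETA_NAMES))
  has_obs <- prep$n_obs > 0
  for (k in c("CL", "Km", "Vmax", "F"))
    act[, k] <- om[[k]] > 0 & has_obs
  act[, "V_delta"] <- prep$ped & om[["V_delta"]] > 0 & prep$has_dbs
  base_free_pla <- prep$has_pla & is.na(prep$anch_pla)
  base_free_dbs <- prep$has_dbs & is.na(prep$anch_dbs)
  act[, "BASE"] <- ifelse(prep$ped,
                          om[["BASE_child"]] > 0 &
                            (base_free_pla | base_free_dbs),
                          om[["BASE_adult"]] > 0 & has_obs)
  sd <- matrix(rep(c(om[["CL"]], om[["Km"]], om[["Vmax"]], om[["F"]],
                     om[["V_delta"]], 0), each = N), N)
  colnames(sd) <- ETA_NAMES
  sd[, "BASE"] <- ifelse(prep$ped, om[["BASE_child"]], om[["BASE_adult"]])
  list(act = act, sd = sd)
}

# per-subject objective: sum(e^2)/sigma^2 + sum(eta^2/omega^2) over active
ll_subject_obj <- function(prep, lay, eta, logpred, sigma) {
  e <- prep$log_dv - logpred
  sse <- as.numeric(rowsum(e^2, prep$obs_subj,
                           reorder = FALSE)[as.character(seq_len(prep$N)),
                                            1])
  sse[is.na(sse)] <- 0
  pen <- rowSums(ifelse(lay$act, (eta / lay$sd)^2, 0))
  list(obj = sse / sigma^2 + pen, e = e, sse = sse)
}

#' Marginal -2 log-likelihood of the population model
#'
#' Laplace-type approximation to minus twice the marginal log-likelihood
#' of a (BLQ-filtered) study dataset under the population model: for each
#' subject the empirical-Bayes mode of the log-normal random effects is
#' found by damped Gauss-Newton, and the Gaussian integral over the random
#' effects is approximated using the Gauss-Newton curvature on the
#' log-prediction scale.  Deterministic given data and starting point.
#'
#' Pediatric pre-dose observations above the LLOQ fix the subject's
#' baseline and are excluded from the residual term; pediatric baselines
#' without such an anchor are estimated through their (shared) random
#' effect.
#'
#' @param pop [population_params()].
#' @param ds study dataset, or a prepared object from a previous call
#'   (attribute `"prep"`).
#' @param control list: `rtol`, `atol` (solver), `inner_maxit`,
#'   `inner_tol` (eta search), `fd_step` (Jacobian step).
#' @param eta_init optional warm-start eta matrix.
#' @return the -2 log-likelihood (scalar) with attributes `"eta"`
#'   (empirical-Bayes modes), `"logpred"` and `"prep"`.
#' @export
neg2ll <- function(pop, ds, control = list(), eta_init = NULL) {
  ctl <- utils::modifyList(list(rtol = 1e-6, atol = 1e-8,
                                inner_maxit = 12L, inner_tol = 1e-4,
                                inner_obj_tol = 1e-3, fd_step = 1e-4),
                           control)
  prep <- if (inherits(ds, "ll_prep")) ds else ll_prepare(ds)
  N <- prep$N
  sigma <- pop$sigma
  lay <- ll_eta_layout(pop, prep)
  act <- lay$act
  eta <- matrix(0, N, length(ETA_NAMES),
                dimnames = list(NULL, ETA_NAMES))
  if (!is.null(eta_init)) eta[, ] <- eta_init
  eta[!act] <- 0
  cols <- which(apply(act, 2, any))
  h <- ctl$fd_step

  lp <- ll_logpred(pop, prep, eta, ctl$rtol, ctl$atol)
  cur <- ll_subject_obj(prep, lay, eta, lp, sigma)
  J <- matrix(0, length(lp), length(ETA_NAMES))
  Hlist <- vector("list", N)

  for (it in seq_len(ctl$inner_maxit)) {
    if (length(cols) == 0L) break
    for (k in cols) {
      ek <- eta
      ek[act[, k], k] <- ek[act[, k], k] + h
      lpk <- ll_logpred(pop, prep, ek, ctl$rtol, ctl$atol)
      J[, k] <- (lpk - lp) / h
      J[!act[prep$obs_subj, k], k] <- 0
    }
    step <- matrix(0, N, length(ETA_NAMES))
    for (i in seq_len(N)) {
      ai <- which(act[i, ])
      if (length(ai) == 0L) next
      oi <- which(prep$obs_subj == i)
      Ji <- J[oi, ai, drop = FALSE]
      Hi <- crossprod(Ji) / sigma^2 + diag(1 / lay$sd[i, ai]^2,
                                           length(ai))
      gi <- -crossprod(Ji, cur$e[oi]) / sigma^2 +
        eta[i, ai] / lay$sd[i, ai]^2
      Hlist[[i]] <- Hi
      step[i, ai] <- tryCatch(-solve(Hi, gi),
                              error = function(err) rep(0, length(ai)))
    }
    # per-subject damped line search, one stacked solve per trial
    tfac <- rep(1, N)
    done <- rowSums(abs(step)) == 0
    best_eta <- eta
    for (ls in 1:4) {
      if (all(done)) break
      etry <- best_eta
      etry[!done, ] <- eta[!done, ] + tfac[!done] * step[!done, ]
      lpt <- ll_logpred(pop, prep, etry, ctl$rtol, ctl$atol)
      tryobj <- ll_subject_obj(prep, lay, etry, lpt, sigma)
      better <- !done & (tryobj$obj <= cur$obj + 1e-10)
      best_eta[better, ] <- etry[better, ]
      done <- done | better
      tfac[!done] <- tfac[!done] / 2
    }
    moved <- max(abs(best_eta - eta))
    eta <- best_eta
    prev <- sum(cur$obj)
    lp <- ll_logpred(pop, prep, eta, ctl$rtol, ctl$atol)
    cur <- ll_subject_obj(prep, lay, eta, lp, sigma)
    # stop on stationarity of either the modes or the joint objective
    # (flat prior directions can keep creeping without likelihood gain)
    if (moved < ctl$inner_tol || prev - sum(cur$obj) < ctl$inner_obj_tol)
      break
  }

  # curvature at the modes (reuse last Jacobian; refresh if never built)
  val <- 0
  for (i in seq_len(N)) {
    if (prep$n_obs[i] == 0L) next
    ai <- which(act[i, ])
    ll_i <- prep$n_obs[i] * log(2 * pi * sigma^2) + cur$sse[i] / sigma^2
    if (length(ai) > 0L) {
      oi <- which(prep$obs_subj == i)
      Ji <- J[oi, ai, drop = FALSE]
      Hi <- crossprod(Ji) / sigma^2 + diag(1 / lay$sd[i, ai]^2,
                                           length(ai))
      ll_i <- ll_i + sum(log(lay$sd[i, ai]^2)) +
        sum((eta[i, ai] / lay$sd[i, ai])^2) +
        2 * sum(log(diag(chol(Hi))))
    }
    if (!is.finite(ll_i)) ll_i <- 1e10  # flagged subject: large penalty
    val <- val + ll_i
  }
  structure(val, eta = eta, logpred = lp, prep = prep)
}
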