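# named accessors for the population parameter vector used by the
# optimiser, SIR, and reporting.  All parameters are positive and are
# optimised on the log scale.
PARAM_NAMES <- c("CL", "V_c", "Q", "V_p", "Km", "Vmax", "F",
                 "Vd_ch", "Vd_neo", "BASE_adult", "BASE_child_pla",
                 "BASE_child_DBS", "Bmax", "KR", "Kd", "NS_Alb",
                 "omega_CL", "omega_Km", "omega_Vmax", "omega_F",
                 "omega_V_delta", "omega_BASE_adult", "omega_BASE_child",
                 "sigma")

get_param <- function(pop, name) {
  switch(name,
         CL = pop$structural$CL, V_c = pop$structural$V_c,
         Q = pop$structural$Q, V_p = pop$structural$V_p,
         Km = pop$structural$Km, Vmax = pop$structural$Vmax,
         F = pop$structural$F,
         Vd_ch = pop$V_delta[["children_infants"]],
         Vd_neo = pop$V_delta[["neonate"]],
         BASE_adult = pop$BASE_adult,
         BASE_child_pla = pop$BASE_child_pla,
         BASE_child_DBS = pop$BASE_child_DBS,
         Bmax = pop$binding$Bmax, KR = pop$binding$KR,
         Kd = pop$binding$Kd, NS_Alb = pop$binding$NS_Alb,
         omega_CL = pop$omega_cv[["CL"]],
         omega_Km = pop$omega_cv[["Km"]],
         omega_Vmax = pop$omega_cv[["Vmax"]],
         omega_F = pop$omega_cv[["F"]],
         omega_V_delta = pop$omega_cv[["V_delta"]],
         omega_BASE_adult = pop$omega_cv[["BASE_adult"]],
         omega_BASE_child = pop$omega_cv[["BASE_child"]],
         sigma = pop$sigma_cv,
         stop("unknown parameter '", name, "'"))
}

set_params <- function(pop, values) {
  st <- pop$structural
  for (nm in names(values)) {
    v <- values[[nm]]
    switch(nm,
           CL = { st$CL <- v }, V_c = { st$V_c <- v },
           Q = { st$Q <- v }, V_p = { st$V_p <- v },
           Km = { st$Km <- v }, Vmax = { st$Vmax <- v },
           F = { st$F <- v },
           Vd_ch = { pop$V_delta[["children_infants"]] <- v },
           Vd_neo = { pop$V_delta[["neonate"]] <- v },
           BASE_adult = { pop$BASE_adult <- v },
           BASE_child_pla = { pop$BASE_child_pla <- v },
           BASE_child_DBS = { pop$BASE_child_DBS <- v },
           Bmax = { pop$binding$Bmax <- v },
           KR = { pop$binding$KR <- v },
           Kd = { pop$binding$Kd <- v },
           NS_Alb = { pop$binding$NS_Alb <- v },
           omega_CL = { pop$omega_cv[["CL"]] <- v },
           omega_Km = { pop$omega_cv[["Km"]] <- v },
           omega_Vmax = { pop$omega_cv[["Vmax"]] <- v },
           omega_F = { pop$omega_cv[["F"]] <- v },
           omega_V_delta = { pop$omega_cv[["V_delta"]] <- v },
           omega_BASE_adult = { pop$omega_cv[["BASE_adult"]] <- v },
           omega_BASE_child = { pop$omega_cv[["BASE_child"]] <- v },
           sigma = { pop$sigma_cv <- v },
           stop("unknown parameter '", nm, "'"))
  }
  pop$structural <- st
  pop$omega <- cv_to_sdlog(pop$omega_cv)
  pop$sigma <- cv_to_sdlog(pop$sigma_cv)
  pop
}

#' Fit the population model to a study dataset
#'
#' Maximum (Laplace-approximated) likelihood estimation of a chosen set of
#' free population parameters, all optimised on the log scale with
#' Nelder-Mead.  Parameters not listed in `free` stay frozen at their
#' values in `init`.  When emulating the source analysis, `Kd`, `NS_Alb`,
#' `F` and `Km` are frozen.  Non-convergence within the iteration budget is
#' reported in the `convergence` field, never silently.
#'
#' @param data study dataset (see [read_dataset()]); BLQ records are
#'   discarded on preparation.
#' @param init [population_params()] providing initial values and the
#'   frozen parameters.
#' @param free character vector of free parameter names, a subset of the
#'   package's parameter vocabulary: structural (`CL`, `V_c`, `Q`, `V_p`,
#'   `Km`, `Vmax`, `F`), volumes (`Vd_ch`, `Vd_neo`), baselines
#'   (`BASE_adult`, `BASE_child_pla`, `BASE_child_DBS`), binding (`Bmax`,
#'   `KR`, `Kd`, `NS_Alb`), IIV CVs (`omega_*`) and `sigma`.
#' @param control list merged over defaults: `maxit` (Nelder-Mead budget,
#'   default 350), `reltol` (1e-6), `hessian` (logical, default TRUE:
#'   numeric Hessian of the objective at the optimum, giving asymptotic
#'   standard errors and the SIR proposal covariance), plus the [neg2ll()]
#'   controls.
#' @param trace integer; > 0 prints optimiser progress.
#' @return An object of class `"hc_fit"`.
#' @export
hc_fit <- function(data,
                   init = population_params(),
                   free = c("CL", "V_c", "Q", "V_p", "Vmax", "Vd_ch",
                            "Vd_neo", "BASE_adult", "omega_CL", "sigma"),
                   control = list(), trace = 0) {
  stopifnot(all(free %in% PARAM_NAMES))
  ctl <- utils::modifyList(list(maxit = 350L, reltol = 1e-5,
                                hessian = TRUE, hess_step = 0.02),
                           control)
  prep <- ll_prepare(data)
  state <- new.env(parent = emptyenv())
  state$eta <- NULL
  state$count <- 0L
  objective <- function(lpar) {
    vals <- stats::setNames(exp(lpar), free)
    pop <- set_params(init, vals)
    v <- tryCatch(neg2ll(pop, prep, control = ctl,
                         eta_init = state$eta),
                  error = function(e) structure(1e10, eta = state$eta))
    state$eta <- attr(v, "eta")
    state$count <- state$count + 1L
    if (trace > 0 && state$count %% trace == 0)
      message(sprintf("eval %d: -2LL = %.4f", state$count, as.numeric(v)))
    as.numeric(v)
  }
  par0 <- log(vapply(free, get_param, numeric(1), pop = init))
  opt <- stats::optim(par0, objective, method = "Nelder-Mead",
                      control = list(maxit = ctl$maxit,
                                     reltol = ctl$reltol))
  est <- stats::setNames(exp(opt$par), free)
  pop_hat <- set_params(init, est)
  final <- neg2ll(pop_hat, prep, control = ctl, eta_init = state$eta)

  vcov_log <- NULL
  if (isTRUE(ctl$hessian) && length(free) > 0) {
    # deterministic objective for differencing: inner search warm-started
    # from the FIXED empirical-Bayes modes of the optimum and run to a
    # tighter tolerance, so finite differences see curvature, not the
    # path-dependence of the warm start
    eta_hat <- attr(final, "eta")
    hctl <- utils::modifyList(ctl, list(inner_obj_tol = 1e-5,
                                        inner_maxit = 20L))
    hess_obj <- function(lpar) {
      pop <- set_params(init, stats::setNames(exp(lpar), free))
      tryCatch(as.numeric(neg2ll(pop, prep, control = hctl,
                                 eta_init = eta_hat)),
               error = function(e) 1e10)
    }
    H <- tryCatch(stats::optimHess(opt$par, hess_obj,
                                   control = list(ndeps = rep(ctl$hess_step,
                                                              length(free)))),
                  error = function(e) NULL)
    if (!is.null(H)) {
      H <- (H + t(H)) / 2
      ev <- eigen(H, symmetric = TRUE)
      floorv <- max(abs(ev$values)) * 1e-6
      if (any(ev$values < floorv)) {   # repair indefinite curvature
        ev$values <- pmax(ev$values, floorv)
        H <- ev$vectors %*% (ev$values * t(ev$vectors))
      }
      vcov_log <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(vcov_log) && any(diag(vcov_log) <= 0)) vcov_log <- NULL
    }
  }
  if (is.null(vcov_log)) {
    # conservative diagonal proposal (20% CV on each parameter) keeps
    # downstream uncertainty steps usable when curvature is unavailable
    vcov_log <- diag(0.2^2, length(free))
    attr(vcov_log, "fallback") <- TRUE
  }
  dimnames(vcov_log) <- list(free, free)

  structure(list(coefficients = est, log_est = stats::setNames(opt$par,
                                                               free),
                 free = free, pop = pop_hat, init = init,
                 neg2ll = as.numeric(final), vcov_log = vcov_log,
                 eta = attr(final, "eta"),
                 logpred = attr(final, "logpred"), prep = prep,
                 convergence = opt$convergence, counts = opt$counts,
                 n_evals = state$count, control = ctl,
                 n_obs = length(prep$log_dv), n_subjects = prep$N),
            class = "hc_fit")
}

#' @export
print.hc_fit <- function(x, ...) {
  cat("Population PK fit (Laplace-type marginal likelihood)\n")
  cat(sprintf("  %d subjects, %d observations; -2LL = %.3f\n",
              x$n_subjects, x$n_obs, x$neg2ll))
  cat(sprintf("  convergence code %d (%d function evaluations)\n",
              x$convergence, x$n_evals))
  cat("  estimates:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.hc_fit <- function(object, ...) object$coefficients

#' @export
logLik.hc_fit <- function(object, ...) {
  structure(-object$neg2ll / 2, df = length(object$free),
            nobs = object$n_obs, class = "logLik")
}

#' @export
vcov.hc_fit <- function(object, ...) object$vcov_log

#' @export
summary.hc_fit <- function(object, ...) {
  se_log <- sqrt(diag(object$vcov_log))
  est <- object$coefficients
  tab <- data.frame(estimate = est,
                    se = est * se_log,  # delta method from log scale
                    rse_pct = 100 * se_log,
                    lower95 = est * exp(-1.96 * se_log),
                    upper95 = est * exp(1.96 * se_log))
  out <- list(table = tab, neg2ll = object$neg2ll,
              convergence = object$convergence,
              n_subjects = object$n_subjects, n_obs = object$n_obs,
              fallback_vcov = isTRUE(attr(object$vcov_log, "fallback")))
  class(out) <- "summary.hc_fit"
  out
}

#' @export
print.summary.hc_fit <- function(x, ...) {
  cat(sprintf("Population PK fit: %d subjects, %d observations, -2LL = %.3f\n",
              x$n_subjects, x$n_obs, x$neg2ll))
  if (x$fallback_vcov)
    cat("  (asymptotic covariance unavailable; diagonal fallback shown)\n")
  print(round(x$table, 4))
  invisible(x)
}

#' @export
fitted.hc_fit <- function(object, ...) exp(object$logpred)

#' @export
residuals.hc_fit <- function(object, type = c("log", "response"), ...) {
  type <- match.arg(type)
  r <- object$prep$log_dv - object$logpred
  if (type == "log") r else exp(object$prep$log_dv) - exp(object$logpred)
}

#' @export
plot.hc_fit <- function(x, ...) {
  obs <- exp(x$prep$log_dv)
  prd <- exp(x$logpred)
  graphics::plot(prd, obs, log = "xy",
                 xlab = "Individual prediction (nmol/L)",
                 ylab = "Observation (nmol/L)",
                 main = "Observed vs individual predictions",
                 col = ifelse(x$prep$obs_dvid == 1, "firebrick",
                              "navy"), ...)
  graphics::abline(0, 1, untf = TRUE, lty = 2)
  graphics::legend("topleft", legend = c("plasma", "DBS"),
                   col = c("firebrick", "navy"), pch = 1, bty = "n")
  invisible(x)
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws new individual random effects and residual errors under the
#' fitted population parameters, keeping every subject's design (dose,
#' weight, age group, sampling times and observation types) fixed.
#'
#' @param object an [hc_fit()] object.
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of numeric vectors of simulated observations, each aligned
#'   with the rows of the prepared (BLQ-filtered) observation set.
#' @export
simulate.hc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_replicates(object$pop, object$prep, nsim, seed)
}

simulate_replicates <- function(pop, prep, nsim, seed = NULL) {
  with_seed(seed, {
    lapply(seq_len(nsim), function(r) {
      ind <- draw_individual(pop, prep$covariates)
      eta <- attr(ind, "eta")
      lp <- ll_logpred(pop, prep, eta)
      exp(lp + stats::rnorm(length(lp), 0, pop$sigma))
    })
  })
}
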