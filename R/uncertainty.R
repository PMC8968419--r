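# multivariate normal helpers (log-parameter scale)
rmvnorm_chol <- function(n, mean, chol_up) {
  k <- length(mean)
  z <- matrix(stats::rnorm(n * k), n, k)
  sweep(z %*% chol_up, 2, mean, `+`)
}

dmvnorm_log <- function(x, mean, chol_up) {
  k <- length(mean)
  dev <- sweep(x, 2, mean, `-`)
  z <- backsolve(chol_up, t(dev), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(chol_up))) - 0.5 * k * log(2 * pi)
}

#' Sampling importance resampling parameter uncertainty
#'
#' Draws parameter vectors from a multivariate-normal proposal on the log
#' scale centred at the estimates (covariance from the fit, optionally
#' inflated), computes each candidate's marginal -2 log-likelihood, and
#' importance-weights the candidates by the likelihood ratio over the
#' proposal density before resampling without replacement.  Confidence
#' intervals are the quantiles of the resampled parameters.  Multiple
#' stages can be run, each recentring the proposal on the moments of the
#' previous stage's resample.
#'
#' @param fit an [hc_fit()] object (with proposal covariance).
#' @param n_samples proposal draws per stage (scalar or vector, one per
#'   stage).
#' @param n_resamples resamples per stage (same length as `n_samples`).
#' @param seed optional seed.
#' @param inflate proposal SD inflation factor. Default 1.
#' @param control overrides of the likelihood controls; by default the
#'   inner eta search is run to a slightly looser tolerance than during
#'   estimation, which is negligible against the spread of the candidate
#'   -2 log-likelihoods but much faster over hundreds of draws.
#' @return object of class `"hc_sir"`: per-parameter median and 95% CI
#'   from the final stage, effective sample size, and the resample matrix.
#' @export
sir <- function(fit, n_samples = 1000, n_resamples = 500, seed = NULL,
                inflate = 1, control = list()) {
  sctl <- utils::modifyList(
    utils::modifyList(fit$control, list(inner_obj_tol = 0.01,
                                        inner_maxit = 8L)),
    control)
  stopifnot(inherits(fit, "hc_fit"),
            length(n_samples) == length(n_resamples),
            all(n_resamples <= n_samples))
  free <- fit$free
  k <- length(free)
  with_seed(seed, {
    centre <- fit$log_est
    Sig <- fit$vcov_log * inflate^2
    ess <- NA_real_
    resampled <- NULL
    for (stage in seq_along(n_samples)) {
      m <- n_samples[stage]
      if (all(Sig == 0)) {  # degenerate proposal collapses to the point
        resampled <- matrix(rep(centre, each = n_resamples[stage]),
                            ncol = k, dimnames = list(NULL, free))
        ess <- m
        next
      }
      ch <- chol(Sig)
      draws <- rmvnorm_chol(m, centre, ch)
      colnames(draws) <- free
      n2 <- numeric(m)
      for (j in seq_len(m)) {
        pop_j <- set_params(fit$init,
                            stats::setNames(exp(draws[j, ]), free))
        n2[j] <- tryCatch(
          as.numeric(neg2ll(pop_j, fit$prep, control = sctl,
                            eta_init = fit$eta)),
          error = function(e) Inf)
      }
      lw <- -0.5 * (n2 - min(n2[is.finite(n2)])) -
        dmvnorm_log(draws, centre, ch)
      lw[!is.finite(lw)] <- -Inf
      w <- exp(lw - max(lw))
      w <- w / sum(w)
      ess <- 1 / sum(w^2)
      if (ess < 0.05 * m)
        warning(sprintf("degenerate importance weights: ESS %.1f of %d",
                        ess, m))
      idx <- sample.int(m, n_resamples[stage], replace = FALSE, prob = w)
      resampled <- draws[idx, , drop = FALSE]
      centre <- colMeans(resampled)
      if (nrow(resampled) > k + 1)
        Sig <- stats::cov(resampled)
    }
    q <- apply(exp(resampled), 2, stats::quantile,
               probs = c(0.025, 0.5, 0.975))
    tab <- data.frame(estimate = fit$coefficients,
                      median = q[2, ], lower95 = q[1, ],
                      upper95 = q[3, ], row.names = free)
    structure(list(table = tab, ess = ess, resample = exp(resampled),
                   n_samples = n_samples, n_resamples = n_resamples),
              class = "hc_sir")
  })
}

#' @export
print.hc_sir <- function(x, ...) {
  cat(sprintf("SIR uncertainty (%s samples / %s resamples; final ESS %.0f)\n",
              paste(x$n_samples, collapse = "+"),
              paste(x$n_resamples, collapse = "+"), x$ess))
  print(round(x$table, 4))
  invisible(x)
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets under the population model on the
#' observed design, and compares the observed 5th/50th/95th concentration
#' percentiles per time bin with the corresponding simulation-based
#' confidence bands, stratified by observation type and age class.
#' Simulated values below the record's LLOQ are discarded, mirroring the
#' handling of the observed data.
#'
#' @param ds study dataset.
#' @param pop [population_params()] or an [hc_fit()] object.
#' @param n_sim number of replicate datasets. Default 1000.
#' @param seed optional seed.
#' @param probs percentiles summarised per bin. Default 5/50/95.
#' @param ci confidence level of the simulation bands. Default 0.95.
#' @return object of class `"hc_vpc"`: data.frame with one row per
#'   stratum/bin/percentile (`observed`, `lo`, `mid`, `hi`) plus counts.
#' @export
vpc <- function(ds, pop, n_sim = 1000, seed = NULL,
                probs = c(0.05, 0.5, 0.95), ci = 0.95) {
  if (inherits(pop, "hc_fit")) pop <- pop$pop
  prep <- ll_prepare(ds)
  sims <- simulate_replicates(pop, prep, n_sim, seed)
  lloq <- ifelse(prep$obs_dvid == 1, 14.1, 1.8)
  strat <- paste(ifelse(prep$obs_dvid == 1, "plasma", "DBS"),
                 prep$covariates$age_group[prep$obs_subj], sep = "|")
  bin <- prep$times[prep$obs_tidx]
  key <- factor(paste(strat, bin, sep = "|"))
  obs_dv <- exp(prep$log_dv)
  out <- list()
  for (lev in levels(key)) {
    sel <- key == lev
    n_in_bin <- sum(sel)
    if (n_in_bin == 0L) next
    op <- stats::quantile(obs_dv[sel], probs, names = FALSE)
    simq <- vapply(sims, function(s) {
      v <- s[sel]
      v <- v[v >= lloq[sel]]
      if (length(v) == 0L) return(rep(NA_real_, length(probs)))
      stats::quantile(v, probs, names = FALSE)
    }, numeric(length(probs)))
    simq <- matrix(simq, nrow = length(probs))
    a <- (1 - ci) / 2
    band <- apply(simq, 1, stats::quantile, probs = c(a, 0.5, 1 - a),
                  na.rm = TRUE)
    parts <- strsplit(lev, "|", fixed = TRUE)[[1]]
    out[[lev]] <- data.frame(
      type = parts[1], age_group = parts[2],
      time = as.numeric(parts[3]), percentile = 100 * probs,
      n = n_in_bin, observed = op,
      lo = band[1, ], mid = band[2, ], hi = band[3, ])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  empty <- setdiff(levels(key), names(out))
  if (length(empty))
    warning("dropped empty bins: ", paste(empty, collapse = ", "))
  structure(list(table = res, n_sim = n_sim, probs = probs, ci = ci),
            class = "hc_vpc")
}

#' @export
print.hc_vpc <- function(x, ...) {
  cat(sprintf("VPC: %d simulated replicates, %d stratum/bin/percentile rows\n",
              x$n_sim, nrow(x$table)))
  cov50 <- with(subset(x$table, x$table$percentile == 50),
                mean(observed >= lo & observed <= hi))
  cat(sprintf("  observed median inside its %.0f%% band in %.0f%% of bins\n",
              100 * x$ci, 100 * cov50))
  print(utils::head(x$table, 12))
  invisible(x)
}

#' @export
plot.hc_vpc <- function(x, type = "DBS", age_group = NULL, ...) {
  tb <- x$table[x$table$type == type, ]
  if (!is.null(age_group)) tb <- tb[tb$age_group == age_group, ]
  if (nrow(tb) == 0L) stop("no VPC rows for this stratum")
  med <- tb[tb$percentile == 50, ]
  graphics::plot(med$time, med$observed, pch = 16,
                 xlab = "Time (h)", ylab = "Concentration (nmol/L)",
                 main = sprintf("VPC (%s)", type),
                 ylim = range(tb$lo, tb$hi, tb$observed, na.rm = TRUE),
                 ...)
  for (p in unique(tb$percentile)) {
    sub <- tb[tb$percentile == p, ]
    o <- order(sub$time)
    graphics::polygon(c(sub$time[o], rev(sub$time[o])),
                      c(sub$lo[o], rev(sub$hi[o])),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(sub$time[o], sub$observed[o], lty = 2)
  }
  graphics::points(med$time, med$observed, pch = 16)
  invisible(x)
}
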