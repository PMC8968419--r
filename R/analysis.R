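#' Binding-species fraction curves
#'
#' Species fractions of total whole-blood cortisol over a concentration
#' grid from the DBS assay LLOQ (1.8 nmol/L) up to the age group's maximum
#' simulated whole-blood concentration (180 nmol/L children/infants,
#' 820 nmol/L neonates), for the typical geometry of the group.  The CBG
#' fraction declines monotonically with concentration as binding
#' saturates; the unbound, albumin and RBC fractions rise.
#'
#' @param group `"children_infants"` or `"neonate"`.
#' @param conc_grid optional grid of whole-blood concentrations, nmol/L;
#'   must lie within `[1.8, Cmax]` for the group.  Default: 200
#'   log-spaced points spanning that range.
#' @param params [binding_params()].
#' @param n grid size when `conc_grid` is NULL.
#' @return data.frame with columns `C_blood`, `Cu`, `f_u`, `f_Alb`,
#'   `f_CBG`, `f_RBC`.
#' @export
fraction_curves <- function(group = c("children_infants", "neonate"),
                            conc_grid = NULL,
                            params = binding_params(), n = 200) {
  group <- match.arg(group)
  cmax <- c(children_infants = 180, neonate = 820)[[group]]
  if (is.null(conc_grid))
    conc_grid <- exp(seq(log(1.8), log(cmax), length.out = n))
  if (any(conc_grid < 1.8 - 1e-9) || any(conc_grid > cmax + 1e-9))
    stop(sprintf("grid must lie within [1.8, %g] nmol/L for %s",
                 cmax, group))
  species_fractions(conc_grid, params, typical_geometry(group))
}

#' Plasma/DBS concentration ratio analysis
#'
#' Pairs plasma and DBS observations taken from the same subject at the
#' same time (both above their LLOQ), computes the plasma/DBS ratio, and
#' summarises it in the two whole-blood concentration ranges in which the
#' ratio regime differs: 0-200 and 200-800 nmol/L DBS.  A Wilcoxon
#' rank-sum test compares the 0-100 and 100-200 nmol/L sub-ranges, where
#' no concentration dependence is expected below CBG saturation.
#'
#' @param ds study dataset with paired plasma (`DVID` 1) and DBS
#'   (`DVID` 2) observations.
#' @param alpha significance level for the sub-range comparison.
#' @return object of class `"ratio_analysis"`: `pairs` (one row per
#'   plasma/DBS pair), `by_bin`, `by_group` summaries and `subbin_test`.
#' @export
ratio_analysis <- function(ds, alpha = 0.05) {
  obs <- ds[ds$EVID == 0 & ds$MDV == 0 & ds$BLQ == 0 & !is.na(ds$DV), ]
  pla <- obs[obs$DVID == 1, c("ID", "TIME", "DV", "AGEGRP")]
  dbs <- obs[obs$DVID == 2, c("ID", "TIME", "DV")]
  m <- merge(pla, dbs, by = c("ID", "TIME"),
             suffixes = c("_pla", "_dbs"))
  if (nrow(m) == 0L) {
    warning("no paired above-LLOQ plasma/DBS observations")
    return(structure(list(pairs = m, by_bin = NULL, by_group = NULL,
                          subbin_test = NULL), class = "ratio_analysis"))
  }
  m$ratio <- m$DV_pla / m$DV_dbs
  m$bin <- cut(m$DV_dbs, c(0, 200, 800, Inf),
               labels = c("0-200", "200-800", ">800"), right = TRUE)
  summarise <- function(x) {
    c(n = length(x), median = stats::median(x), min = min(x),
      max = max(x))
  }
  by_bin <- do.call(rbind, lapply(split(m$ratio, m$bin, drop = TRUE),
                                  summarise))
  by_group <- do.call(rbind,
                      lapply(split(m$ratio,
                                   list(m$AGEGRP, m$bin), drop = TRUE),
                             summarise))
  lo <- m$ratio[m$DV_dbs <= 100]
  hi <- m$ratio[m$DV_dbs > 100 & m$DV_dbs <= 200]
  subbin <- NULL
  if (length(lo) > 0 && length(hi) > 0) {
    wt <- stats::wilcox.test(lo, hi, exact = FALSE)
    subbin <- list(p_value = wt$p.value, alpha = alpha,
                   significant = wt$p.value < alpha,
                   n_low = length(lo), n_high = length(hi))
  }
  structure(list(pairs = m, by_bin = by_bin, by_group = by_group,
                 subbin_test = subbin),
            class = "ratio_analysis")
}

#' @export
print.ratio_analysis <- function(x, ...) {
  cat("Plasma/DBS concentration ratio analysis\n")
  if (is.null(x$by_bin)) {
    cat("  (no pairs)\n")
    return(invisible(x))
  }
  print(round(x$by_bin, 3))
  if (!is.null(x$subbin_test))
    cat(sprintf("  0-100 vs 100-200 nmol/L: Wilcoxon p = %.3f (%ssignificant at %.2g)\n",
                x$subbin_test$p_value,
                if (x$subbin_test$significant) "" else "not ",
                x$subbin_test$alpha))
  invisible(x)
}

#' Boxplot of plasma/DBS ratios by concentration range
#'
#' @param x a [ratio_analysis()] result.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.ratio_analysis <- function(x, ...) {
  if (nrow(x$pairs) == 0L) stop("nothing to plot")
  graphics::boxplot(ratio ~ bin, data = x$pairs,
                    xlab = "DBS concentration range (nmol/L)",
                    ylab = "Plasma/DBS concentration ratio", ...)
  invisible(x)
}

#' Deterministic typical-individual dose simulation
#'
#' Simulates a single oral dose in the typical individual of a pediatric
#' age group (13.5 kg children/infants, 3.6 kg neonates) with zero
#' interindividual variability and zero baselines, over 6 h, and reports
#' the whole-blood concentration maximum together with the full species
#' trajectory.
#'
#' @param dose_mg dose, mg.
#' @param group `"children_infants"` or `"neonate"`.
#' @param pop [population_params()] supplying typical values.
#' @param times output grid, h.
#' @return list: `Cmax_DBS`, `t_Cmax`, `Cmax_pla` and `profile` (the
#'   [simulate_profile()] data.frame extended with species amounts).
#' @export
typical_dose_simulation <- function(dose_mg,
                                    group = c("children_infants",
                                              "neonate"),
                                    pop = population_params(),
                                    times = seq(0, 6, by = 0.01)) {
  group <- match.arg(group)
  g <- typical_geometry(group, V_c_ref = pop$structural$V_c)
  p <- allometric_scale(pop$structural, g$weight)
  prof <- simulate_profile(dose_events(0, dose_mg), p, pop$binding, g,
                           times)
  sp <- partition_from_unbound(prof$Cu, pop$binding, g)
  prof$A_u <- sp$A_u
  prof$A_CBG <- sp$A_CBG
  prof$A_Alb <- sp$A_Alb
  cm <- attr(prof, "Cmax")
  list(Cmax_DBS = unname(cm["C_DBS"]), t_Cmax = unname(cm["t_Cmax_DBS"]),
       Cmax_pla = unname(cm["C_pla"]), profile = prof)
}

#' Stacked-area chart of binding-species fractions
#'
#' @param group age group passed to [fraction_curves()].
#' @param params [binding_params()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_fraction_curves <- function(group = "children_infants",
                                 params = binding_params(), ...) {
  fc <- fraction_curves(group, params = params)
  cum <- cbind(fc$f_u, fc$f_u + fc$f_Alb, fc$f_u + fc$f_Alb + fc$f_RBC,
               fc$f_u + fc$f_Alb + fc$f_RBC + fc$f_CBG)
  cols <- c("#cfe8f3", "#8fc4e3", "#4f94c4", "#1b5e93")
  graphics::plot(fc$C_blood, cum[, 4], type = "n", log = "x",
                 ylim = c(0, 1), xlab = "Whole-blood cortisol (nmol/L)",
                 ylab = "Fraction of total", main = group, ...)
  base <- rep(0, nrow(fc))
  for (j in 1:4) {
    graphics::polygon(c(fc$C_blood, rev(fc$C_blood)),
                      c(cum[, j], rev(base)), col = cols[j], border = NA)
    base <- cum[, j]
  }
  graphics::legend("topright",
                   legend = c("unbound", "albumin", "RBC", "CBG"),
                   fill = cols, bty = "n", bg = "white")
  invisible(fc)
}
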