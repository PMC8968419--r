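#' Read a study dataset
#'
#' Reads a NONMEM-like CSV dataset (comma-separated, UTF-8, '.' decimal)
#' with the required columns `ID`, `TIME` (h), `EVID`, `AMT` (nmol, or mg
#' with `amt_unit = "mg"`), `DV` (nmol/L), `DVID` (1 plasma, 2 DBS),
#' `MDV`, `WT` (kg), `AGEGRP`, `LLOQ` (nmol/L), `BLQ`.
#'
#' @param path CSV path.
#' @param amt_unit unit of the `AMT` column; `"mg"` converts doses via
#'   [dose_to_nmol()] on ingestion.
#' @return validated data.frame.
#' @export
read_dataset <- function(path, amt_unit = c("nmol", "mg")) {
  amt_unit <- match.arg(amt_unit)
  ds <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("ID", "TIME", "EVID", "AMT", "DV", "DVID", "MDV", "WT",
           "AGEGRP", "LLOQ", "BLQ")
  miss <- setdiff(req, names(ds))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "))
  if (any(stats::na.omit(ds$DV) < 0))
    stop("negative DV values found")
  bad <- vapply(split(ds$TIME, ds$ID), is.unsorted, logical(1))
  if (any(bad))
    stop("non-monotone times within subject(s): ",
         paste(names(bad)[bad], collapse = ", "))
  if (amt_unit == "mg") ds$AMT <- dose_to_nmol(ds$AMT)
  ds
}

#' Write a study dataset
#'
#' Full-precision CSV output so that `write_dataset()` followed by
#' [read_dataset()] is the identity on values.
#'
#' @param ds dataset data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  out <- ds
  for (cn in names(out)) {
    if (is.double(out[[cn]])) {
      v <- sprintf("%.17g", out[[cn]])  # shortest exact decimal round-trip
      v[is.na(out[[cn]])] <- "NA"
      out[[cn]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Validated configuration for pipeline runs (used by the command-line
#' wrapper).  Unknown keys are rejected; the defaults reproduce the
#' model's published parameterisation.
#'
#' @param seed integer RNG seed.
#' @param ... overrides among `n_sim` (VPC replicates), `sir_samples`,
#'   `sir_resamples`, `free` (free parameter names for fitting), `rtol`,
#'   `atol` (solver tolerances), `dose_mg`, `group`, `maxit`.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(seed = as.integer(seed), n_sim = 1000L,
              sir_samples = 1000L, sir_resamples = 500L,
              free = c("CL", "V_c", "Q", "V_p", "Vmax", "Vd_ch",
                       "Vd_neo", "BASE_adult", "omega_CL", "sigma"),
              rtol = 1e-6, atol = 1e-8, dose_mg = 7,
              group = "children_infants", maxit = 350L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "run_config")
}

#' Write a run manifest
#'
#' Records seed, configuration and session versions next to a run's
#' outputs, for reproducibility.
#'
#' @param cfg [run_config()].
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cfg, path) {
  man <- list(seed = cfg$seed, config = unclass(cfg),
              package_version = as.character(utils::packageVersion("cortdbs")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
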