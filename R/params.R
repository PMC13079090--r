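#' Load the forcing parameter set
#'
#' Reads the versioned YAML parameter file holding every physical coefficient
#' used by the forcing pathways: simplified radiative-expression coefficients
#' for CO2, CH4 and N2O, the multi-exponential CO2 impulse response, the
#' SSP2-4.5 background concentration table, biomass-burning emission factors
#' with standard deviations, global warming potentials, aerosol ratios, and the
#' permafrost release-curve and dALT tables. The shipped defaults are
#' literature-plausible placeholders (see the file header); supply your own
#' file to override.
#'
#' @param file path to a YAML parameter file; default is the file shipped with
#'   the package.
#' @return a validated nested list of parameters.
#' @export
#' @examples
#' p <- forcingParams()
#' p$gases$ch4$lifetime_years
forcingParams <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "forcing_params.yaml", package = "borealForcing")
  }
  if (!nzchar(file) || !file.exists(file)) {
    stop("parameter file not found: ", file)
  }
  p <- yaml::read_yaml(file)
  validateForcingParams(p)
  p
}

validateForcingParams <- function(p) {
  need <- c("constants", "gases", "co2_impulse_response", "background",
            "emission_factors", "gwp", "aerosol", "permafrost", "horizon_years")
  missing <- setdiff(need, names(p))
  if (length(missing)) {
    stop("parameter file is missing sections: ", paste(missing, collapse = ", "))
  }
  irf <- p$co2_impulse_response
  tot <- irf$a0 + sum(unlist(irf$a))
  if (abs(tot - 1) > 1e-6) {
    stop("impulse-response coefficients must sum to 1 at t = 0 (got ", tot, ")")
  }
  if (irf$a0 < 0 || irf$a0 > 1) stop("impulse-response asymptote a0 must lie in [0, 1]")
  if (length(irf$a) != length(irf$tau_years)) {
    stop("impulse response needs one timescale per coefficient")
  }
  stopifnot(p$gases$ch4$lifetime_years > 0)
  bg <- p$background
  if (length(bg$years) != length(bg$co2_ppm) ||
      length(bg$years) != length(bg$ch4_ppb) ||
      length(bg$years) != length(bg$n2o_ppb)) {
    stop("background table columns must have equal length")
  }
  ef <- p$emission_factors$species
  vals <- vapply(ef, function(s) c(s$ef, s$sd), numeric(2))
  if (any(vals < 0)) stop("emission factors and their sds must be non-negative")
  pf <- p$permafrost
  for (cls in names(pf$release_curves)) {
    fr <- unlist(pf$release_curves[[cls]])
    if (any(fr < 0)) stop("release fractions must be non-negative")
  }
  if (pf$ch4_c_fraction < 0 || pf$ch4_c_fraction > 1) {
    stop("ch4_c_fraction must be a fraction")
  }
  breaks <- unlist(pf$soc_interval_breaks_cm)
  if (is.unsorted(breaks, strictly = TRUE)) stop("SOC interval breaks must be increasing")
  invisible(TRUE)
}

#' Background mixing ratio of a well-mixed gas under the configured scenario
#'
#' Linear interpolation between the tabulated anchor years, held constant
#' outside the table.
#'
#' @param gas one of "co2", "ch4", "n2o".
#' @param year calendar year (vectorised).
#' @param params parameter list from [forcingParams()].
#' @return mixing ratio in ppm (CO2) or ppb (CH4, N2O).
#' @export
backgroundConcentration <- function(gas, year, params = forcingParams()) {
  gas <- match.arg(gas, c("co2", "ch4", "n2o"))
  bg <- params$background
  col <- switch(gas, co2 = "co2_ppm", ch4 = "ch4_ppb", n2o = "n2o_ppb")
  approx(unlist(bg$years), unlist(bg[[col]]), xout = year, rule = 2)$y
}

#' Write a parameter list back to YAML
#'
#' @param params parameter list.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeForcingParams <- function(params, file) {
  validateForcingParams(params)
  yaml::write_yaml(params, file)
  invisible(file)
}

# interval names like "0-30" from the configured breaks
socIntervalNames <- function(params) {
  b <- unlist(params$permafrost$soc_interval_breaks_cm)
  paste0(b[-length(b)], "-", b[-1])
}
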