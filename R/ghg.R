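# Greenhouse-gas, precursor and aerosol forcing pathways.
#
# Conventions: the fire pulse is placed at the middle of the burn year and
# annual values are evaluated at post-fire mid-years t - 0.5 for t = 1..70.
# Global-mean forcing of a pixel's emissions is rescaled to W m-2 of burned
# area by the factor (Earth surface area / pixel burned area).

#' Species emissions from combusted carbon
#'
#' Converts per-pixel combusted carbon into per-species emitted mass using
#' emission factors (g species per kg dry matter) and the fuel carbon fraction:
#' mass_s = (carbon / carbon_fraction) * EF_s / 1000, in kg per m2 burned.
#'
#' @param carbon combusted carbon, kg C per m2 burned (vectorised over pixels).
#' @param params parameter list from [forcingParams()].
#' @param ef optional override of `params$emission_factors` (same structure),
#'   e.g. a perturbed draw from [drawParameterVersion()].
#' @return matrix `length(carbon)` x species, kg species per m2 burned.
#' @export
#' @examples
#' emissionsFromCombustion(3.13, forcingParams())
emissionsFromCombustion <- function(carbon, params = forcingParams(), ef = NULL) {
  if (any(carbon < 0)) stop("combusted carbon must be non-negative")
  if (is.null(ef)) ef <- params$emission_factors
  species <- names(ef$species)
  fuel <- carbon / ef$carbon_fraction          # kg dry matter per m2
  out <- vapply(species, function(s) fuel * ef$species[[s]]$ef / 1000,
                numeric(length(carbon)))
  out <- matrix(out, nrow = length(carbon), dimnames = list(NULL, species))
  out
}

#' Airborne fraction of a CO2 pulse
#'
#' Multi-exponential impulse response a0 + sum_i a_i exp(-t / tau_i); equals 1
#' at t = 0 and decays towards the asymptote a0.
#'
#' @param t years since the pulse (vectorised, >= 0).
#' @param irf impulse-response list with elements `a0`, `a`, `tau_years`;
#'   default from [forcingParams()].
#' @return airborne fraction in (0, 1].
#' @export
co2AirborneFraction <- function(t, irf = forcingParams()$co2_impulse_response) {
  if (any(t < 0)) stop("t must be non-negative")
  a <- unlist(irf$a); tau <- unlist(irf$tau_years)
  out <- rep(irf$a0, length(t))
  for (i in seq_along(a)) out <- out + a[i] * exp(-t / tau[i])
  out
}

#' N2O lifetime with burden feedback
#'
#' The atmospheric lifetime of N2O shrinks as its background burden grows:
#' tau(N) = tau_ref * (N / N_ref)^s with the sensitivity exponent s < 0 held in
#' config. Backgrounds outside the validity range of the simplified expression
#' are clamped with a warning.
#'
#' @param background_n2o background N2O, ppb (vectorised).
#' @param params parameter list.
#' @return lifetime in years.
#' @export
n2oLifetime <- function(background_n2o, params = forcingParams()) {
  lt <- params$gases$n2o$lifetime
  rng <- unlist(params$gases$n2o$valid_range)
  if (any(background_n2o < rng[1] | background_n2o > rng[2])) {
    warning("background N2O outside validity range [", rng[1], ", ", rng[2],
            "] ppb; clamped")
    background_n2o <- pmin(pmax(background_n2o, rng[1]), rng[2])
  }
  lt$tau_ref_years * (background_n2o / lt$n_ref_ppb)^lt$feedback_exponent
}

# mixing-ratio units per kg of emitted gas (ppm for CO2, ppb otherwise)
mixingRatioPerKg <- function(gas, params) {
  mm <- params$constants$molar_mass[[gas]]
  per_mol <- 1 / params$constants$atmosphere_moles
  scale <- if (gas == "co2") 1e6 else 1e9
  per_mol * scale / mm
}

# airborne fraction of an N2O pulse emitted at `emission_year`, evaluated a
# vector of ages later; integrates 1/tau along the evolving background
n2oAirborneFraction <- function(t, params, emission_year) {
  vapply(t, function(ti) {
    if (ti <= 0) return(1)
    step <- 0.25
    s <- seq(0, ti, by = step)
    tau <- n2oLifetime(backgroundConcentration("n2o", emission_year + 0.5 + s, params),
                       params)
    inv <- 1 / tau
    integral <- sum((inv[-1] + inv[-length(inv)]) / 2) * step +
      if ((ti - s[length(s)]) > 0) (ti - s[length(s)]) * inv[length(inv)] else 0
    exp(-integral)
  }, numeric(1))
}

#' Mixing-ratio perturbation from an emitted mass
#'
#' Converts an emitted mass to a global mixing-ratio perturbation via
#' atmospheric molar bookkeeping and decays it: CO2 through the impulse
#' response, CH4 as exp(-t / 12.4), and N2O with the burden-dependent lifetime.
#'
#' @param mass emitted mass of the gas, kg (whole-pixel total, not per m2).
#' @param gas one of "co2", "ch4", "n2o".
#' @param t years since emission (vectorised, >= 0).
#' @param params parameter list.
#' @param emission_year calendar year of the pulse (sets the evolving N2O
#'   background for its lifetime feedback).
#' @return perturbation in ppm (CO2) or ppb (CH4, N2O).
#' @export
concentrationPerturbation <- function(mass, gas, t, params = forcingParams(),
                                      emission_year = 2010) {
  gas <- match.arg(gas, c("co2", "ch4", "n2o"))
  if (any(mass < 0)) stop("mass must be non-negative")
  if (any(t < 0)) stop("t must be non-negative")
  x0 <- mass * mixingRatioPerKg(gas, params)
  decay <- switch(gas,
    co2 = co2AirborneFraction(t, params$co2_impulse_response),
    ch4 = exp(-t / params$gases$ch4$lifetime_years),
    n2o = n2oAirborneFraction(t, params, emission_year))
  x0 * decay
}

#' Simplified radiative forcing expression for a well-mixed gas
#'
#' Global-mean radiative forcing of a perturbed concentration `conc` relative
#' to the unperturbed background `conc0`, using the simplified expressions with
#' band-overlap terms: a logarithmic form for CO2 and square-root forms for CH4
#' and N2O. Overlap terms use the background concentrations of the other gases
#' supplied in `bars`. Concentrations outside the validity range are computed
#' with a warning.
#'
#' @param gas one of "co2", "ch4", "n2o".
#' @param conc perturbed concentration (ppm for CO2, ppb otherwise; vectorised).
#' @param conc0 background concentration, same units.
#' @param params parameter list.
#' @param bars list with `co2`, `ch4`, `n2o` background values entering the
#'   overlap terms; defaults to the configured scenario at `year`.
#' @param year calendar year used to look up `bars` when not supplied.
#' @param warn emit validity-range warnings (default TRUE).
#' @return forcing in W m-2 (global mean); exactly 0 where `conc == conc0`.
#' @export
simplifiedRF <- function(gas, conc, conc0, params = forcingParams(),
                         bars = NULL, year = 2010, warn = TRUE) {
  gas <- match.arg(gas, c("co2", "ch4", "n2o"))
  if (is.null(bars)) {
    bars <- list(co2 = backgroundConcentration("co2", year, params),
                 ch4 = backgroundConcentration("ch4", year, params),
                 n2o = backgroundConcentration("n2o", year, params))
  }
  rng <- unlist(params$gases[[gas]]$valid_range)
  if (warn && any(conc < rng[1] | conc > rng[2] | conc0 < rng[1] | conc0 > rng[2])) {
    warning(gas, " concentration outside validity range [", rng[1], ", ",
            rng[2], "]; expression evaluated anyway")
  }
  simplifiedRFDelta(gas, conc - conc0, conc0, params, bars)
}

# the simplified expressions written in terms of the perturbation dx = C - C0;
# sqrt(C) - sqrt(C0) is evaluated as dx / (sqrt(C) + sqrt(C0)) and ln(C/C0) as
# log1p(dx/C0), both algebraically identical but immune to cancellation for the
# tiny perturbations a single pixel's emissions produce
simplifiedRFDelta <- function(gas, dx, conc0, params, bars) {
  e <- params$gases[[gas]]$expr
  dsqrt <- dx / (sqrt(conc0 + dx) + sqrt(conc0))
  switch(gas,
    co2 = {
      (e$a1 * dx^2 + e$b1 * abs(dx) + e$c1 * bars$n2o + e$ln_coeff) *
        log1p(dx / conc0)
    },
    ch4 = {
      mbar <- conc0 + dx / 2
      (e$a3 * mbar + e$b3 * bars$n2o + e$coeff) * dsqrt
    },
    n2o = {
      nbar <- conc0 + dx / 2
      (e$a2 * bars$co2 + e$b2 * nbar + e$c2 * bars$ch4 + e$coeff) * dsqrt
    })
}

# post-fire evaluation grid: mid-year ages and calendar years
postFireGrid <- function(burn_year, horizon = 70) {
  t <- seq_len(horizon)
  list(age = t - 0.5, year = burn_year + t - 0.5, t = t)
}

#' Global-mean forcing series from annual emission pulses of one gas
#'
#' Each element of `release` is the mass (kg) emitted during post-fire year
#' 1..70 (mid-year pulse convention). Pulses decay with the gas's airborne
#' fraction; the summed concentration perturbation is pushed through the
#' simplified expression against the evolving background. For CO2 a
#' `baseline_release` (e.g. the fire's own direct emissions) may shift the
#' reference background so that later uptake is evaluated against the
#' fire-perturbed atmosphere.
#'
#' @param release numeric vector (length <= horizon) of emitted mass per
#'   post-fire year, kg; negative values represent uptake.
#' @param gas one of "co2", "ch4", "n2o".
#' @param params parameter list.
#' @param burn_year calendar year of the fire.
#' @param baseline_release optional vector like `release` added to the
#'   background on both sides of the expression (CO2 bookkeeping for the
#'   vegetation-recovery counterfactual).
#' @param horizon series length in years (default 70).
#' @return numeric length-`horizon` global-mean forcing series, W m-2.
#' @export
pulseForcingSeries <- function(release, gas, params = forcingParams(),
                               burn_year = 2010, baseline_release = NULL,
                               horizon = params$horizon_years) {
  gas <- match.arg(gas, c("co2", "ch4", "n2o"))
  grid <- postFireGrid(burn_year, horizon)
  perturb <- function(rel) {
    rel <- c(rel, rep(0, horizon - length(rel)))
    out <- numeric(horizon)
    per_kg <- mixingRatioPerKg(gas, params)
    for (y in which(rel != 0)) {
      ages <- grid$age[grid$t >= y] - (y - 0.5)
      decay <- switch(gas,
        co2 = co2AirborneFraction(ages, params$co2_impulse_response),
        ch4 = exp(-ages / params$gases$ch4$lifetime_years),
        n2o = n2oAirborneFraction(ages, params, burn_year + y - 0.5))
      out[grid$t >= y] <- out[grid$t >= y] + rel[y] * per_kg * decay
    }
    out
  }
  dx <- perturb(release)
  base <- backgroundConcentration(gas, grid$year, params)
  if (!is.null(baseline_release)) base <- base + perturb(baseline_release)
  bars <- list(co2 = backgroundConcentration("co2", grid$year, params),
               ch4 = backgroundConcentration("ch4", grid$year, params),
               n2o = backgroundConcentration("n2o", grid$year, params))
  simplifiedRFDelta(gas, dx, base, params, bars = bars)
}

# CH4-pathway global forcing series of an equivalent CH4 mass pulse at year 1
ch4PathwaySeries <- function(mass_kg, params, burn_year, horizon = params$horizon_years) {
  sign(mass_kg) * pulseForcingSeries(c(abs(mass_kg), rep(0, horizon - 1)), "ch4",
                                     params, burn_year, horizon = horizon)
}

#' Rescale global-mean forcing to a per-burned-area basis
#'
#' @param series global-mean forcing series (vector or list of vectors), W m-2.
#' @param burned_area burned area of the pixel, m2.
#' @param params parameter list.
#' @return series in W m-2 of burned area.
#' @export
perBurnedArea <- function(series, burned_area, params = forcingParams()) {
  f <- params$constants$earth_surface_area_m2 / burned_area
  if (is.list(series)) lapply(series, function(s) s * f) else series * f
}

#' Ozone forcing from fire CO emissions
#'
#' CO-driven tropospheric ozone forcing, linear in the emitted CO mass: the CO
#' mass is converted to an equivalent CH4 mass by the GWP ratio at the
#' configured horizon and routed through the CH4 forcing pathway.
#'
#' @param co_mass emitted CO, kg per m2 burned.
#' @param params parameter list.
#' @param burn_year calendar year of the fire.
#' @param burned_area burned area of the pixel, m2.
#' @param gwp optional override of `params$gwp`.
#' @return length-70 forcing series, W m-2 of burned area.
#' @export
ozoneFromCO <- function(co_mass, params = forcingParams(), burn_year = 2010,
                        burned_area = params$constants$pixel_area_m2, gwp = NULL) {
  if (any(co_mass < 0)) stop("CO mass must be non-negative")
  if (is.null(gwp)) gwp <- params$gwp
  h <- params$ozone$horizon_years
  ratio <- gwpAt(gwp, "co", h) / gwpAt(gwp, "ch4", h)
  eq_mass <- co_mass * burned_area * ratio
  perBurnedArea(ch4PathwaySeries(eq_mass, params, burn_year), burned_area, params)
}

gwpAt <- function(gwp, species, horizon) {
  stopifnot(horizon %in% c(20, 100))
  gwp[[species]][[if (horizon == 20) "gwp20" else "gwp100"]]
}

#' Precursor forcing via GWP conversion onto the CH4 pathway
#'
#' The species mass is converted to a CH4-equivalent mass by the GWP ratio at
#' the requested horizon (mass * GWP_s / GWP_CH4) and pushed through the CH4
#' forcing pathway, preserving the GWP time-integral over the horizon. Negative
#' GWPs (e.g. NOx at 100 years) yield negative forcing.
#'
#' @param mass emitted species mass, kg per m2 burned.
#' @param species one of "nox", "co", "nmvoc".
#' @param params parameter list.
#' @param horizon GWP horizon, 20 or 100 years.
#' @param burn_year calendar year of the fire.
#' @param burned_area burned area of the pixel, m2.
#' @param gwp optional override of `params$gwp`.
#' @return length-70 forcing series, W m-2 of burned area.
#' @export
precursorForcingGWP <- function(mass, species, params = forcingParams(),
                                horizon = params$precursor$horizon_years,
                                burn_year = 2010,
                                burned_area = params$constants$pixel_area_m2,
                                gwp = NULL) {
  species <- match.arg(species, c("nox", "co", "nmvoc"))
  if (is.null(gwp)) gwp <- params$gwp
  ratio <- gwpAt(gwp, species, horizon) / gwpAt(gwp, "ch4", horizon)
  eq_mass <- mass * burned_area * ratio
  perBurnedArea(ch4PathwaySeries(eq_mass, params, burn_year), burned_area, params)
}

#' Aerosol forcing from organic and black carbon emissions
#'
#' Direct forcing converts each aerosol mass to a CH4-equivalent mass with the
#' GWP ratio at 20 years, time-integrates the resulting CH4-pathway forcing
#' over that horizon, and assigns the whole integral to post-fire year 1
#' (aerosols deposit within weeks of the fire); years 2-70 are exactly zero.
#' Indirect forcing is the direct forcing times the configured
#' indirect-to-direct ratio.
#'
#' @param oc_mass organic-carbon aerosol mass, kg per m2 burned.
#' @param bc_mass black-carbon aerosol mass, kg per m2 burned.
#' @param params parameter list.
#' @param burn_year calendar year of the fire.
#' @param burned_area burned area of the pixel, m2.
#' @param gwp optional override of `params$gwp`.
#' @param indirect_ratio optional override of the indirect:direct ratio.
#' @return list with length-70 series `direct`, `indirect`, `total`
#'   (W m-2 of burned area).
#' @export
aerosolForcing <- function(oc_mass, bc_mass, params = forcingParams(),
                           burn_year = 2010,
                           burned_area = params$constants$pixel_area_m2,
                           gwp = NULL, indirect_ratio = NULL) {
  if (any(c(oc_mass, bc_mass) < 0)) stop("aerosol masses must be non-negative")
  if (is.null(gwp)) gwp <- params$gwp
  if (is.null(indirect_ratio)) indirect_ratio <- params$aerosol$indirect_direct_ratio
  h <- params$aerosol$gwp_horizon_years
  horizon <- params$horizon_years
  year1 <- function(mass, species) {
    eq <- mass * burned_area * gwpAt(gwp, species, h) / gwpAt(gwp, "ch4", h)
    ser <- ch4PathwaySeries(eq, params, burn_year)
    sum(ser[seq_len(min(h, length(ser)))])   # annual sums approximate the integral
  }
  direct <- numeric(horizon)
  direct[1] <- year1(oc_mass, "oc") + year1(bc_mass, "bc")
  direct <- perBurnedArea(direct, burned_area, params)
  indirect <- direct * indirect_ratio
  list(direct = direct, indirect = indirect, total = direct + indirect)
}

#' Assemble per-component forcing series for one pixel's emissions
#'
#' Runs the full combustion-emission pathway for a single pixel: CO2, CH4 and
#' N2O through their concentration pathways, CO through the ozone pathway, NOx
#' and NMVOC through the precursor GWP pathway, and OC/BC through the aerosol
#' pathway; rescales everything to W m-2 of burned area and returns the
#' component sums used in reporting.
#'
#' @param carbon combusted carbon, kg C per m2 burned (scalar).
#' @param params parameter list.
#' @param burn_year calendar year of the fire.
#' @param burned_area burned area, m2.
#' @param ef,gwp optional overrides of the emission-factor and GWP tables.
#' @param indirect_ratio optional override of the aerosol indirect:direct ratio.
#' @return list of length-70 series: `co2`, `ch4`, `n2o`, `ozone`,
#'   `precursors`, `ghg_precursor` (their sum) and `aerosol` (direct +
#'   indirect), all W m-2 of burned area.
#' @export
#' @examples
#' f <- ghgAerosolForcing(3.13, forcingParams())
#' mean(f$ghg_precursor)
ghgAerosolForcing <- function(carbon, params = forcingParams(), burn_year = 2010,
                              burned_area = params$constants$pixel_area_m2,
                              ef = NULL, gwp = NULL, indirect_ratio = NULL) {
  stopifnot(length(carbon) == 1L)
  em <- emissionsFromCombustion(carbon, params, ef = ef)[1, ]
  horizon <- params$horizon_years
  one_gas <- function(gas) {
    rel <- c(em[[gas]] * burned_area, rep(0, horizon - 1))
    perBurnedArea(pulseForcingSeries(rel, gas, params, burn_year), burned_area, params)
  }
  co2 <- one_gas("co2"); ch4 <- one_gas("ch4"); n2o <- one_gas("n2o")
  ozone <- ozoneFromCO(em[["co"]], params, burn_year, burned_area, gwp = gwp)
  prec <- Reduce(`+`, lapply(params$precursor$species, function(s) {
    precursorForcingGWP(em[[s]], s, params, burn_year = burn_year,
                        burned_area = burned_area, gwp = gwp)
  }))
  aer <- aerosolForcing(em[["oc"]], em[["bc"]], params, burn_year, burned_area,
                        gwp = gwp, indirect_ratio = indirect_ratio)
  list(co2 = co2, ch4 = ch4, n2o = n2o, ozone = ozone, precursors = prec,
       ghg_precursor = co2 + ch4 + n2o + ozone + prec, aerosol = aer$total)
}

#' Rescale and sum per-gas global forcing trajectories for a pixel
#'
#' Takes named global-mean component trajectories (each length 70), rescales
#' them to W m-2 of burned area, and returns them together with the
#' greenhouse-gas + precursor sum and the aerosol sum reported separately.
#'
#' @param components named list of length-70 global-mean series; aerosol
#'   components must be named `aerosol_direct` / `aerosol_indirect` or
#'   `aerosol`.
#' @param burned_area burned area of the pixel, m2.
#' @param params parameter list.
#' @return list of rescaled components plus `ghg_precursor` and `aerosol` sums.
#' @export
integrateForcing <- function(components, burned_area, params = forcingParams()) {
  len <- vapply(components, length, integer(1))
  if (any(len != params$horizon_years)) {
    stop("all component trajectories must have length ", params$horizon_years)
  }
  scaled <- perBurnedArea(components, burned_area, params)
  is_aer <- grepl("^aerosol", names(scaled))
  ghg <- Reduce(`+`, scaled[!is_aer])
  aer <- if (any(is_aer)) Reduce(`+`, scaled[is_aer]) else numeric(params$horizon_years)
  c(scaled, list(ghg_precursor = ghg, aerosol = aer))
}
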