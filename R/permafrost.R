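# First-order post-fire permafrost emission model: active-layer thickening
# exposes depth-partitioned soil organic carbon, which decomposes along
# incubation-derived release curves modulated by a frost-free-day seasonality
# factor and a lab-to-field scaling factor, is split into CO2 and CH4, weighted
# by permafrost probability, and converted to radiative forcing.

#' Fraction and mass of SOC exposed by active-layer deepening
#'
#' Assuming carbon is uniformly distributed with depth within each interval,
#' the exposed fraction of an interval is the overlap of
#' `[pre_alt, post_alt]` with the interval divided by the interval thickness;
#' exposed carbon is that fraction times the interval stock. E.g. deepening
#' from 70 to 110 cm exposes 60 % of the 50-100 cm interval and 10 % of the
#' 100-200 cm interval.
#'
#' @param pre_alt pre-fire active layer thickness, cm (>= 0).
#' @param post_alt post-fire active layer thickness, cm (>= `pre_alt`; values
#'   beyond the deepest interval are clamped with a warning).
#' @param stocks named SOC stocks per interval (kg C m-2), names matching the
#'   configured intervals ("0-30", "30-50", ...); may be omitted to get
#'   fractions only.
#' @param params parameter list.
#' @return list with `fraction` (per interval), `carbon` (per interval, kg C
#'   m-2; NA if `stocks` missing) and `total_carbon`.
#' @export
#' @examples
#' exposedSOCFraction(70, 110)$fraction
exposedSOCFraction <- function(pre_alt, post_alt, stocks = NULL,
                               params = forcingParams()) {
  breaks <- unlist(params$permafrost$soc_interval_breaks_cm)
  max_depth <- breaks[length(breaks)]
  if (pre_alt < 0) stop("pre-fire ALT must be non-negative")
  if (post_alt < pre_alt) stop("post-fire ALT must not be shallower than pre-fire ALT")
  if (post_alt > max_depth) {
    warning("post-fire ALT exceeds ", max_depth, " cm; clamped")
    post_alt <- max_depth
  }
  lo <- breaks[-length(breaks)]; hi <- breaks[-1]
  overlap <- pmax(0, pmin(post_alt, hi) - pmax(pre_alt, lo))
  fraction <- overlap / (hi - lo)
  names(fraction) <- socIntervalNames(params)
  carbon <- if (is.null(stocks)) {
    rep(NA_real_, length(fraction))
  } else {
    fraction * stocks[names(fraction)]
  }
  names(carbon) <- names(fraction)
  list(fraction = fraction, carbon = carbon,
       total_carbon = if (is.null(stocks)) NA_real_ else sum(carbon))
}

#' Post-fire active layer thickness
#'
#' ALT(t) = pre-fire ALT x (1 + dALT(t)), capped at the deepest SOC interval
#' (300 cm). The fractional-change curve dALT(t) is piecewise linear between
#' the tabulated post-fire years.
#'
#' @param pre_alt pre-fire ALT, cm.
#' @param t years since fire (vectorised, within 0-70).
#' @param params parameter list.
#' @param dalt optional override list with `years` and `frac`.
#' @param alt_multiplier multiplies the fractional change (sensitivity
#'   scenarios).
#' @return ALT in cm.
#' @export
postFireALT <- function(pre_alt, t, params = forcingParams(), dalt = NULL,
                        alt_multiplier = 1) {
  if (is.null(dalt)) dalt <- params$permafrost$dalt
  frac <- approx(unlist(dalt$years), unlist(dalt$frac), xout = t, rule = 2)$y
  pmin(params$permafrost$max_depth_cm, pre_alt * (1 + alt_multiplier * frac))
}

# annual release fraction for release-clock year t (1-based), by soil class,
# extrapolated beyond the incubation record per the configured mode
releaseFraction <- function(t, soil_class, params) {
  curve <- unlist(params$permafrost$release_curves[[soil_class]])
  k <- length(curve)
  out <- numeric(length(t))
  inside <- t >= 1 & t <= k
  out[inside] <- curve[t[inside]]
  beyond <- t > k
  if (any(beyond)) {
    out[beyond] <- switch(params$permafrost$release_extrapolation,
      hold_last = curve[k],
      decay = curve[k] * exp(-params$permafrost$release_decay_rate * (t[beyond] - k)),
      stop("unknown release_extrapolation mode"))
  }
  out
}

#' Annual CO2 and CH4 emission from exposed permafrost carbon
#'
#' Released carbon in release-clock year `t` is
#' `exposed_c * annual_fraction(t, soil_class) * season / lab_to_field`;
#' a fixed fraction (15.89 %) of the released carbon is emitted as CH4-C and
#' the remainder as CO2-C, converted to species masses by molar ratios
#' (x 16/12 for CH4, x 44/12 for CO2).
#'
#' @param exposed_c exposed carbon, kg C m-2.
#' @param soil_class "mineral" or "organic".
#' @param t release-clock year (1 = year of exposure; vectorised).
#' @param season frost-free-day fraction for that year, in [0, 1].
#' @param params parameter list.
#' @param lab_to_field override of the lab-to-field factor (1 disables it).
#' @param emission_multiplier sensitivity-scenario multiplier on released
#'   carbon.
#' @return list with `released_c`, `co2_kg`, `ch4_kg` (per m2).
#' @export
#' @examples
#' annualEmission(1, "mineral", 1, season = 1, lab_to_field = 1)
annualEmission <- function(exposed_c, soil_class, t, season,
                           params = forcingParams(), lab_to_field = NULL,
                           emission_multiplier = 1) {
  if (any(exposed_c < 0)) stop("exposed carbon must be non-negative")
  soil_class <- match.arg(soil_class, c("mineral", "organic"))
  if (is.null(lab_to_field)) lab_to_field <- params$permafrost$lab_to_field_factor
  released <- exposed_c * releaseFraction(t, soil_class, params) * season /
    lab_to_field * emission_multiplier
  f_ch4 <- params$permafrost$ch4_c_fraction
  ch4_c <- f_ch4 * released
  list(released_c = released,
       co2_kg = (released - ch4_c) * 44 / 12,
       ch4_kg = ch4_c * 16 / 12)
}

#' Annual permafrost emission streams for one pixel
#'
#' Tracks active-layer deepening year by year: carbon newly exposed in
#' post-fire year y starts its own release clock, and all clocks contribute to
#' the emission of each later year, modulated by that year's seasonality and
#' the lab-to-field factor. Cumulative release per clock is capped at the
#' exposed carbon.
#'
#' @param soc named interval stocks, kg C m-2.
#' @param soil_class "mineral" or "organic".
#' @param pre_alt pre-fire ALT, cm.
#' @param frost_free length-70 frost-free-day fractions.
#' @param params parameter list.
#' @param dalt,alt_multiplier passed to [postFireALT()].
#' @param lab_to_field,emission_multiplier passed to [annualEmission()].
#' @return list with length-70 vectors `co2_kg`, `ch4_kg`, `released_c` (per
#'   m2) and scalars `exposed_c`, plus `newly_exposed` per year.
#' @export
permafrostEmissions <- function(soc, soil_class, pre_alt, frost_free,
                                params = forcingParams(), dalt = NULL,
                                alt_multiplier = 1, lab_to_field = NULL,
                                emission_multiplier = 1) {
  horizon <- params$horizon_years
  stopifnot(length(frost_free) == horizon)
  if (is.null(lab_to_field)) lab_to_field <- params$permafrost$lab_to_field_factor
  alt <- postFireALT(pre_alt, seq_len(horizon), params, dalt, alt_multiplier)
  exposed_cum <- vapply(alt, function(a) {
    exposedSOCFraction(pre_alt, max(a, pre_alt), soc, params)$total_carbon
  }, numeric(1))
  newly <- pmax(0, diff(c(0, exposed_cum)))   # kg C m-2 newly exposed per year
  released <- numeric(horizon)
  f_rel <- releaseFraction(seq_len(horizon), soil_class, params)
  for (y in which(newly > 0)) {
    idx <- y:horizon
    raw <- newly[y] * f_rel[idx - y + 1] * frost_free[idx] / lab_to_field *
      emission_multiplier
    capped <- diff(c(0, pmin(cumsum(raw), newly[y])))
    released[idx] <- released[idx] + capped
  }
  f_ch4 <- params$permafrost$ch4_c_fraction
  ch4_c <- f_ch4 * released
  list(co2_kg = (released - ch4_c) * 44 / 12, ch4_kg = ch4_c * 16 / 12,
       released_c = released, exposed_c = max(exposed_cum),
       newly_exposed = newly)
}

# 70x70 unit pulse-response matrix: row y = global forcing series of a
# reference-mass pulse of `gas` emitted in post-fire year y, per kg
unitPulseMatrix <- function(gas, params, burn_year, horizon = params$horizon_years) {
  ref <- 1e9   # kg; keeps intermediate forcing well scaled, still linear
  t(vapply(seq_len(horizon), function(y) {
    rel <- numeric(horizon); rel[y] <- ref
    pulseForcingSeries(rel, gas, params, burn_year, horizon = horizon) / ref
  }, numeric(horizon)))
}

#' Radiative forcing from fire-induced permafrost emissions
#'
#' Converts a pixel's annual CO2/CH4 permafrost emission streams - weighted by
#' the permafrost zonation index - into a 70-year forcing series through the
#' well-mixed-gas pathways, reported as the combined CO2 + CH4 impact in W m-2
#' of burned area.
#'
#' @param soc,soil_class,pre_alt,frost_free per-pixel soil and thaw state (see
#'   [permafrostEmissions()]).
#' @param zonation_index permafrost probability p in [0, 1].
#' @param params parameter list.
#' @param burn_year calendar year of the fire.
#' @param burned_area burned area, m2 (default: full pixel).
#' @param pixel_area pixel area, m2.
#' @param dalt,alt_multiplier,lab_to_field,emission_multiplier scenario knobs.
#' @param unit_matrices optional precomputed list
#'   `list(co2 = , ch4 = )` of [unitPulseMatrix()] results for this burn year
#'   (large-landscape speed-up).
#' @return length-70 forcing series, W m-2 of burned area.
#' @export
permafrostForcing <- function(soc, soil_class, pre_alt, frost_free,
                              zonation_index, params = forcingParams(),
                              burn_year = 2010,
                              burned_area = params$constants$pixel_area_m2,
                              pixel_area = params$constants$pixel_area_m2,
                              dalt = NULL, alt_multiplier = 1,
                              lab_to_field = NULL, emission_multiplier = 1,
                              unit_matrices = NULL) {
  stopifnot(zonation_index >= 0, zonation_index <= 1)
  horizon <- params$horizon_years
  if (zonation_index == 0) return(numeric(horizon))
  em <- permafrostEmissions(soc, soil_class, pre_alt, frost_free, params, dalt,
                            alt_multiplier, lab_to_field, emission_multiplier)
  co2_rel <- em$co2_kg * zonation_index * pixel_area
  ch4_rel <- em$ch4_kg * zonation_index * pixel_area
  if (is.null(unit_matrices)) {
    ser <- pulseForcingSeries(co2_rel, "co2", params, burn_year) +
      pulseForcingSeries(ch4_rel, "ch4", params, burn_year)
  } else {
    ser <- as.numeric(co2_rel %*% unit_matrices$co2 +
                        ch4_rel %*% unit_matrices$ch4)
  }
  perBurnedArea(ser, burned_area, params)
}

#' Permafrost forcing for every pixel of a synthetic landscape
#'
#' @param landscape a `"PermafrostLandscape"` from [genPermafrostLandscape()].
#' @param fires fire grid (supplies burn years); a single common burn year is
#'   used for the unit-response cache when `common_burn_year` is TRUE.
#' @param params parameter list.
#' @param common_burn_year use one representative burn year (the median) for
#'   the pulse-response cache; the approximation only shifts the slowly varying
#'   background (default TRUE).
#' @param ... scenario knobs forwarded to [permafrostForcing()].
#' @return matrix pixels x 70, W m-2 of burned area.
#' @export
permafrostForcingSeries <- function(landscape, fires, params = forcingParams(),
                                    common_burn_year = TRUE, ...) {
  stopifnot(inherits(landscape, "PermafrostLandscape"))
  n <- nrow(landscape$pixels)
  horizon <- params$horizon_years
  by <- if (common_burn_year) round(median(fires$burn_year)) else NULL
  um <- if (common_burn_year) {
    list(co2 = unitPulseMatrix("co2", params, by),
         ch4 = unitPulseMatrix("ch4", params, by))
  } else NULL
  out <- matrix(0, n, horizon)
  for (i in seq_len(n)) {
    out[i, ] <- permafrostForcing(
      soc = landscape$soc[i, ], soil_class = landscape$pixels$soil_class[i],
      pre_alt = landscape$pixels$pre_alt_cm[i],
      frost_free = landscape$frost_free[i, ],
      zonation_index = landscape$pixels$zonation_index[i], params = params,
      burn_year = if (common_burn_year) by else fires$burn_year[i],
      unit_matrices = um, ...)
  }
  out
}

#' Compare modelled permafrost fluxes with field observations
#'
#' Matches modelled fluxes to in-situ observations by years since fire and
#' reports their ratios; no pass/fail threshold is applied.
#'
#' @param modelled data.frame with `years_post_fire` and `flux`.
#' @param field_obs data.frame with `years_post_fire` and `flux` (same units).
#' @return list with the matched `table` (observed, modelled, ratio) and
#'   `mean_ratio`.
#' @export
validateAgainstField <- function(modelled, field_obs) {
  m <- merge(field_obs, modelled, by = "years_post_fire",
             suffixes = c("_observed", "_modelled"))
  if (!nrow(m)) stop("no overlapping years between model and observations")
  m$ratio <- ifelse(m$flux_observed == 0, NA_real_,
                    m$flux_modelled / m$flux_observed)
  list(table = m, mean_ratio = mean(m$ratio, na.rm = TRUE))
}
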