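# borealForcing default parameter set (version 1).
#
# All physical coefficients used by the forcing pathways live here, never in
# code. Values marked "non-authoritative" are literature-plausible defaults
# assembled from the standard sources for each quantity (simplified radiative
# expressions, pulse-response fits, biomass-burning emission-factor
# compilations, IPCC-era GWPs, permafrost incubation syntheses). Replace them
# with a project-specific table before drawing quantitative conclusions about
# real landscapes; unit tests and the synthetic-landscape analyses do not
# depend on their exact magnitudes unless stated.
version: 1
constants:
  earth_surface_area_m2: 5.100656e+14
  # total moles of dry air (5.1352e18 kg / 0.0289644 kg mol-1)
  atmosphere_moles: 1.77294e+20
  pixel_area_m2: 2.5e+05        # 500 m grid cell
  molar_mass:                 # kg mol-1
    co2: 0.04401
    ch4: 0.01604
    n2o: 0.04401
    air: 0.0289644

gases:
  # Simplified radiative expressions (global-mean W m-2), ln-form for CO2 and
  # sqrt-forms for CH4 and N2O with band-overlap terms. Concentrations in ppm
  # (CO2) and ppb (CH4, N2O).
  co2:
    expr: {a1: -2.4e-7, b1: 7.2e-4, c1: -2.1e-4, ln_coeff: 5.36}
    valid_range: [180.0, 2000.0]
  ch4:
    expr: {a3: -1.3e-6, b3: -8.2e-6, coeff: 0.043}
    valid_range: [340.0, 3500.0]
    lifetime_years: 12.4
  n2o:
    expr: {a2: -8.0e-6, b2: 4.2e-6, c2: -4.9e-6, coeff: 0.117}
    valid_range: [200.0, 525.0]
    lifetime:
      tau_ref_years: 116.0
      n_ref_ppb: 323.0
      feedback_exponent: -0.055   # d ln(tau) / d ln(N2O); lifetime shrinks as burden grows

# Multi-exponential airborne fraction of a CO2 pulse (value 1 at t = 0,
# asymptote a0). Coefficients follow the widely used multi-model pulse fit;
# non-authoritative stand-in for a scenario-specific response.
co2_impulse_response:
  a0: 0.2173
  a: [0.2240, 0.2824, 0.2763]
  tau_years: [394.4, 36.54, 4.304]

# Approximate SSP2-4.5 background mixing ratios, linearly interpolated between
# anchor years and held flat outside the table. Non-authoritative.
background:
  years:    [2001, 2010, 2020, 2030, 2040, 2050, 2060, 2070, 2080, 2090, 2100]
  co2_ppm:  [ 371,  389,  412,  436,  460,  481,  500,  515,  527,  535,  540]
  ch4_ppb:  [1772, 1798, 1860, 1890, 1900, 1880, 1840, 1790, 1740, 1690, 1650]
  n2o_ppb:  [ 316,  323,  332,  341,  350,  358,  365,  371,  376,  380,  383]

# Boreal-forest emission factors, g species per kg dry matter burned, with one
# standard deviation. Non-authoritative defaults in the style of the standard
# biomass-burning compilations.
emission_factors:
  carbon_fraction: 0.45       # kg C per kg dry matter
  species:
    co2:   {ef: 1489.0, sd: 121.0}
    co:    {ef:  127.0, sd:  45.0}
    ch4:   {ef:    5.96, sd:  3.14}
    n2o:   {ef:    0.41, sd:  0.21}
    nox:   {ef:    0.90, sd:  0.69}
    nmvoc: {ef:   27.0,  sd: 14.0}
    oc:    {ef:   10.9,  sd:  6.9}
    bc:    {ef:    0.43, sd:  0.30}

# Global warming potentials (mass basis, relative to CO2) at 20- and 100-year
# horizons with one standard deviation; CH4 rows anchor the conversion of
# precursor and aerosol masses onto the CH4 forcing pathway. Non-authoritative.
gwp:
  ch4:   {gwp20:   84.0, gwp20_sd:  24.0, gwp100:  28.0, gwp100_sd:  8.0}
  co:    {gwp20:    5.9, gwp20_sd:   2.5, gwp100:   1.9, gwp100_sd:  0.8}
  nox:   {gwp20:   19.0, gwp20_sd:  24.0, gwp100: -11.0, gwp100_sd: 15.0}
  nmvoc: {gwp20:   14.0, gwp20_sd:   8.0, gwp100:   4.5, gwp100_sd:  2.5}
  bc:    {gwp20: 3200.0, gwp20_sd: 1800.0, gwp100: 900.0, gwp100_sd: 500.0}
  oc:    {gwp20: -240.0, gwp20_sd: 130.0, gwp100: -69.0, gwp100_sd: 38.0}

aerosol:
  # ratio of indirect to all-sky direct aerosol radiative forcing
  indirect_direct_ratio: 2.0
  gwp_horizon_years: 20

ozone:
  # CO-driven ozone forcing: CO mass routed through the CH4 pathway scaled by
  # its GWP ratio at this horizon.
  horizon_years: 20

precursor:
  horizon_years: 20           # config switch: 20 or 100
  species: [nox, nmvoc]       # CO enters via the ozone pathway to avoid double counting

permafrost:
  soc_interval_breaks_cm: [0, 30, 50, 100, 200, 300]
  organic_threshold_pct_c: 20.0
  lab_to_field_factor: 2.93   # divide lab-derived release by this
  ch4_c_fraction: 0.1589      # fraction of released C emitted as CH4-C
  # Annual release fractions (fraction of exposed C released in incubation year
  # 1..10 at constant 5 degC, aerobic), by soil class. Non-authoritative
  # placeholder tables shaped like published incubation syntheses.
  release_curves:
    mineral: [0.030, 0.025, 0.021, 0.018, 0.016, 0.014, 0.013, 0.012, 0.011, 0.010]
    organic: [0.016, 0.014, 0.012, 0.011, 0.010, 0.009, 0.009, 0.008, 0.008, 0.008]
  release_extrapolation: hold_last   # hold_last | decay
  release_decay_rate: 0.03           # used when release_extrapolation == decay
  # Post-fire fractional change in active layer thickness vs years since fire,
  # piecewise-linear; literature-review-shaped placeholder.
  dalt:
    years: [0,    1,    5,    10,   15,   25,   50,   70]
    frac:  [0.05, 0.15, 0.40, 0.50, 0.45, 0.30, 0.10, 0.05]
  max_depth_cm: 300

albedo:
  # kernels are declared in W m-2 (contribution to the annual mean) per unit
  # increase in surface albedo; negative values mean an albedo increase cools.
  kernel_units: Wm2_per_unit_albedo_annual_mean

horizon_years: 70
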