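# GHG, precursor and aerosol pathways: emission bookkeeping, impulse response,
# lifetimes, simplified expressions, and the per-burned-area convention.

test_that("emissions are the configured linear function of combusted carbon", {
  em0 <- emissionsFromCombustion(0, PARAMS)
  expect_true(all(em0 == 0))
  em1 <- emissionsFromCombustion(3.13, PARAMS)
  em2 <- emissionsFromCombustion(6.26, PARAMS)
  expect_equal(em2, 2 * em1)
  # spreadsheet oracle over the configured EF table
  ef <- PARAMS$emission_factors
  for (s in colnames(em1)) {
    expect_equal(unname(em1[1, s]),
                 3.13 / ef$carbon_fraction * ef$species[[s]]$ef / 1000,
                 info = s)
  }
  expect_error(emissionsFromCombustion(-1, PARAMS), "non-negative")
})

test_that("the impulse response starts at 1, decays monotonically to a0", {
  irf <- PARAMS$co2_impulse_response
  expect_equal(co2AirborneFraction(0, irf), 1)
  expect_equal(co2AirborneFraction(1e7, irf), irf$a0, tolerance = 1e-10)
  t <- seq(0, 500, by = 0.5)
  af <- co2AirborneFraction(t, irf)
  expect_true(all(diff(af) <= 0))
  expect_true(all(af > 0 & af <= 1))
  # closed form for a single-exponential response
  single <- list(a0 = 0, a = 1, tau_years = 17)
  expect_equal(co2AirborneFraction(17, single), exp(-1))
  expect_error(co2AirborneFraction(-1, irf), "non-negative")
})

test_that("concentration perturbations decay with the right e-folding", {
  m <- 5e6
  ch4 <- concentrationPerturbation(m, "ch4", c(0, 12.4), PARAMS)
  expect_equal(ch4[2] / ch4[1], exp(-1), tolerance = 1e-12)
  expect_equal(concentrationPerturbation(0, "ch4", c(0, 5, 50), PARAMS),
               rep(0, 3))
  # irf held at 1 -> constant CO2 perturbation
  p1 <- PARAMS
  p1$co2_impulse_response <- list(a0 = 1, a = numeric(0), tau_years = numeric(0))
  co2 <- concentrationPerturbation(m, "co2", c(0, 10, 70), p1)
  expect_equal(co2, rep(co2[1], 3))
  expect_error(concentrationPerturbation(m, "xyz", 1, PARAMS))
})

test_that("a CH4 perturbation integrates to tau * (1 - exp(-T/tau))", {
  m <- 1e7
  x0 <- concentrationPerturbation(m, "ch4", 0, PARAMS)
  num <- integrate(function(t) concentrationPerturbation(m, "ch4", t, PARAMS),
                   0, 70, rel.tol = 1e-10)$value
  tau <- PARAMS$gases$ch4$lifetime_years
  expect_equal(num, x0 * tau * (1 - exp(-70 / tau)), tolerance = 1e-6)
})

test_that("the N2O lifetime feedback shortens the lifetime as burden grows", {
  lt <- PARAMS$gases$n2o$lifetime
  expect_equal(n2oLifetime(lt$n_ref_ppb, PARAMS), lt$tau_ref_years)
  expect_lt(n2oLifetime(400, PARAMS), n2oLifetime(330, PARAMS))
  p0 <- PARAMS
  p0$gases$n2o$lifetime$feedback_exponent <- 0
  expect_equal(n2oLifetime(c(210, 330, 500), p0), rep(lt$tau_ref_years, 3))
  expect_warning(n2oLifetime(600, PARAMS), "clamped")
})

test_that("simplified expressions vanish at the background and behave", {
  for (gas in c("co2", "ch4", "n2o")) {
    c0 <- backgroundConcentration(gas, 2010, PARAMS)
    expect_identical(simplifiedRF(gas, c0, c0, PARAMS), 0)
  }
  # CO2 doubling with band-overlap coefficients zeroed -> ln-coefficient * ln 2
  p0 <- PARAMS
  p0$gases$co2$expr$a1 <- 0; p0$gases$co2$expr$b1 <- 0; p0$gases$co2$expr$c1 <- 0
  expect_equal(simplifiedRF("co2", 800, 400, p0),
               PARAMS$gases$co2$expr$ln_coeff * log(2))
  # strictly increasing in concentration over the validity range
  grid <- seq(400, 1990, by = 10)
  rf <- simplifiedRF("co2", grid, 400, PARAMS)
  expect_true(all(diff(rf) > 0))
  expect_warning(simplifiedRF("co2", 3000, 400, PARAMS), "validity")
})

test_that("ozone forcing is linear in CO with the configured coefficient", {
  z <- ozoneFromCO(0, PARAMS)
  expect_identical(z, rep(0, 70))
  f1 <- ozoneFromCO(0.5, PARAMS)
  f2 <- ozoneFromCO(1.0, PARAMS)
  expect_equal(f2, 2 * f1, tolerance = 1e-6)
  # hand-computed product: the CO mass converted by the GWP ratio through the
  # CH4 pathway, evaluated at the first post-fire mid-year
  mass <- 0.5; A <- PARAMS$constants$pixel_area_m2
  eq <- mass * A * PARAMS$gwp$co$gwp20 / PARAMS$gwp$ch4$gwp20
  # the mid-year pulse is evaluated at its own mid-year (age 0) in year 1
  dppb <- eq / PARAMS$constants$molar_mass$ch4 / PARAMS$constants$atmosphere_moles * 1e9
  m0 <- backgroundConcentration("ch4", 2010.5, PARAMS)
  rf <- simplifiedRF("ch4", m0 + dppb, m0, PARAMS, year = 2010.5)
  expect_equal(f1[1], rf * PARAMS$constants$earth_surface_area_m2 / A,
               tolerance = 1e-6)
})

test_that("precursor forcing follows the GWP conversion onto the CH4 pathway", {
  gwp0 <- PARAMS$gwp
  gwp0$nmvoc$gwp20 <- 0
  expect_equal(precursorForcingGWP(0.1, "nmvoc", PARAMS, gwp = gwp0),
               rep(0, 70))
  # species with the CH4 GWP and equal mass is identical to CH4 forcing
  gwp1 <- PARAMS$gwp
  gwp1$nox$gwp20 <- gwp1$ch4$gwp20
  mass <- 0.02; A <- PARAMS$constants$pixel_area_m2
  f <- precursorForcingGWP(mass, "nox", PARAMS, gwp = gwp1)
  ref <- perBurnedArea(
    pulseForcingSeries(c(mass * A, rep(0, 69)), "ch4", PARAMS, 2010), A, PARAMS)
  expect_equal(f, ref, tolerance = 1e-12)
  # negative GWP propagates to negative forcing
  f_neg <- precursorForcingGWP(0.02, "nox", PARAMS, horizon = 100)
  expect_true(all(f_neg <= 0) && any(f_neg < 0))
  expect_error(precursorForcingGWP(1, "so2", PARAMS))
})

test_that("aerosol forcing is confined to the first post-fire year", {
  z <- aerosolForcing(0, 0, PARAMS)
  expect_identical(z$total, rep(0, 70))
  a <- aerosolForcing(0.07, 0.003, PARAMS)
  expect_identical(a$total[2:70], rep(0, 69))
  expect_identical(a$direct[2:70], rep(0, 69))
  expect_true(a$total[1] != 0)
  a0 <- aerosolForcing(0.07, 0.003, PARAMS, indirect_ratio = 0)
  expect_equal(a0$total, a0$direct)
  expect_error(aerosolForcing(-1, 0, PARAMS), "non-negative")
})

test_that("per-burned-area rescaling follows the reporting convention", {
  comp <- list(co2 = rep(1e-9, 70), aerosol = rep(-2e-10, 70))
  A <- PARAMS$constants$pixel_area_m2
  half <- integrateForcing(comp, A / 2, PARAMS)
  full <- integrateForcing(comp, A, PARAMS)
  expect_equal(half$ghg_precursor, 2 * full$ghg_precursor)
  expect_equal(full$ghg_precursor + full$aerosol, full$co2 + full$aerosol)
  expect_error(integrateForcing(list(co2 = rep(1, 69)), A, PARAMS), "length")
})

test_that("total forcing is additive across pixels and monotone in carbon", {
  f <- function(carbon) ghgAerosolForcing(carbon, PARAMS)$ghg_precursor
  joint <- f(2.0 + 4.0)
  expect_equal(f(2.0) + f(4.0), joint, tolerance = 1e-6)
  means <- vapply(c(0.5, 1, 2, 4, 8), function(c) mean(f(c)), numeric(1))
  expect_true(all(diff(means) > 0))
  # zero emissions give a zero series in every component
  f0 <- ghgAerosolForcing(0, PARAMS)
  expect_true(all(vapply(f0, function(s) all(s == 0), logical(1))))
})

test_that("a single CO2 pulse under a flat response and background is constant", {
  p1 <- PARAMS
  p1$co2_impulse_response <- list(a0 = 1, a = numeric(0), tau_years = numeric(0))
  p1$background$co2_ppm <- rep(400, length(p1$background$years))
  p1$background$ch4_ppb <- rep(1800, length(p1$background$years))
  p1$background$n2o_ppb <- rep(330, length(p1$background$years))
  ser <- pulseForcingSeries(c(1e9, rep(0, 69)), "co2", p1, 2005)
  expect_equal(ser, rep(ser[1], 70), tolerance = 1e-12)
})
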