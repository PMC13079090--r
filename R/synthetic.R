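# Synthetic burned-landscape generator.
#
# Generates pixel tables, permafrost landscapes, observation trajectories and
# radiative kernels with the statistical structure the analysis assumes, while
# retaining the generating ("truth") parameters so that recovery tests can
# compare estimates against known values. Fields are i.i.d. per pixel (no
# spatial covariance is imposed).

#' Configuration for the synthetic landscape generator
#'
#' Defaults encode the study conditions the analysis assumes: combustion drawn
#' from a normal with mean 3.13 and sd 1.20 kg C m-2 truncated at zero,
#' permafrost-zone shares matching the burned-area distribution across
#' isolated/sporadic/discontinuous/continuous zones, a post-fire spring albedo
#' increase decaying over ~25 years, and a source-to-sink NEE recovery
#' trajectory.
#'
#' @param n_pixels number of burned pixels (>= 1).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param combustion_mean,combustion_sd combustion distribution, kg C m-2.
#' @param zone_mix named proportions over
#'   `c("none", "isolated", "sporadic", "discontinuous", "continuous")`;
#'   must sum to 1.
#' @param albedo_truth list: `amplitude` (peak spring albedo increase at year
#'   0), `decay_years` (e-folding time of the increase), `obs_months` (months
#'   emitted by the observation generator).
#' @param nee_truth list: `source` and `sink` magnitudes (g C m-2 yr-1),
#'   `tau_source`, `tau_sink` (years), `baseline` (pre-fire NEE).
#' @param noise_sd per-observable additive noise sds: `albedo`, `nee`.
#' @param burn_years calendar years fires may occur in (historical record for
#'   the space-for-time design).
#' @param obs_years calendar years with satellite observations.
#' @param pixel_area_m2 pixel area carried as metadata (500 m grid).
#' @return a validated list of class `"SyntheticConfig"`.
#' @export
#' @examples
#' cfg <- syntheticConfig(n_pixels = 100, seed = 1)
syntheticConfig <- function(n_pixels = 10000,
                            seed = 1L,
                            combustion_mean = 3.13,
                            combustion_sd = 1.20,
                            zone_mix = c(none = 0.02, isolated = 0.09,
                                         sporadic = 0.49, discontinuous = 0.36,
                                         continuous = 0.04),
                            albedo_truth = list(amplitude = 0.25,
                                                decay_years = 40,
                                                obs_months = 2:6),
                            nee_truth = list(source = 40, sink = 30,
                                             tau_source = 10, tau_sink = 30,
                                             baseline = -20),
                            noise_sd = list(albedo = 0.02, nee = 10),
                            burn_years = 1950:2019,
                            obs_years = 2000:2020,
                            pixel_area_m2 = 2.5e5) {
  if (length(n_pixels) != 1 || !is.finite(n_pixels) || n_pixels < 1) {
    stop("n_pixels must be a positive count")
  }
  zones <- c("none", "isolated", "sporadic", "discontinuous", "continuous")
  if (!setequal(names(zone_mix), zones)) {
    stop("zone_mix must be named over: ", paste(zones, collapse = ", "))
  }
  zone_mix <- zone_mix[zones]
  if (abs(sum(zone_mix) - 1) > 1e-8 || any(zone_mix < 0)) {
    stop("zone_mix must be non-negative and sum to 1")
  }
  if (combustion_sd < 0) stop("combustion_sd must be non-negative")
  cfg <- list(n_pixels = as.integer(n_pixels), seed = as.integer(seed),
              combustion_mean = combustion_mean, combustion_sd = combustion_sd,
              zone_mix = zone_mix, albedo_truth = albedo_truth,
              nee_truth = nee_truth, noise_sd = noise_sd,
              burn_years = burn_years, obs_years = obs_years,
              pixel_area_m2 = pixel_area_m2)
  class(cfg) <- "SyntheticConfig"
  cfg
}

# exact truncated-normal (lower bound 0) sampler via inverse CDF
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  p0 <- pnorm(0, mean, sd)
  qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

# shared monthly structure of the synthetic albedo climate: snow-driven
# pre-fire baseline and the seasonal weighting of the post-fire increase
albedoMonthlyBase <- function() {
  c(0.55, 0.60, 0.55, 0.35, 0.15, 0.12, 0.11, 0.11, 0.12, 0.25, 0.45, 0.55)
}
albedoSeasonalWeight <- function() {
  c(0.50, 0.90, 1.00, 1.00, 0.60, 0.15, 0.05, 0.05, 0.10, 0.20, 0.30, 0.40)
}

#' Generate the synthetic burned-pixel table
#'
#' Per-pixel burn year, day of burning, combusted carbon (truncated normal),
#' ecoregion label, latitude, treeline distance, land-cover fractions, and the
#' environmental feature set used by the albedo and NEE models.
#'
#' @param cfg a [syntheticConfig()].
#' @return data.frame with one row per pixel.
#' @export
genFireGrid <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_pixels
    combustion <- rtruncnorm0(n, cfg$combustion_mean, cfg$combustion_sd)
    burn_year <- sample(cfg$burn_years, n, replace = TRUE)
    day_of_burning <- pmin(pmax(round(rnorm(n, 193, 42)), 100), 300)
    ecoregion <- sample(c("Interior Alaska", "Boreal Shield", "Boreal Cordillera",
                          "Taiga Plain", "Boreal Plain", "Taiga Shield"),
                        n, replace = TRUE,
                        prob = c(0.25, 0.25, 0.15, 0.15, 0.10, 0.10))
    latitude <- runif(n, 52, 69)
    treeline_km <- pmax(0, (69 - latitude) * 110 + rnorm(n, 0, 60))
    # land cover: a share of near-pure stands so the forest-type contrast has data
    kind <- sample(c("evergreen", "deciduous", "mixed"), n, replace = TRUE,
                   prob = c(0.30, 0.10, 0.60))
    frac_evergreen <- ifelse(kind == "evergreen", runif(n, 0.90, 1.0),
                             ifelse(kind == "deciduous", runif(n, 0.0, 0.08),
                                    runif(n, 0.2, 0.7)))
    frac_deciduous <- pmin(1 - frac_evergreen, ifelse(
      kind == "deciduous", runif(n, 0.90, 1.0), runif(n, 0.0, 0.25)))
    frac_other <- pmax(0, runif(n, 0, 1) * (1 - frac_evergreen - frac_deciduous))
    df <- data.frame(
      pixel_id = seq_len(n), burn_year = burn_year,
      day_of_burning = day_of_burning, combustion = combustion,
      ecoregion = ecoregion, latitude = latitude, treeline_km = treeline_km,
      frac_evergreen = frac_evergreen, frac_deciduous = frac_deciduous,
      frac_other = frac_other,
      # albedo-model features
      ruggedness = rexp(n, 1 / 40),
      elevation = rlnorm(n, log(400), 0.5),
      soil_ph = rnorm(n, 5.5, 0.7),
      silt_pct = runif(n, 10, 60),
      cmd = pmax(0, rnorm(n, 150, 50)),
      evaporation = pmax(0, rnorm(n, 300, 60)),
      autumn_precip = pmax(0, rnorm(n, 120, 35)),
      autumn_temp = rnorm(n, -2, 3),
      spring_temp = rnorm(n, 1, 3),
      # additional NEE-model features
      dd18 = rexp(n, 1 / 90),
      emt = rnorm(n, -42, 5),
      spring_precip = pmax(0, rnorm(n, 90, 30)),
      winter_temp = rnorm(n, -20, 5),
      continentality = rnorm(n, 35, 8))
    attr(df, "pixel_area_m2") <- cfg$pixel_area_m2
    df
  })
}

zoneBands <- function() {
  list(none = c(0, 0), isolated = c(1e-6, 0.10), sporadic = c(0.10, 0.50),
       discontinuous = c(0.50, 0.90), continuous = c(0.90, 1.0))
}

#' Generate the synthetic permafrost landscape
#'
#' Assigns each pixel a permafrost zone by the configured mix and draws its
#' zonation index uniformly within the zone's band (isolated (0, 0.10),
#' sporadic 0.10-0.50, discontinuous 0.50-0.90, continuous >= 0.90; "none"
#' pixels get index 0). Generates depth-interval SOC stocks (0-30, 30-50,
#' 50-100, 100-200, 200-300 cm), topsoil carbon content with the 20 %
#' organic/mineral threshold, pre-fire active layer thickness in 20-150 cm, and
#' a per-pixel frost-free-day fraction series over the 70 post-fire years.
#'
#' @param cfg a [syntheticConfig()].
#' @param params parameter list (supplies the SOC interval breaks).
#' @return list of class `"PermafrostLandscape"`: `pixels` (data.frame with
#'   zone, zonation_index, pre_alt_cm, carbon_pct, soil_class), `soc` (matrix
#'   pixels x intervals, kg C m-2), `frost_free` (matrix pixels x 70,
#'   fraction of frost-free days per post-fire year).
#' @export
genPermafrostLandscape <- function(cfg, params = forcingParams()) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  withr::with_seed(cfg$seed + 1L, {
    n <- cfg$n_pixels
    zones <- names(cfg$zone_mix)
    zone <- sample(zones, n, replace = TRUE, prob = cfg$zone_mix)
    bands <- zoneBands()
    idx <- vapply(zone, function(z) {
      b <- bands[[z]]
      if (z == "none") 0 else runif(1, b[1], b[2])
    }, numeric(1))
    carbon_pct <- ifelse(runif(n) < 0.45,
                         pmin(60, rlnorm(n, log(30), 0.35)),
                         pmin(19.9, rlnorm(n, log(8), 0.45)))
    thr <- params$permafrost$organic_threshold_pct_c
    soil_class <- ifelse(carbon_pct >= thr, "organic", "mineral")
    mean_stock <- rbind(organic = c(16, 10, 18, 22, 12),
                        mineral = c(7, 5, 9, 12, 8))
    soc <- t(vapply(seq_len(n), function(i) {
      rlnorm(5, log(mean_stock[soil_class[i], ]), 0.30)
    }, numeric(5)))
    colnames(soc) <- socIntervalNames(params)
    pre_alt <- pmin(150, pmax(20, rnorm(n, 70, 25)))
    ff_mean <- pmin(0.95, pmax(0.05, rnorm(n, 0.42, 0.05)))
    horizon <- params$horizon_years
    frost_free <- matrix(pmin(1, pmax(0, rep(ff_mean, horizon) +
                                        rnorm(n * horizon, 0, 0.02))),
                         nrow = n, ncol = horizon)
    out <- list(pixels = data.frame(pixel_id = seq_len(n), zone = zone,
                                    zonation_index = idx, pre_alt_cm = pre_alt,
                                    carbon_pct = carbon_pct,
                                    soil_class = soil_class),
                soc = soc, frost_free = frost_free)
    class(out) <- "PermafrostLandscape"
    out
  })
}

#' Ground-truth record for the synthetic landscape
#'
#' Combines the fire grid and permafrost landscape with the per-pixel
#' generating parameters of the albedo and NEE recovery curves. Kept alongside
#' the observations so recovery tests can compare estimates against truth.
#'
#' @param cfg a [syntheticConfig()].
#' @param fires fire grid from [genFireGrid()] (regenerated if NULL).
#' @param permafrost landscape from [genPermafrostLandscape()] (regenerated if
#'   NULL).
#' @param params parameter list.
#' @return list of class `"TruthRecord"` with elements `pixels` (per-pixel
#'   truth table), `monthly_base`, `seasonal_weight`, `cfg`.
#' @export
makeTruthRecord <- function(cfg, fires = NULL, permafrost = NULL,
                            params = forcingParams()) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  if (is.null(fires)) fires <- genFireGrid(cfg)
  if (is.null(permafrost)) permafrost <- genPermafrostLandscape(cfg, params)
  withr::with_seed(cfg$seed + 2L, {
    n <- cfg$n_pixels
    z <- function(x) as.numeric(scale(x))
    at <- cfg$albedo_truth
    # the post-fire albedo increase depends on elevation and permafrost extent
    amplitude <- pmax(0, at$amplitude *
                        (1 + 0.30 * z(fires$elevation) +
                           0.20 * permafrost$pixels$zonation_index - 0.10))
    # pre-fire baseline varies with soil, so the noiseless truth is fully
    # determined by the model features
    base_offset <- 0.04 * z(fires$soil_ph) + 0.02 * z(fires$silt_pct)
    nt <- cfg$nee_truth
    source_mag <- pmax(0, nt$source * (1 + 0.25 * z(fires$dd18)))
    sink_mag <- pmax(0, nt$sink * (1 + 0.20 * z(fires$evaporation)))
    truth <- list(
      pixels = data.frame(
        pixel_id = fires$pixel_id, burn_year = fires$burn_year,
        combustion = fires$combustion,
        zonation_index = permafrost$pixels$zonation_index,
        pre_alt_cm = permafrost$pixels$pre_alt_cm,
        albedo_amplitude = amplitude, albedo_decay = at$decay_years,
        albedo_base_offset = base_offset,
        nee_source = source_mag, nee_sink = sink_mag,
        nee_tau_source = nt$tau_source, nee_tau_sink = nt$tau_sink,
        nee_baseline = nt$baseline),
      monthly_base = albedoMonthlyBase(),
      seasonal_weight = albedoSeasonalWeight(),
      cfg = cfg)
    class(truth) <- "TruthRecord"
    truth
  })
}

#' Noiseless truth curves of the synthetic generator
#'
#' `trueAlbedo()` returns the generating monthly blue-sky albedo of a pixel at
#' a given years-since-fire (negative values give the pre-fire baseline);
#' `trueNEE()` the generating annual NEE (g C m-2 yr-1, positive = source).
#'
#' @param truth a `"TruthRecord"`.
#' @param pixel_id pixel identifiers (vectorised, recycled against `month`/`t`).
#' @param month calendar month 1-12.
#' @param t years since fire.
#' @return numeric vector.
#' @export
trueAlbedo <- function(truth, pixel_id, month, t) {
  stopifnot(inherits(truth, "TruthRecord"))
  px <- truth$pixels[pixel_id, ]
  base <- truth$monthly_base[month] + px$albedo_base_offset
  inc <- ifelse(t >= 0,
                px$albedo_amplitude * truth$seasonal_weight[month] *
                  exp(-pmax(t, 0) / px$albedo_decay),
                0)
  pmin(1, pmax(0, base + inc))
}

#' @rdname trueAlbedo
#' @export
trueNEE <- function(truth, pixel_id, t) {
  stopifnot(inherits(truth, "TruthRecord"))
  px <- truth$pixels[pixel_id, ]
  ifelse(t >= 0,
         px$nee_baseline + px$nee_source * exp(-pmax(t, 0) / px$nee_tau_source) -
           px$nee_sink * (1 - exp(-pmax(t, 0) / px$nee_tau_sink)),
         px$nee_baseline)
}

#' Generate calendar-dated observation trajectories
#'
#' Emits monthly blue-sky albedo samples and annual NEE samples for every pixel
#' over the configured observation window, adding i.i.d. Gaussian noise to the
#' truth curves (albedo clamped to [0, 1]). Observations predating a pixel's
#' fire carry the pre-fire baseline and feed the pre-fire monthly means in the
#' chronosequence builder; years-since-fire values up to 70 are produced by
#' pairing the historical burn years with the observation window.
#'
#' @param truth a `"TruthRecord"` from [makeTruthRecord()].
#' @param cfg the [syntheticConfig()] used to build `truth`.
#' @param months calendar months to emit for albedo (default
#'   `cfg$albedo_truth$obs_months`).
#' @return list with data.frames `albedo` (pixel_id, obs_year, month, albedo)
#'   and `nee` (pixel_id, obs_year, nee).
#' @export
genObservationTrajectories <- function(truth, cfg,
                                       months = cfg$albedo_truth$obs_months) {
  stopifnot(inherits(truth, "TruthRecord"), inherits(cfg, "SyntheticConfig"))
  withr::with_seed(cfg$seed + 3L, {
    n <- cfg$n_pixels
    oy <- cfg$obs_years
    alb <- expand.grid(pixel_id = seq_len(n), obs_year = oy, month = months,
                       KEEP.OUT.ATTRS = FALSE)
    ysf <- alb$obs_year - truth$pixels$burn_year[alb$pixel_id]
    mu <- trueAlbedo(truth, alb$pixel_id, alb$month, ysf)
    alb$albedo <- pmin(1, pmax(0, mu + rnorm(nrow(alb), 0, cfg$noise_sd$albedo)))
    nee <- expand.grid(pixel_id = seq_len(n), obs_year = oy,
                       KEEP.OUT.ATTRS = FALSE)
    ysf_n <- nee$obs_year - truth$pixels$burn_year[nee$pixel_id]
    nee$nee <- trueNEE(truth, nee$pixel_id, ysf_n) +
      rnorm(nrow(nee), 0, cfg$noise_sd$nee)
    list(albedo = alb, nee = nee)
  })
}

#' Latitude-dependent monthly albedo radiative kernels
#'
#' Synthetic top-of-atmosphere kernels in W m-2 (contribution to the annual
#' mean) per unit increase in surface albedo, negative by convention (an albedo
#' increase cools). The seasonal profile peaks in spring (high insolation over
#' snow) and scales weakly with latitude.
#'
#' @param fires fire grid from [genFireGrid()] (supplies pixel latitudes).
#' @param cfg a [syntheticConfig()].
#' @return matrix `n_pixels` x 12.
#' @export
genKernelGrid <- function(fires, cfg) {
  withr::with_seed(cfg$seed + 4L, {
    profile <- -c(3, 8, 14, 20, 16, 12, 10, 8, 5, 3, 1.5, 1.5)
    latfac <- 1 + 0.15 * (fires$latitude - 60) / 10
    k <- outer(latfac, profile) * (1 + matrix(rnorm(nrow(fires) * 12, 0, 0.05),
                                              nrow(fires), 12))
    colnames(k) <- month.abb
    k
  })
}

#' Generate a complete synthetic landscape
#'
#' Convenience wrapper running [genFireGrid()], [genPermafrostLandscape()],
#' [makeTruthRecord()], [genObservationTrajectories()] and [genKernelGrid()]
#' under one configuration.
#'
#' @param cfg a [syntheticConfig()].
#' @param params parameter list.
#' @param months albedo observation months (see
#'   [genObservationTrajectories()]).
#' @return list with elements `fires`, `permafrost`, `truth`, `observations`,
#'   `kernels`, `cfg`.
#' @export
#' @examples
#' land <- genSyntheticLandscape(syntheticConfig(n_pixels = 50, seed = 7))
#' names(land)
genSyntheticLandscape <- function(cfg, params = forcingParams(),
                                  months = cfg$albedo_truth$obs_months) {
  fires <- genFireGrid(cfg)
  permafrost <- genPermafrostLandscape(cfg, params)
  truth <- makeTruthRecord(cfg, fires, permafrost, params)
  observations <- genObservationTrajectories(truth, cfg, months)
  kernels <- genKernelGrid(fires, cfg)
  list(fires = fires, permafrost = permafrost, truth = truth,
       observations = observations, kernels = kernels, cfg = cfg)
}
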