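# Uncertainty machinery: a 10-version parameter ensemble for GHG/precursor and
# aerosol forcing, bootstrap model ensembles for the albedo/NEE regressors, and
# the six-scenario permafrost sensitivity analysis.

#' Draw one perturbed parameter version
#'
#' Samples every emission factor and GWP within one standard deviation of its
#' mean: uniformly on [mu - sd, mu + sd] by default (the bounded reading of
#' "within one standard deviation"), or from a normal truncated to that
#' interval. Parameters without an sd are held fixed with a warning. Emission
#' factors are clamped at zero; GWPs may be negative.
#'
#' @param params parameter list.
#' @param sampling `"uniform"` or `"truncnorm"`.
#' @return list with perturbed `ef` (structure of `params$emission_factors`)
#'   and `gwp` tables.
#' @export
drawParameterVersion <- function(params = forcingParams(),
                                 sampling = c("uniform", "truncnorm")) {
  sampling <- match.arg(sampling)
  draw1 <- function(mu, sd) {
    if (is.null(sd) || is.na(sd)) {
      warning("parameter without sd held fixed at its mean")
      return(mu)
    }
    if (sd == 0) return(mu)
    if (sampling == "uniform") {
      runif(1, mu - sd, mu + sd)
    } else {
      lo <- pnorm(-1); hi <- pnorm(1)
      mu + sd * qnorm(runif(1, lo, hi))
    }
  }
  ef <- params$emission_factors
  for (s in names(ef$species)) {
    ef$species[[s]]$ef <- max(0, draw1(ef$species[[s]]$ef, ef$species[[s]]$sd))
  }
  gwp <- params$gwp
  for (s in names(gwp)) {
    gwp[[s]]$gwp20 <- draw1(gwp[[s]]$gwp20, gwp[[s]]$gwp20_sd)
    gwp[[s]]$gwp100 <- draw1(gwp[[s]]$gwp100, gwp[[s]]$gwp100_sd)
  }
  list(ef = ef, gwp = gwp)
}

#' Parameter-ensemble uncertainty of GHG/precursor and aerosol forcing
#'
#' Builds `n_versions` versions of the forcing framework by sampling emission
#' factors and GWPs within one standard deviation, runs each version over a
#' sample of experimentally burned pixels with combustion drawn from the
#' truncated normal (mean 3.13, sd 1.20 kg C m-2 by default), and summarises
#' the across-version spread of the pixel-mean 70-year mean forcing. The
#' primary relative uncertainty is the across-version sd divided by the
#' across-version mean (in percent); `pooled_relative_pct` additionally folds
#' in the pixel-to-pixel combustion spread.
#'
#' @param n_pixels number of experimentally burned pixels.
#' @param n_versions ensemble size (10 in the reference design).
#' @param seed RNG seed; the ensemble is reproducible under a fixed seed.
#' @param params parameter list.
#' @param combustion_mean,combustion_sd combustion distribution, kg C m-2.
#' @param burn_year calendar year of the fires.
#' @param sampling passed to [drawParameterVersion()].
#' @return list of class `"EnsembleResult"`: `summary` data.frame with one row
#'   per component (`ghg_precursor`, `aerosol`) holding the ensemble mean, sd,
#'   `relative_pct` and `pooled_relative_pct`; plus the per-version component
#'   means in `versions`.
#' @export
ghgParameterEnsemble <- function(n_pixels = 10000, n_versions = 10, seed = 1,
                                 params = forcingParams(),
                                 combustion_mean = 3.13, combustion_sd = 1.20,
                                 burn_year = 2010,
                                 sampling = "uniform") {
  withr::with_seed(seed, {
    combustion <- rtruncnorm0(n_pixels, combustion_mean, combustion_sd)
    unit <- vapply(seq_len(n_versions), function(v) {
      draw <- drawParameterVersion(params, sampling)
      f <- ghgAerosolForcing(1, params, burn_year = burn_year,
                             ef = draw$ef, gwp = draw$gwp)
      c(ghg_precursor = mean(f$ghg_precursor), aerosol = mean(f$aerosol))
    }, numeric(2))
  })
  # forcing is linear in combusted carbon: pixel p under version v forces
  # combustion[p] * unit[comp, v] (W m-2 of burned area, 70-year mean)
  mean_c <- mean(combustion)
  versions <- t(unit) * mean_c          # n_versions x 2 pixel-mean forcing
  summarise <- function(comp) {
    v <- versions[, comp]
    m <- mean(v); s <- sd(v)
    rel <- if (m == 0) NA_real_ else 100 * s / abs(m)
    # pooled spread over (pixel, version) pairs
    pooled_mean <- mean_c * mean(unit[comp, ])
    pooled_var <- mean(combustion^2) * mean(unit[comp, ]^2) - pooled_mean^2
    pooled <- if (pooled_mean == 0) NA_real_ else
      100 * sqrt(max(pooled_var, 0)) / abs(pooled_mean)
    data.frame(component = comp, mean = m, sd = s, relative_pct = rel,
               pooled_relative_pct = pooled)
  }
  out <- list(summary = rbind(summarise("ghg_precursor"), summarise("aerosol")),
              versions = versions, n_pixels = n_pixels,
              n_versions = n_versions, seed = seed)
  class(out) <- "EnsembleResult"
  out
}

#' Bootstrap model ensemble for albedo / NEE predictions
#'
#' Trains `n_models` regressors, each on a random `train_fraction` (default
#' 60 %) of the available training samples, and predicts over `newdata`. The
#' across-model standard deviation is the prediction uncertainty and the mean
#' absolute value across models is the measured value; the relative uncertainty
#' is their ratio in percent, averaged over the prediction set.
#'
#' @param samples training data.frame (one chronosequence cell).
#' @param features feature columns.
#' @param response response column.
#' @param newdata data.frame of prediction pixels.
#' @param n_models ensemble size.
#' @param train_fraction fraction of samples per model (without replacement).
#' @param seed RNG seed; subsets differ across models, the fit seed is shared,
#'   so `train_fraction = 1` yields identical models and zero spread.
#' @param regressor,num_trees passed to the regressor.
#' @return list of class `"EnsembleResult"`: `measured` (mean absolute
#'   prediction), `sd` (per prediction pixel), `relative_pct`, and the raw
#'   `predictions` matrix (pixels x models).
#' @export
bootstrapModelEnsemble <- function(samples, features, response, newdata,
                                   n_models = 10, train_fraction = 0.60,
                                   seed = 1, regressor = "ranger",
                                   num_trees = 100) {
  stopifnot(train_fraction > 0, train_fraction <= 1)
  samples <- samples[complete.cases(samples[c(features, response)]), ,
                     drop = FALSE]
  if (nrow(samples) < 2) stop("too few samples for a bootstrap ensemble")
  pred <- withr::with_seed(seed, {
    vapply(seq_len(n_models), function(m) {
      idx <- sample.int(nrow(samples),
                        size = max(1, round(nrow(samples) * train_fraction)))
      reg <- fitRegressor(samples[idx, features, drop = FALSE],
                          samples[[response]][idx], regressor, seed, num_trees)
      reg$predict(newdata[features])
    }, numeric(nrow(newdata)))
  })
  pred <- matrix(pred, nrow = nrow(newdata))
  measured <- rowMeans(abs(pred))
  s <- apply(pred, 1, sd)
  rel <- if (mean(measured) == 0) NA_real_ else
    100 * mean(s) / mean(measured)
  out <- list(measured = measured, sd = s, relative_pct = rel,
              predictions = pred, n_models = n_models,
              train_fraction = train_fraction, seed = seed)
  class(out) <- "EnsembleResult"
  out
}

#' The six default permafrost sensitivity scenarios
#'
#' One version without the lab-to-field scaling factor, carbon emissions
#' reduced and increased by 50 %, a 50 % additional thickening of the active
#' layer, and two versions combining the emission changes with the additional
#' thickening. The unmodified model is the baseline the scenarios are compared
#' against.
#'
#' @param params parameter list (supplies the baseline lab-to-field factor).
#' @return list of six scenario specs (label + multipliers).
#' @export
permafrostScenarioSpecs <- function(params = forcingParams()) {
  lab <- params$permafrost$lab_to_field_factor
  spec <- function(label, lab_to_field = lab, emission = 1, alt = 1) {
    list(label = label, lab_to_field = lab_to_field,
         emission_multiplier = emission, alt_multiplier = alt)
  }
  list(spec("no_lab_to_field_factor", lab_to_field = 1),
       spec("emissions_minus_50", emission = 0.5),
       spec("emissions_plus_50", emission = 1.5),
       spec("alt_plus_50", alt = 1.5),
       spec("combined_plus50_alt50", emission = 1.5, alt = 1.5),
       spec("combined_minus50_alt50", emission = 0.5, alt = 1.5))
}

#' Permafrost sensitivity analysis across model scenarios
#'
#' Re-runs the permafrost forcing model over a sample of permafrost-underlain
#' burned pixels under each scenario's multipliers and summarises the
#' dispersion of the scenario set (baseline included) as a relative
#' uncertainty: sd across scenario means divided by their mean, in percent.
#'
#' @param landscape a `"PermafrostLandscape"`.
#' @param fires fire grid aligned with `landscape`.
#' @param scenarios list of scenario specs (default
#'   [permafrostScenarioSpecs()]).
#' @param params parameter list.
#' @param n_pixels number of permafrost pixels to sample (default: all with a
#'   positive zonation index).
#' @param seed RNG seed for the pixel sample.
#' @return list of class `"ScenarioResult"`: `table` (label, multipliers, mean
#'   forcing), `baseline`, `relative_uncertainty_pct`.
#' @export
permafrostScenarios <- function(landscape, fires,
                                scenarios = permafrostScenarioSpecs(params),
                                params = forcingParams(), n_pixels = NULL,
                                seed = 1) {
  stopifnot(inherits(landscape, "PermafrostLandscape"))
  pf <- which(landscape$pixels$zonation_index > 0)
  if (!length(pf)) stop("landscape has no permafrost pixels")
  idx <- withr::with_seed(seed, {
    if (is.null(n_pixels) || n_pixels >= length(pf)) pf else
      sample(pf, n_pixels)
  })
  sub <- list(pixels = landscape$pixels[idx, , drop = FALSE],
              soc = landscape$soc[idx, , drop = FALSE],
              frost_free = landscape$frost_free[idx, , drop = FALSE])
  class(sub) <- "PermafrostLandscape"
  fsub <- fires[idx, , drop = FALSE]
  run <- function(lab, em, alt) {
    mean(rowMeans(permafrostForcingSeries(sub, fsub, params,
                                          lab_to_field = lab,
                                          emission_multiplier = em,
                                          alt_multiplier = alt)))
  }
  baseline <- run(params$permafrost$lab_to_field_factor, 1, 1)
  vals <- vapply(scenarios, function(s) {
    run(s$lab_to_field, s$emission_multiplier, s$alt_multiplier)
  }, numeric(1))
  tab <- data.frame(label = vapply(scenarios, `[[`, character(1), "label"),
                    lab_to_field = vapply(scenarios, `[[`, numeric(1), "lab_to_field"),
                    emission_multiplier = vapply(scenarios, `[[`, numeric(1),
                                                 "emission_multiplier"),
                    alt_multiplier = vapply(scenarios, `[[`, numeric(1),
                                            "alt_multiplier"),
                    mean_forcing = vals)
  all_vals <- c(baseline, vals)
  rel <- if (mean(all_vals) == 0) NA_real_ else
    100 * sd(all_vals) / abs(mean(all_vals))
  out <- list(table = tab, baseline = baseline,
              relative_uncertainty_pct = rel, n_pixels = length(idx),
              seed = seed)
  class(out) <- "ScenarioResult"
  out
}
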