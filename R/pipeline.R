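# End-to-end driver over a synthetic landscape plus plain-text output writers
# (pixel tables and forcing series as CSV, configs as YAML, run manifest as
# JSON).

# complete a per-pixel-month pre-fire mean table: pixels burned before the
# observation record fall back to the cross-pixel mean of their month
completePrefire <- function(prefire, pixel_ids, months) {
  grid <- expand.grid(pixel_id = pixel_ids, month = months,
                      KEEP.OUT.ATTRS = FALSE)
  m <- merge(grid, prefire, by = c("pixel_id", "month"), all.x = TRUE)
  month_mean <- tapply(prefire$prefire_mean, prefire$month, mean)
  na <- is.na(m$prefire_mean)
  m$prefire_mean[na] <- month_mean[as.character(m$month[na])]
  m
}

#' Run the full forcing framework over a synthetic landscape
#'
#' Generates a synthetic burned landscape, computes all five forcing components
#' per pixel - direct GHG + precursor emissions, aerosols, surface-albedo
#' change through kernels, vegetation recovery, and fire-induced permafrost
#' thaw - assembles the [FireForcingLedger-class], and derives the comparative
#' summaries (classification shares, permafrost-zone distributions, treeline
#' trends, warming/cooling group contrasts, forest-type contrast, and the
#' no-permafrost variant of the net forcing).
#'
#' @param cfg a [syntheticConfig()].
#' @param params parameter list.
#' @param years post-fire years modelled by the recovery regressions
#'   (default 0:69, i.e. the full 70-year horizon).
#' @param regressor regressor for the albedo/NEE models.
#' @param num_trees trees per forest (kept modest; the chronosequence cells are
#'   small).
#' @param min_cell minimum samples per chronosequence cell.
#' @return list of class `"ForcingPipeline"`: `ledger`, `summaries`,
#'   `model_metrics`, `landscape`, `cfg`.
#' @export
runPipeline <- function(cfg = syntheticConfig(n_pixels = 500),
                        params = forcingParams(), years = 0:69,
                        regressor = "ranger", num_trees = 50, min_cell = 20) {
  land <- genSyntheticLandscape(cfg, params)
  fires <- land$fires
  n <- nrow(fires)
  horizon <- params$horizon_years

  # --- direct GHG/precursor + aerosol: linear in combustion, one unit series
  # per distinct burn year
  ghg <- matrix(0, n, horizon); aer <- matrix(0, n, horizon)
  for (by in unique(fires$burn_year)) {
    sel <- fires$burn_year == by
    unit <- ghgAerosolForcing(1, params, burn_year = by,
                              burned_area = cfg$pixel_area_m2)
    ghg[sel, ] <- outer(fires$combustion[sel], unit$ghg_precursor)
    aer[sel, ] <- outer(fires$combustion[sel], unit$aerosol)
  }

  # --- albedo: chronosequence -> per-cell models -> delta-albedo -> kernels
  months <- cfg$albedo_truth$obs_months
  chrono_a <- buildChronosequence(fires, land$observations$albedo, "albedo")
  feat <- cbind(fires, zonation_index = land$permafrost$pixels$zonation_index)
  samples_a <- merge(chrono_a$samples, feat[c("pixel_id", albedoFeatures())],
                     by = "pixel_id")
  chrono_a$samples <- samples_a
  mod_a <- fitAlbedoModels(chrono_a, months = months, years = years,
                           seed = cfg$seed, regressor = regressor,
                           min_cell = min_cell, num_trees = num_trees)
  prefire <- completePrefire(chrono_a$prefire, fires$pixel_id, months)
  delta <- predictDeltaAlbedo(mod_a, feat, prefire, months = months,
                              years = years)
  alb <- kernelForcing(delta, land$kernels, fires$pixel_id, horizon)
  alb[is.na(alb)] <- 0   # unmodelled cells contribute no forcing

  # --- vegetation recovery: annual NEE models -> trajectories -> CO2 pathway
  chrono_n <- buildChronosequence(fires, land$observations$nee, "nee")
  samples_n <- merge(chrono_n$samples, feat[c("pixel_id", neeFeatures())],
                     by = "pixel_id")
  chrono_n$samples <- samples_n
  mod_n <- fitNEEModels(chrono_n, years = years, seed = cfg$seed,
                        regressor = regressor, min_cell = min_cell,
                        num_trees = num_trees)
  # no-fire counterfactual: the pre-fire prediction held constant; pixels
  # burned before the observation record fall back to the cross-pixel mean
  prefire_n <- chrono_n$prefire
  base_n <- prefire_n$prefire_mean[match(fires$pixel_id, prefire_n$pixel_id)]
  base_n[is.na(base_n)] <- mean(prefire_n$prefire_mean)
  traj <- neeRecoveryTrajectory(mod_n, feat, years = years,
                                prefire = data.frame(pixel_id = fires$pixel_id,
                                                     prefire_mean = base_n))
  nee <- matrix(0, n, horizon)
  for (i in seq_len(n)) {
    ann <- numeric(horizon)
    ann[seq_along(years)] <- traj$annual[i, ]
    nee[i, ] <- neeToForcing(ann, fire_carbon = fires$combustion[i], params,
                             burn_year = fires$burn_year[i],
                             burned_area = cfg$pixel_area_m2,
                             pixel_area = cfg$pixel_area_m2)$series
  }

  # --- permafrost thaw
  pf <- permafrostForcingSeries(land$permafrost, fires, params)

  covars <- cbind(fires, land$permafrost$pixels[c("zone", "zonation_index",
                                                  "pre_alt_cm", "soil_class")])
  ledger <- netForcing(list(ghg_precursor = ghg, permafrost = pf, albedo = alb,
                            aerosol = aer, nee = nee), covariates = covars)

  summaries <- summarizeLedger(ledger)
  structure(list(ledger = ledger, summaries = summaries,
                 model_metrics = list(albedo = mod_a$metrics,
                                      nee = mod_n$metrics),
                 landscape = land, cfg = cfg),
            class = "ForcingPipeline")
}

#' Standard summaries of a forcing ledger
#'
#' Component means, warming share, the no-permafrost variant of the net
#' forcing, per-zone permafrost and net distributions, the treeline trend of
#' the net forcing, and the warming-vs-cooling contrast of combustion and day
#' of burning.
#'
#' @param ledger a [FireForcingLedger-class] whose rowData carries the pipeline
#'   covariates.
#' @return named list of summary tables.
#' @export
summarizeLedger <- function(ledger) {
  rd <- rowData(ledger)
  comps <- forcingComponents(ledger)
  comp_means <- vapply(comps, function(k) {
    mean(rowMeans(componentForcing(ledger, k)))
  }, numeric(1))
  cum <- cumulativeForcing(ledger, "mean")
  cls <- classification(ledger)
  out <- list(
    component_means = c(comp_means, net = mean(cum)),
    warming_share_pct = 100 * mean(cls == "warming"),
    net_without_permafrost =
      mean(cum - rowMeans(componentForcing(ledger, "permafrost"))))
  if ("zone" %in% names(rd)) {
    pfm <- rowMeans(componentForcing(ledger, "permafrost"))
    out$permafrost_by_zone <- summarizeByZone(pfm, rd$zone)
    out$net_by_zone <- summarizeByZone(cum, rd$zone)
  }
  if ("treeline_km" %in% names(rd)) {
    out$treeline_trend_net <- treelineTrend(rd$treeline_km, cum)
  }
  if ("combustion" %in% names(rd) && length(unique(cls)) == 2) {
    out$combustion_contrast <- compareGroups(rd$combustion[cls == "warming"],
                                             rd$combustion[cls == "cooling"])
    if ("day_of_burning" %in% names(rd)) {
      out$day_of_burning_contrast <-
        compareGroups(rd$day_of_burning[cls == "warming"],
                      rd$day_of_burning[cls == "cooling"])
    }
  }
  out
}

#' Write ledger outputs as plain-text files
#'
#' Writes the per-pixel cumulative component/net means plus covariates to
#' `pixels.csv`, the long per-pixel-year net series to `net_series.csv`, and a
#' JSON run manifest (seed, configuration hash, counts) to `manifest.json`.
#'
#' @param ledger a [FireForcingLedger-class].
#' @param dir output directory (created if needed).
#' @param cfg optional [syntheticConfig()] recorded in the manifest.
#' @return the directory, invisibly.
#' @export
writeLedgerOutputs <- function(ledger, dir, cfg = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rd <- as.data.frame(rowData(ledger))
  comps <- forcingComponents(ledger)
  for (k in comps) rd[[paste0("mean_", k)]] <- rowMeans(componentForcing(ledger, k))
  write.csv(rd, file.path(dir, "pixels.csv"), row.names = FALSE)
  net <- netSeries(ledger)
  long <- data.frame(pixel = rep(seq_len(nrow(net)), ncol(net)),
                     post_fire_year = rep(seq_len(ncol(net)), each = nrow(net)),
                     net_forcing = as.vector(net))
  write.csv(long, file.path(dir, "net_series.csv"), row.names = FALSE)
  manifest <- list(n_pixels = nrow(net), horizon_years = ncol(net),
                   components = comps,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(cfg)) {
    manifest$seed <- cfg$seed
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(unclass(cfg), tmp)
    manifest$config_md5 <- unname(tools::md5sum(tmp))
    unlink(tmp)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
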