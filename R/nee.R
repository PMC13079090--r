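# Post-fire vegetation recovery: annual NEE trajectories per post-fire year via
# the space-for-time design, and conversion of cumulative CO2 uptake into
# (negative) radiative forcing against the fire-perturbed background.

#' Annual NEE budgets from monthly gridded fluxes
#'
#' Sums the twelve monthly fluxes of each pixel-year into an annual budget
#' (g C m-2 yr-1, positive = source to atmosphere). Pixel-years with missing
#' months are excluded and flagged.
#'
#' @param monthly data.frame with `pixel_id`, `year`, `month`, `nee`
#'   (g C m-2 month-1).
#' @return data.frame `pixel_id`, `year`, `nee` (annual), with attribute
#'   `incomplete` listing excluded pixel-years.
#' @export
buildAnnualNEE <- function(monthly) {
  stopifnot(all(c("pixel_id", "year", "month", "nee") %in% names(monthly)))
  agg <- aggregate(nee ~ pixel_id + year, data = monthly, FUN = sum)
  cnt <- aggregate(month ~ pixel_id + year, data = monthly,
                   FUN = function(m) length(unique(m)))
  full <- cnt$month == 12L
  out <- agg[full, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "incomplete") <- cnt[!full, c("pixel_id", "year")]
  if (any(!full)) {
    warning(sum(!full), " pixel-year(s) with missing months excluded")
  }
  out
}

#' Fit per-post-fire-year NEE models
#'
#' Annual analogue of [fitAlbedoModels()]: one regressor per years-since-fire
#' cell with an 80/20 train-test split, holdout R2/RMSE, permutation feature
#' importance and top-feature selection.
#'
#' @param chrono a `"Chronosequence"` built on annual NEE observations
#'   (`value_col = "nee"`).
#' @param years years-since-fire values to model.
#' @param features candidate feature columns (default [neeFeatures()]).
#' @param seed,regressor,min_cell,num_trees,test_fraction,top_features see
#'   [fitAlbedoModels()].
#' @return a `"RecoveryModelSet"` of annual cells.
#' @export
fitNEEModels <- function(chrono, years, features = neeFeatures(), seed = 1,
                         regressor = "ranger", min_cell = 30, num_trees = 100,
                         test_fraction = 0.2, top_features = 10) {
  fitRecoveryModels(chrono, months = NA, years = years, features = features,
                    seed = seed, regressor = regressor, min_cell = min_cell,
                    num_trees = num_trees, test_fraction = test_fraction,
                    top_features = top_features)
}

#' Fire-attributable NEE recovery trajectories
#'
#' Predicts annual NEE for each pixel over the requested post-fire years and
#' subtracts the no-fire counterfactual. The counterfactual is the year-0
#' pre-fire prediction held constant (`baseline = "year0"`) or a user-supplied
#' per-pixel baseline (`baseline = "custom"`, `baseline_value`). Cumulative
#' carbon is the running sum of the annual values.
#'
#' @param modelset a `"RecoveryModelSet"` from [fitNEEModels()].
#' @param pixels data.frame with `pixel_id` and the model features.
#' @param years post-fire years to predict (default: all fitted cells; year 0
#'   must be included when `baseline = "year0"`).
#' @param baseline `"year0"` or `"custom"`.
#' @param baseline_value per-pixel baseline NEE when `baseline = "custom"`.
#' @param prefire optional per-pixel pre-fire mean NEE table (`pixel_id`,
#'   `prefire_mean`); used as the year-0 baseline when supplied.
#' @return list of class `"RecoveryTrajectory"`: `annual` (pixels x years
#'   matrix of fire-attributable NEE, g C m-2 yr-1), `cumulative` (running
#'   sum), `years`, `baseline`.
#' @export
neeRecoveryTrajectory <- function(modelset, pixels,
                                  years = sort(unique(modelset$cells$year)),
                                  baseline = c("year0", "custom"),
                                  baseline_value = NULL, prefire = NULL) {
  stopifnot(inherits(modelset, "RecoveryModelSet"), !modelset$monthly)
  baseline <- match.arg(baseline)
  pred <- vapply(years, function(y) {
    mod <- getCellModel(modelset, NA, y)
    if (is.null(mod)) rep(NA_real_, nrow(pixels)) else mod(pixels[modelset$features])
  }, numeric(nrow(pixels)))
  pred <- matrix(pred, nrow = nrow(pixels),
                 dimnames = list(NULL, paste0("y", years)))
  base <- if (baseline == "custom") {
    stopifnot(length(baseline_value) %in% c(1L, nrow(pixels)))
    rep_len(baseline_value, nrow(pixels))
  } else if (!is.null(prefire)) {
    prefire$prefire_mean[match(pixels$pixel_id, prefire$pixel_id)]
  } else {
    if (!0 %in% years) stop("year 0 must be modelled for the year0 baseline")
    pred[, "y0"]
  }
  annual <- pred - base
  cumulative <- t(apply(annual, 1, cumsum))
  if (length(years) == 1L) cumulative <- matrix(cumulative, ncol = 1L)
  dimnames(cumulative) <- dimnames(annual)
  structure(list(annual = annual, cumulative = cumulative, years = years,
                 baseline = base),
            class = "RecoveryTrajectory")
}

#' Radiative forcing from post-fire carbon uptake
#'
#' Each year's fire-attributable net uptake becomes a (negative) CO2 mass pulse
#' routed through the CO2 pathway - impulse-response decay plus the simplified
#' expression - with the background concentration already perturbed by the
#' fire's own direct CO2 emissions, isolating the influence of post-fire uptake
#' from the combustion pulse itself.
#'
#' @param annual_nee length-70 fire-attributable annual NEE (g C m-2 yr-1,
#'   negative = uptake).
#' @param fire_carbon the pixel's combusted carbon, kg C m-2 (sets the direct
#'   CO2 perturbation of the background); 0 for an unperturbed background.
#' @param params parameter list.
#' @param burn_year calendar year of the fire.
#' @param burned_area burned area, m2.
#' @param pixel_area pixel area over which the NEE flux applies, m2.
#' @return list with `series` (length-70 W m-2 of burned area) and
#'   `cumulative` (running sum).
#' @export
neeToForcing <- function(annual_nee, fire_carbon = 0, params = forcingParams(),
                         burn_year = 2010,
                         burned_area = params$constants$pixel_area_m2,
                         pixel_area = params$constants$pixel_area_m2) {
  horizon <- params$horizon_years
  stopifnot(length(annual_nee) == horizon)
  annual_nee[is.na(annual_nee)] <- 0
  # g C m-2 yr-1 -> kg CO2 per pixel per year
  release <- annual_nee * (44 / 12) / 1000 * pixel_area
  baseline_release <- NULL
  if (fire_carbon > 0) {
    ef <- params$emission_factors
    fire_co2 <- fire_carbon / ef$carbon_fraction * ef$species$co2$ef / 1000 *
      burned_area
    baseline_release <- c(fire_co2, rep(0, horizon - 1))
  }
  ser <- perBurnedArea(pulseForcingSeries(release, "co2", params, burn_year,
                                          baseline_release = baseline_release),
                       burned_area, params)
  list(series = ser, cumulative = cumsum(ser))
}
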