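# Space-for-time chronosequence modelling of post-fire surface albedo and its
# conversion to radiative forcing through monthly albedo radiative kernels.

#' Build a space-for-time chronosequence
#'
#' Joins fire records (pixel, burn year) with calendar-dated observations:
#' each observation's years-since-fire is its observation year minus the
#' pixel's burn year. Observations with years-since-fire in [0, `max_age`]
#' become training samples; observations predating the fire contribute only to
#' the pre-fire means (per pixel, and per month when a `month` column is
#' present).
#'
#' @param fires data.frame with `pixel_id` and `burn_year`.
#' @param observations data.frame with `pixel_id`, `obs_year`, optional
#'   `month`, and the response named by `value_col`.
#' @param value_col response column name (e.g. `"albedo"`, `"nee"`).
#' @param max_age maximum years-since-fire retained (default 70).
#' @param prefire_window how many years before the fire feed the pre-fire mean
#'   (default all available pre-fire observations).
#' @return list of class `"Chronosequence"`: `samples` (observations with a
#'   `years_since_fire` column), `prefire` (per-pixel[-month] pre-fire means),
#'   `value_col`.
#' @export
buildChronosequence <- function(fires, observations, value_col = "albedo",
                                max_age = 70, prefire_window = Inf) {
  stopifnot(all(c("pixel_id", "burn_year") %in% names(fires)),
            all(c("pixel_id", "obs_year", value_col) %in% names(observations)))
  by <- fires$burn_year[match(observations$pixel_id, fires$pixel_id)]
  obs <- observations
  obs$years_since_fire <- obs$obs_year - by
  samples <- obs[!is.na(obs$years_since_fire) & obs$years_since_fire >= 0 &
                   obs$years_since_fire <= max_age, , drop = FALSE]
  pre <- obs[!is.na(obs$years_since_fire) & obs$years_since_fire < 0 &
               obs$years_since_fire >= -prefire_window, , drop = FALSE]
  keys <- intersect(c("pixel_id", "month"), names(obs))
  prefire <- if (nrow(pre)) {
    agg <- aggregate(pre[[value_col]], by = pre[keys], FUN = mean)
    names(agg)[ncol(agg)] <- "prefire_mean"
    agg
  } else {
    empty <- pre[keys]
    empty$prefire_mean <- numeric(0)
    empty
  }
  structure(list(samples = samples, prefire = prefire, value_col = value_col),
            class = "Chronosequence")
}

# ---- pluggable regressors ------------------------------------------------

fitRegressor <- function(x, y, regressor, seed, num_trees) {
  switch(regressor,
    ranger = {
      d <- cbind(x, .response = y)
      m <- ranger::ranger(.response ~ ., data = d, num.trees = num_trees,
                          importance = "permutation", seed = seed,
                          num.threads = 1)
      list(fit = m,
           predict = function(newx) predict(m, newx, num.threads = 1)$predictions,
           importance = m$variable.importance)
    },
    lm = {
      d <- cbind(x, .response = y)
      m <- lm(.response ~ ., data = d)
      list(fit = m, predict = function(newx) unname(predict(m, newx)),
           importance = NULL)
    },
    cellmean = {
      mu <- mean(y)
      list(fit = mu, predict = function(newx) rep(mu, nrow(newx)),
           importance = setNames(rep(0, ncol(x)), colnames(x)))
    },
    stop("unknown regressor: ", regressor))
}

#' Permutation importance of features on a holdout set
#'
#' Mean increase in squared prediction error when a feature column is permuted;
#' approximately zero for features the fitted model does not use.
#'
#' @param predict_fun function mapping a feature data.frame to predictions.
#' @param x holdout feature data.frame.
#' @param y holdout response.
#' @param n_repeats permutations per feature.
#' @param seed RNG seed.
#' @return named numeric vector of importances.
#' @export
permutationImportance <- function(predict_fun, x, y, n_repeats = 3, seed = 1) {
  base_mse <- mean((predict_fun(x) - y)^2)
  withr::with_seed(seed, {
    vapply(colnames(x), function(f) {
      mean(vapply(seq_len(n_repeats), function(r) {
        xp <- x
        xp[[f]] <- sample(xp[[f]])
        mean((predict_fun(xp) - y)^2) - base_mse
      }, numeric(1)))
    }, numeric(1))
  })
}

fitCell <- function(data, features, response, regressor, seed, num_trees,
                    test_fraction) {
  n <- nrow(data)
  idx <- withr::with_seed(seed, sample.int(n, size = max(1, round(n * (1 - test_fraction)))))
  train <- data[idx, , drop = FALSE]
  test <- data[-idx, , drop = FALSE]
  reg <- fitRegressor(train[features], train[[response]], regressor, seed, num_trees)
  imp <- reg$importance
  if (nrow(test)) {
    pred <- reg$predict(test[features])
    res <- test[[response]] - pred
    rmse <- sqrt(mean(res^2))
    sst <- sum((test[[response]] - mean(test[[response]]))^2)
    r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
    if (is.null(imp)) {
      imp <- permutationImportance(reg$predict, test[features], test[[response]],
                                   seed = seed)
    }
  } else {
    rmse <- NA_real_; r2 <- NA_real_
    if (is.null(imp)) imp <- setNames(rep(NA_real_, length(features)), features)
  }
  list(predict = reg$predict, r2 = r2, rmse = rmse, n = n, importance = imp)
}

# shared cell-wise fitter over (month, years-since-fire) cells; month NA means
# annual cells only
fitRecoveryModels <- function(chrono, months, years, features, seed, regressor,
                              min_cell, num_trees, test_fraction, top_features) {
  stopifnot(inherits(chrono, "Chronosequence"))
  samples <- chrono$samples
  response <- chrono$value_col
  monthly <- !all(is.na(months))
  if (monthly && !"month" %in% names(samples)) {
    stop("samples carry no month column but monthly cells were requested")
  }
  features <- intersect(features, names(samples))
  if (!length(features)) stop("no requested features present in the samples")
  cells <- expand.grid(month = if (monthly) months else NA_integer_,
                       year = years, KEEP.OUT.ATTRS = FALSE)
  pass <- function(feats) {
    models <- vector("list", nrow(cells))
    metrics <- cells
    metrics$n <- 0L; metrics$r2 <- NA_real_; metrics$rmse <- NA_real_
    imps <- matrix(NA_real_, nrow(cells), length(feats),
                   dimnames = list(NULL, feats))
    for (i in seq_len(nrow(cells))) {
      sel <- samples$years_since_fire == cells$year[i]
      if (monthly) sel <- sel & samples$month == cells$month[i]
      d <- samples[sel, , drop = FALSE]
      d <- d[complete.cases(d[c(feats, response)]), , drop = FALSE]
      if (nrow(d) < min_cell) {
        warning("cell (month=", cells$month[i], ", year=", cells$year[i],
                ") has ", nrow(d), " samples (< ", min_cell, "); skipped")
        next
      }
      f <- fitCell(d, feats, response, regressor, seed + i, num_trees,
                   test_fraction)
      models[[i]] <- f$predict
      metrics$n[i] <- f$n; metrics$r2[i] <- f$r2; metrics$rmse[i] <- f$rmse
      imps[i, names(f$importance)] <- f$importance
    }
    list(models = models, metrics = metrics, imps = imps)
  }
  first <- pass(features)
  mean_imp <- colMeans(first$imps, na.rm = TRUE)
  n_keep <- min(top_features, length(features))
  keep <- if (all(!is.finite(mean_imp))) {
    features[seq_len(n_keep)]    # no cell was fit; keep the leading features
  } else {
    features[order(mean_imp, decreasing = TRUE, na.last = TRUE)][seq_len(n_keep)]
  }
  dropped <- setdiff(features, keep)
  final <- if (length(dropped)) pass(keep) else first
  structure(list(cells = final$metrics[c("month", "year")],
                 models = final$models, metrics = final$metrics,
                 importance = mean_imp, features = keep, dropped = dropped,
                 regressor = regressor, seed = seed, response = response,
                 monthly = monthly),
            class = "RecoveryModelSet")
}

#' Fit per-(month, post-fire-year) albedo models
#'
#' Trains one regressor per requested (calendar month, years-since-fire) cell
#' of the chronosequence, holding out `test_fraction` (default 20 %) of each
#' cell for R2/RMSE. Permutation feature importance is averaged across cells
#' and features outside the `top_features` most influential are dropped before
#' a final refit. The regressor is pluggable; the default is a random forest.
#'
#' @param chrono a `"Chronosequence"` built on albedo observations.
#' @param months calendar months to model.
#' @param years years-since-fire values to model.
#' @param features candidate feature columns.
#' @param seed RNG seed for splits and fits.
#' @param regressor `"ranger"`, `"lm"` or `"cellmean"`.
#' @param min_cell minimum samples per cell (smaller cells are skipped with a
#'   warning).
#' @param num_trees trees per forest.
#' @param test_fraction holdout fraction.
#' @param top_features retained feature count after importance ranking.
#' @return a `"RecoveryModelSet"` with per-cell models and metrics.
#' @export
fitAlbedoModels <- function(chrono, months, years, features = albedoFeatures(),
                            seed = 1, regressor = "ranger", min_cell = 30,
                            num_trees = 100, test_fraction = 0.2,
                            top_features = 10) {
  fitRecoveryModels(chrono, months, years, features, seed, regressor, min_cell,
                    num_trees, test_fraction, top_features)
}

#' Feature sets used by the recovery models
#'
#' The retained predictors for the albedo models (permafrost extent,
#' ruggedness, elevation, soil pH, silt percentage, climate moisture deficit,
#' evaporation, autumn precipitation, autumn and spring temperature) and the
#' NEE models (ruggedness, degree-days above 18 C, extreme minimum
#' temperature, evaporation, spring/autumn precipitation,
#' autumn/winter/spring temperature, continentality).
#'
#' @return character vector of feature column names.
#' @export
albedoFeatures <- function() {
  c("zonation_index", "ruggedness", "elevation", "soil_ph", "silt_pct", "cmd",
    "evaporation", "autumn_precip", "autumn_temp", "spring_temp")
}

#' @rdname albedoFeatures
#' @export
neeFeatures <- function() {
  c("ruggedness", "dd18", "emt", "evaporation", "spring_precip",
    "autumn_precip", "autumn_temp", "winter_temp", "spring_temp",
    "continentality")
}

getCellModel <- function(modelset, month, year) {
  sel <- modelset$cells$year == year
  if (modelset$monthly) sel <- sel & modelset$cells$month == month
  i <- which(sel)
  if (length(i) != 1) return(NULL)
  modelset$models[[i]]
}

#' Predict fire-induced albedo change
#'
#' For each requested (month, post-fire year) cell, predicts post-fire albedo
#' for the supplied pixels and subtracts the pixel's pre-fire monthly mean:
#' delta-alpha(month, year) = predicted - pre-fire mean, clamped to [-1, 1].
#' Cells without a fitted model yield NA and are excluded from kernel sums.
#'
#' @param modelset a `"RecoveryModelSet"` from [fitAlbedoModels()].
#' @param pixels data.frame with `pixel_id` and the model features.
#' @param prefire per-pixel-month pre-fire means (`pixel_id`, `month`,
#'   `prefire_mean`), e.g. from [buildChronosequence()].
#' @param months,years cells to predict (default: all fitted cells).
#' @return long data.frame (pixel_id, month, year, predicted, delta).
#' @export
predictDeltaAlbedo <- function(modelset, pixels, prefire,
                               months = unique(modelset$cells$month),
                               years = unique(modelset$cells$year)) {
  stopifnot(inherits(modelset, "RecoveryModelSet"))
  out <- list()
  for (m in months) {
    pm <- prefire[prefire$month == m, c("pixel_id", "prefire_mean")]
    base <- pm$prefire_mean[match(pixels$pixel_id, pm$pixel_id)]
    for (y in years) {
      mod <- getCellModel(modelset, m, y)
      pred <- if (is.null(mod)) rep(NA_real_, nrow(pixels)) else
        mod(pixels[modelset$features])
      delta <- pmin(1, pmax(-1, pred - base))
      out[[length(out) + 1L]] <- data.frame(pixel_id = pixels$pixel_id,
                                            month = m, year = y,
                                            predicted = pred, delta = delta)
    }
  }
  do.call(rbind, out)
}

#' Albedo radiative forcing through monthly kernels
#'
#' Annual forcing in post-fire year y is the sum over months of the pixel's
#' kernel value times its fire-induced albedo change:
#' F(y) = sum_m K(m) * delta-alpha(m, y). Kernels follow the negative
#' convention (albedo increase => negative forcing) and are declared in W m-2
#' per unit albedo change (annual-mean contribution). Months with missing
#' deltas are excluded from the sum and counted in the `n_months` attribute;
#' years with no modelled month are NA.
#'
#' @param delta long data.frame from [predictDeltaAlbedo()].
#' @param kernels matrix pixels x 12 (rows aligned with `pixel_ids`).
#' @param pixel_ids pixel identifiers for the kernel rows.
#' @param horizon series length (default 70; year index y holds
#'   years-since-fire y - 1).
#' @return matrix pixels x `horizon` of W m-2 of burned area, with attribute
#'   `n_months` (months contributing per pixel-year).
#' @export
kernelForcing <- function(delta, kernels, pixel_ids = seq_len(nrow(kernels)),
                          horizon = 70) {
  stopifnot(ncol(kernels) == 12)
  px <- match(delta$pixel_id, pixel_ids)
  if (anyNA(px)) stop("delta table contains pixels without kernel rows")
  yi <- delta$year + 1L   # years-since-fire 0 -> series index 1
  keep <- !is.na(delta$delta) & yi >= 1 & yi <= horizon
  forcing <- matrix(NA_real_, length(pixel_ids), horizon)
  nm <- matrix(0L, length(pixel_ids), horizon)
  contrib <- kernels[cbind(px, delta$month)] * delta$delta
  for (j in which(keep)) {
    i <- px[j]; y <- yi[j]
    forcing[i, y] <- if (is.na(forcing[i, y])) contrib[j] else forcing[i, y] + contrib[j]
    nm[i, y] <- nm[i, y] + 1L
  }
  attr(forcing, "n_months") <- nm
  forcing
}
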