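# Chronosequence construction, per-cell albedo models, delta-albedo prediction
# and kernel forcing.

test_that("years-since-fire is observation year minus burn year", {
  fires <- data.frame(pixel_id = 1:2, burn_year = c(1960, 2010))
  obs <- data.frame(pixel_id = c(1, 1, 2, 2, 2),
                    obs_year = c(2010, 1955, 2010, 2012, 2005),
                    month = 6,
                    albedo = c(0.2, 0.4, 0.3, 0.25, 0.35))
  ch <- buildChronosequence(fires, obs, "albedo")
  # a 1960 fire observed in June 2010 is a 50-years-after sample
  expect_equal(ch$samples$years_since_fire[ch$samples$pixel_id == 1], 50)
  # observation in the burn year counts as year 0
  expect_true(0 %in% ch$samples$years_since_fire[ch$samples$pixel_id == 2])
  # pre-fire observations only feed the pre-fire means
  expect_equal(ch$prefire$prefire_mean[ch$prefire$pixel_id == 1], 0.4)
  expect_equal(ch$prefire$prefire_mean[ch$prefire$pixel_id == 2], 0.35)
  expect_false(any(ch$samples$years_since_fire < 0))
})

test_that("no post-fire observations yields an empty table, not an error", {
  fires <- data.frame(pixel_id = 1, burn_year = 2030)
  obs <- data.frame(pixel_id = 1, obs_year = 2010, month = 4, albedo = 0.3)
  ch <- buildChronosequence(fires, obs, "albedo")
  expect_equal(nrow(ch$samples), 0)
})

test_that("noiseless truth is recovered with high holdout R2", {
  cfg <- smallConfig(n = 2500, seed = 5, noise_sd = list(albedo = 0, nee = 0))
  land <- genSyntheticLandscape(cfg, PARAMS, months = 4)
  ch <- albedoChrono(land)
  # the synthetic truth is feature-determined: the linear plug-in regressor
  # recovers it exactly, the default forest close behind
  ms_lm <- fitAlbedoModels(ch, months = 4, years = c(0, 2, 5), seed = 1,
                           regressor = "lm")
  expect_true(all(ms_lm$metrics$r2 >= 0.95))
  ms_rf <- fitAlbedoModels(ch, months = 4, years = c(0, 2, 5), seed = 1,
                           regressor = "ranger", num_trees = 150)
  expect_true(all(ms_rf$metrics$r2 >= 0.80))
  expect_true(all(ms_rf$metrics$rmse < 0.05))
})

test_that("a constant response gives zero RMSE and undefined R2", {
  fires <- data.frame(pixel_id = 1:200, burn_year = 2005)
  obs <- data.frame(pixel_id = 1:200, obs_year = 2010, month = 4, albedo = 0.4,
                    f1 = rnorm(200), f2 = rnorm(200))
  ch <- buildChronosequence(fires, obs, "albedo")
  ms <- fitAlbedoModels(ch, months = 4, years = 5, features = c("f1", "f2"),
                        seed = 1, regressor = "lm")
  expect_equal(ms$metrics$rmse, 0, tolerance = 1e-10)
  expect_true(is.na(ms$metrics$r2))
})

test_that("irrelevant features get near-zero permutation importance", {
  cfg <- smallConfig(n = 1200, seed = 6, noise_sd = list(albedo = 0, nee = 0))
  land <- genSyntheticLandscape(cfg, PARAMS, months = 4)
  ch <- albedoChrono(land)
  withr::with_seed(1, ch$samples$pure_noise <- rnorm(nrow(ch$samples)))
  ms <- fitAlbedoModels(ch, months = 4, years = c(0, 3),
                        features = c(albedoFeatures(), "pure_noise"),
                        seed = 1, num_trees = 150, top_features = 11)
  imp <- ms$importance
  expect_lt(abs(imp[["pure_noise"]]), 0.05 * max(imp))
  # truth drivers rank at the top
  expect_true(imp[["elevation"]] > imp[["pure_noise"]])
})

test_that("undersized cells are skipped with a warning", {
  fires <- data.frame(pixel_id = 1:10, burn_year = 2005)
  obs <- data.frame(pixel_id = 1:10, obs_year = 2010, month = 4,
                    albedo = runif(10), f1 = rnorm(10))
  ch <- buildChronosequence(fires, obs, "albedo")
  expect_warning(
    ms <- fitAlbedoModels(ch, months = 4, years = 5, features = "f1",
                          seed = 1, min_cell = 50, regressor = "lm"),
    "skipped")
  expect_true(is.na(ms$metrics$r2))
})

test_that("delta-albedo is prediction minus pre-fire mean, bounded in [-1, 1]", {
  cfg <- smallConfig(n = 800, seed = 7, noise_sd = list(albedo = 0, nee = 0),
                     burn_years = 2005:2015)
  land <- genSyntheticLandscape(cfg, PARAMS, months = 4)
  ch <- albedoChrono(land)
  ms <- fitAlbedoModels(ch, months = 4, years = 0, seed = 1, regressor = "lm")
  feat <- featureTable(land)
  delta <- predictDeltaAlbedo(ms, feat, ch$prefire, months = 4, years = 0)
  expect_true(all(delta$delta >= -1 & delta$delta <= 1, na.rm = TRUE))
  # at year 0 in the peak month the fitted change equals the generating
  # amplitude (seasonal weight 1 in April)
  truth_amp <- land$truth$pixels$albedo_amplitude
  ok <- !is.na(delta$delta)
  expect_lt(mean(abs(delta$delta[ok] - truth_amp[delta$pixel_id[ok]])), 0.01)
})

test_that("prediction equal to the pre-fire mean gives zero delta", {
  ms <- structure(list(cells = data.frame(month = 4, year = 0),
                       models = list(function(x) rep(0.42, nrow(x))),
                       features = "f1", monthly = TRUE),
                  class = "RecoveryModelSet")
  pixels <- data.frame(pixel_id = 1:5, f1 = rnorm(5))
  prefire <- data.frame(pixel_id = 1:5, month = 4, prefire_mean = 0.42)
  d <- predictDeltaAlbedo(ms, pixels, prefire, months = 4, years = 0)
  expect_equal(d$delta, rep(0, 5))
})

test_that("kernel forcing does the month-by-month arithmetic", {
  kernels <- matrix(0, 1, 12)
  kernels[1, 4] <- -100
  d <- data.frame(pixel_id = 1, month = 4, year = 0, predicted = NA,
                  delta = 0.1)
  f <- kernelForcing(d, kernels, pixel_ids = 1, horizon = 70)
  expect_equal(f[1, 1], -10)
  expect_true(all(is.na(f[1, 2:70])))

  # two months with equal and opposite contributions cancel
  kernels2 <- matrix(0, 1, 12); kernels2[1, 3] <- -50; kernels2[1, 4] <- -50
  d2 <- data.frame(pixel_id = 1, month = c(3, 4), year = 0, predicted = NA,
                   delta = c(0.2, -0.2))
  f2 <- kernelForcing(d2, kernels2, pixel_ids = 1)
  expect_equal(f2[1, 1], 0)
  expect_equal(attr(f2, "n_months")[1, 1], 2L)

  # zero delta everywhere -> zero forcing
  d3 <- data.frame(pixel_id = 1, month = 1:12, year = 0, predicted = NA,
                   delta = 0)
  f3 <- kernelForcing(d3, matrix(-10, 1, 12), pixel_ids = 1)
  expect_equal(f3[1, 1], 0)
})

test_that("albedo increases with negative kernels never warm", {
  withr::with_seed(42, {
    n <- 50
    kernels <- -matrix(runif(n * 12, 0, 15), n, 12)
    d <- expand.grid(pixel_id = 1:n, month = 1:12, year = 0:4)
    d$delta <- runif(nrow(d), 0, 0.3)
  })
  f <- kernelForcing(d, kernels, pixel_ids = 1:n)
  expect_true(all(f[, 1:5] <= 0))
})

test_that("a common truth curve is reproduced as the cell-wise mean", {
  # space-for-time consistency: every pixel follows the same curve, so the
  # cell-mean regressor recovers that curve
  cfg <- smallConfig(n = 500, seed = 12, noise_sd = list(albedo = 0.01, nee = 0))
  land <- genSyntheticLandscape(cfg, PARAMS, months = 4)
  tr <- land$truth
  tr$pixels$albedo_amplitude <- 0.12     # identical truth for all pixels
  tr$pixels$albedo_base_offset <- 0
  obs <- genObservationTrajectories(tr, cfg, months = 4)$albedo
  ch <- buildChronosequence(land$fires, obs, "albedo")
  ch$samples <- merge(ch$samples,
                      featureTable(land)[c("pixel_id", albedoFeatures())],
                      by = "pixel_id")
  yrs <- c(0, 5, 10, 20, 40)
  ms <- fitAlbedoModels(ch, months = 4, years = yrs, seed = 1,
                        regressor = "cellmean")
  fitted <- vapply(seq_along(yrs), function(i) {
    ms$models[[i]](data.frame(row = 1))
  }, numeric(1))
  truth_curve <- trueAlbedo(tr, rep(1, length(yrs)), 4, yrs)
  expect_equal(fitted, truth_curve, tolerance = 0.005)
})
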