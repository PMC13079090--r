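# Net forcing assembly, classification, group statistics, treeline trends,
# zone summaries and the forest-type contrast.

test_that("net forcing is the exact component sum and zero-fill is explicit", {
  withr::with_seed(21, {
    comps <- lapply(setNames(nm = c("ghg_precursor", "permafrost", "albedo",
                                    "aerosol", "nee")),
                    function(k) matrix(rnorm(30 * 70), 30, 70))
  })
  led <- netForcing(comps)
  total <- Reduce(`+`, comps)
  expect_identical(assay(led, "net"), total)
  expect_lt(max(abs(netSeries(led) - total)), 1e-15)
  expect_error(netForcing(comps[1:4]), "missing component")
  led0 <- netForcing(comps[c(1, 3, 4, 5)], zero_fill = "permafrost")
  expect_true(all(componentForcing(led0, "permafrost") == 0))
  # removing a positive component never increases the net
  pos <- abs(comps$permafrost)
  led_pos <- netForcing(c(comps[-2], list(permafrost = pos)))
  expect_true(all(cumulativeForcing(led_pos) >=
                    cumulativeForcing(led0) - 1e-12))
})

test_that("the Interior-Alaska component means sum to +0.34 and classify warming", {
  led <- constantLedger(list(ghg_precursor = 9.32, permafrost = 1.36,
                             albedo = -6.48, aerosol = -3.30, nee = -0.56))
  expect_equal(cumulativeForcing(led, "mean"), 0.34, tolerance = 1e-12)
  expect_identical(classification(led), "warming")
})

test_that("classification follows the sign with zero ties breaking to cooling", {
  led <- constantLedger(list(ghg_precursor = c(0.84, -3.37, 0),
                             permafrost = 0, albedo = 0, aerosol = 0, nee = 0),
                        n_pixels = 3)
  expect_identical(classification(led), c("warming", "cooling", "cooling"))
})

test_that("fire-level labels come from the perimeter mean", {
  led <- constantLedger(list(ghg_precursor = c(3, -1, -4, 5),
                             permafrost = 0, albedo = 0, aerosol = 0, nee = 0),
                        n_pixels = 4)
  lab <- classifyForcing(led, "fire", fire = c("A", "A", "B", "B"))
  # fire A mean = +1 (warming), fire B mean = +0.5 (warming)
  expect_equal(lab, rep("warming", 4), ignore_attr = TRUE)
  expect_equal(unname(attr(lab, "fire_means")), c(1, 0.5))
  expect_identical(classifyForcing(led, "pixel"),
                   c("warming", "cooling", "cooling", "warming"))
})

test_that("warming share is invariant to pixel ordering", {
  withr::with_seed(22, vals <- rnorm(500))
  led <- constantLedger(list(ghg_precursor = vals, permafrost = 0, albedo = 0,
                             aerosol = 0, nee = 0), n_pixels = 500)
  perm <- sample(500)
  led2 <- constantLedger(list(ghg_precursor = vals[perm], permafrost = 0,
                              albedo = 0, aerosol = 0, nee = 0), n_pixels = 500)
  expect_equal(mean(classification(led) == "warming"),
               mean(classification(led2) == "warming"))
})

test_that("flipping the albedo sign flips the dominant classification", {
  withr::with_seed(23, {
    n <- 400
    ghg <- matrix(rnorm(n, 8, 1.5), n, 70)
    alb <- matrix(rnorm(n, -10, 1.5), n, 70)
    rest <- list(permafrost = matrix(rnorm(n, 1, 0.3), n, 70),
                 aerosol = matrix(rnorm(n, -2, 0.5), n, 70),
                 nee = matrix(rnorm(n, -0.5, 0.2), n, 70))
  })
  cooling <- netForcing(c(list(ghg_precursor = ghg, albedo = alb), rest))
  warming <- netForcing(c(list(ghg_precursor = ghg, albedo = -alb), rest))
  expect_lt(mean(classification(cooling) == "warming"), 0.5)
  expect_gt(mean(classification(warming) == "warming"), 0.5)
})

test_that("Welch and Mann-Whitney tests match closed-form small-sample oracles", {
  same <- compareGroups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  x <- c(1, 2, 3); y <- c(101, 102, 103)
  out <- compareGroups(x, y)
  # closed-form Welch statistic: (mean difference) / sqrt(s1^2/3 + s2^2/3)
  t_hand <- (mean(x) - mean(y)) / sqrt(var(x) / 3 + var(y) / 3)
  expect_equal(out$statistic, t_hand)
  expect_lt(out$p, 0.001)

  # fully separated ranks: U = 0
  mw <- compareGroups(c(1, 2, 3), c(4, 5, 6), kind = "ordinal")
  expect_equal(unname(mw$statistic), 0)
  expect_error(compareGroups(1, c(1, 2)), "at least 2")
})

test_that("treeline trends recover the generating slope per 100 km", {
  withr::with_seed(24, {
    d <- runif(4000, 0, 900)
    flat <- rnorm(4000, -2, 0.3)
    sloped <- -1 - 0.004 * d + rnorm(4000, 0, 0.3)
  })
  tf <- treelineTrend(d, flat)
  expect_lt(abs(tf$slope_per_100km), 0.05)
  expect_gt(tf$p, 0.05)
  ts <- treelineTrend(d, sloped)
  expect_equal(ts$slope_per_100km, -0.4, tolerance = 0.1)
  expect_lt(ts$p, 0.001)
  # bins are ordered and non-overlapping by construction
  expect_true(all(diff(ts$bins$centre) == 50))
  expect_warning(short <- treelineTrend(c(10, 60), c(1, 2)), "undefined")
  expect_true(is.na(short$slope_per_100km))
})

test_that("treeline bin means shift the OLS slope as the closed form says", {
  d <- c(25, 75, 125, 175) * 2  # four bins at 50,150,250,350? keep direct:
  d <- c(25, 75, 125, 175)
  v <- c(1, 2, 3, 10)           # outlier in the last bin
  tt <- treelineTrend(d, v, bin_width = 50)
  x <- tt$bins$centre; y <- tt$bins$mean
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(tt$slope_per_100km, slope_hand * 100)
})

test_that("zone summaries reproduce direct quantile computations", {
  v <- c(1, 2, 3, 4, 10)
  s <- summarizeByZone(v, rep("sporadic", 5))
  expect_equal(s$q25, 2)
  expect_equal(s$q75, 4)
  expect_equal(s$median, 3)
  expect_equal(s$whisker_high, 4)   # 10 lies beyond q75 + 1.5 IQR = 7
  sym <- summarizeByZone(c(-2, -1, 0, 1, 2), rep("continuous", 5))
  expect_equal(sym$mean, sym$median)
  const <- summarizeByZone(rep(5, 4), rep("isolated", 4))
  expect_equal(const$q75 - const$q25, 0)
  # empty zones are omitted
  s2 <- summarizeByZone(v, c(rep("sporadic", 5)))
  expect_false("continuous" %in% s2$zone)
})

test_that("the forest-type contrast normalises component contributions", {
  n <- 40
  fe <- c(rep(0.95, 20), rep(0.02, 20))
  fd <- c(rep(0.02, 20), rep(0.95, 20))
  # deciduous pixels have exactly twice the albedo cooling, rest identical
  comps <- list(ghg_precursor = matrix(8, n, 70),
                permafrost = matrix(1, n, 70),
                albedo = matrix(rep(c(-4, -8), each = 20), n, 70),
                aerosol = matrix(-2, n, 70),
                nee = matrix(-0.5, n, 70))
  led <- netForcing(comps, covariates = data.frame(frac_evergreen = fe,
                                                   frac_deciduous = fd))
  fc <- forestTypeContrast(led)
  expect_equal(abs(unname(fc$pct_change_vs_evergreen["albedo"])), 100)
  expect_equal(unname(fc$pct_change_vs_evergreen["ghg_precursor"]), 0)
  expect_equal(sum(fc$contribution_share_pct), 100)
  expect_equal(unname(fc$contribution_share_pct["albedo"]), 100)
  expect_equal(unname(fc$warming_share_pct["evergreen"]), 100)
  expect_equal(unname(fc$warming_share_pct["deciduous"]), 0)

  # identical types: all percentage changes zero
  comps$albedo <- matrix(-4, n, 70)
  led2 <- netForcing(comps, covariates = data.frame(frac_evergreen = fe,
                                                    frac_deciduous = fd))
  fc2 <- forestTypeContrast(led2)
  expect_true(all(abs(fc2$pct_change_vs_evergreen) < 1e-12))
})
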