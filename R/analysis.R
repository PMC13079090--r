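# Comparative analyses of the forcing ledger: warming/cooling classification at
# pixel and fire level, group contrasts, treeline-distance trends, permafrost
# -zone summaries and the evergreen/deciduous forest-type contrast.

#' Classify pixels or whole fires as climate-warming or climate-cooling
#'
#' Pixel level: warming iff the pixel's 70-year cumulative mean net forcing is
#' positive. Fire level: the perimeter mean of the pixel values decides the
#' label, applied to every pixel of the fire. Exact zero ties break to
#' "cooling".
#'
#' @param ledger a [FireForcingLedger-class].
#' @param level `"pixel"` or `"fire"`.
#' @param fire fire identifiers per pixel (required for `level = "fire"`).
#' @return character vector of labels per pixel (fire-level labels are
#'   broadcast to member pixels); for `level = "fire"` the attribute
#'   `fire_means` carries the per-fire perimeter means.
#' @export
classifyForcing <- function(ledger, level = c("pixel", "fire"), fire = NULL) {
  level <- match.arg(level)
  cum <- cumulativeForcing(ledger, "mean")
  if (level == "pixel") return(ifelse(cum > 0, "warming", "cooling"))
  if (is.null(fire)) stop("fire-level classification needs fire identifiers")
  stopifnot(length(fire) == length(cum))
  means <- tapply(cum, fire, mean)
  lab <- ifelse(as.vector(means) > 0, "warming", "cooling")
  out <- lab[match(as.character(fire), names(means))]
  attr(out, "fire_means") <- setNames(as.vector(means), names(means))
  out
}

#' Two-group comparison of a ledger variable
#'
#' Welch's two-sided t test for continuous variables; two-sided Mann-Whitney U
#' test for ordinal/categorical variables (e.g. moisture class) and for the
#' forest-type net-impact contrast.
#'
#' @param x,y numeric values of the two groups (each n >= 2).
#' @param kind `"continuous"` (Welch) or `"ordinal"` (Mann-Whitney).
#' @return list of class `"GroupComparison"`: test name, statistic, two-sided
#'   `p`, per-group `mean`, `sd` and `n`.
#' @export
#' @examples
#' compareGroups(c(1, 2, 3), c(101, 102, 103))$p
compareGroups <- function(x, y, kind = c("continuous", "ordinal")) {
  kind <- match.arg(kind)
  if (length(x) < 2 || length(y) < 2) stop("both groups need at least 2 values")
  res <- if (kind == "continuous") {
    ht <- t.test(x, y, var.equal = FALSE)
    list(test = "Welch t", statistic = unname(ht$statistic), p = ht$p.value)
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
    list(test = "Mann-Whitney U", statistic = unname(ht$statistic),
         p = ht$p.value)
  }
  structure(c(res, list(mean = c(mean(x), mean(y)), sd = c(sd(x), sd(y)),
                        n = c(length(x), length(y)))),
            class = "GroupComparison")
}

#' Forcing trend with distance to the latitudinal treeline
#'
#' Bins pixels into non-overlapping distance intervals (default 50 km),
#' computes the bin means and fits ordinary least squares to them; the slope is
#' reported per 100 km with the two-sided t-test p value of the regression
#' coefficient.
#'
#' @param distance_km distance to the treeline per pixel, km (>= 0).
#' @param values forcing values per pixel (one component or the net).
#' @param bin_width bin width in km (default 50).
#' @return list of class `"TreelineTrend"`: `bins` (centre, mean, n),
#'   `slope_per_100km`, `p`; slope and p are NA with a warning when fewer than
#'   3 non-empty bins exist.
#' @export
treelineTrend <- function(distance_km, values, bin_width = 50) {
  stopifnot(length(distance_km) == length(values))
  keep <- is.finite(distance_km) & is.finite(values)
  d <- distance_km[keep]; v <- values[keep]
  idx <- floor(d / bin_width)
  centre <- tapply(rep(1, length(d)), idx, length)
  bins <- data.frame(centre = (as.numeric(names(centre)) + 0.5) * bin_width,
                     mean = as.numeric(tapply(v, idx, mean)),
                     n = as.integer(centre))
  bins <- bins[order(bins$centre), ]
  rownames(bins) <- NULL
  if (nrow(bins) < 3) {
    warning("fewer than 3 distance bins; trend undefined")
    return(structure(list(bins = bins, slope_per_100km = NA_real_, p = NA_real_),
                     class = "TreelineTrend"))
  }
  fit <- lm(mean ~ centre, data = bins)
  sm <- summary(fit)$coefficients
  structure(list(bins = bins,
                 slope_per_100km = unname(coef(fit)["centre"]) * 100,
                 p = unname(sm["centre", "Pr(>|t|)"])),
            class = "TreelineTrend")
}

#' Box-plot statistics of forcing by permafrost zone
#'
#' Median, mean, quartiles and whiskers at 1.5 times the interquartile range
#' for each permafrost zone; empty zones are omitted.
#'
#' @param values forcing values per pixel.
#' @param zone zone labels per pixel (isolated/sporadic/discontinuous/
#'   continuous/none).
#' @return data.frame with one row per non-empty zone.
#' @export
summarizeByZone <- function(values, zone) {
  stopifnot(length(values) == length(zone))
  zs <- intersect(c("none", "isolated", "sporadic", "discontinuous",
                    "continuous"), unique(zone))
  if (!length(zs)) zs <- sort(unique(zone))
  do.call(rbind, lapply(zs, function(z) {
    v <- values[zone == z & is.finite(values)]
    if (!length(v)) return(NULL)
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(zone = z, n = length(v), mean = mean(v), median = q[2],
               q25 = q[1], q75 = q[3],
               whisker_low = min(v[v >= q[1] - 1.5 * iqr]),
               whisker_high = max(v[v <= q[3] + 1.5 * iqr]))
  }))
}

#' Contrast near-pure evergreen and deciduous forest pixels
#'
#' Pixels with at least `threshold` (default 90 %) fractional cover of a type
#' are labelled; per-type mean component and net forcings are reported together
#' with the percentage of each type's pixels that warm or cool, the percentage
#' change of each component using evergreen forests as the baseline, and each
#' component's share of the absolute between-type difference (shares sum to
#' 100 %).
#'
#' @param ledger a [FireForcingLedger-class] whose rowData carries
#'   `frac_evergreen` and `frac_deciduous`.
#' @param threshold fractional-cover threshold for "near-pure" stands.
#' @return list of class `"ForestTypeContrast"`: `means` (type x component),
#'   `n`, `warming_share_pct`, `pct_change_vs_evergreen`,
#'   `contribution_share_pct`, and the Mann-Whitney comparison of net impacts.
#' @export
forestTypeContrast <- function(ledger, threshold = 0.90) {
  rd <- rowData(ledger)
  stopifnot(all(c("frac_evergreen", "frac_deciduous") %in% names(rd)))
  ever <- rd$frac_evergreen >= threshold
  decid <- rd$frac_deciduous >= threshold
  if (!any(ever) || !any(decid)) stop("no near-pure pixels of one of the types")
  comps <- forcingComponents(ledger)
  mean_by <- function(sel) {
    v <- vapply(comps, function(k) mean(rowMeans(componentForcing(ledger, k))[sel]),
                numeric(1))
    c(v, net = mean(cumulativeForcing(ledger, "mean")[sel]))
  }
  means <- rbind(evergreen = mean_by(ever), deciduous = mean_by(decid))
  cls <- classification(ledger)
  warming_share <- c(evergreen = 100 * mean(cls[ever] == "warming"),
                     deciduous = 100 * mean(cls[decid] == "warming"))
  base <- means["evergreen", comps]
  pct_change <- 100 * (means["deciduous", comps] - base) / abs(base)
  diffs <- abs(means["deciduous", comps] - base)
  contribution <- 100 * diffs / sum(diffs)
  mw <- compareGroups(cumulativeForcing(ledger, "mean")[ever],
                      cumulativeForcing(ledger, "mean")[decid],
                      kind = "ordinal")
  structure(list(means = means, n = c(evergreen = sum(ever),
                                      deciduous = sum(decid)),
                 warming_share_pct = warming_share,
                 pct_change_vs_evergreen = pct_change,
                 contribution_share_pct = contribution,
                 net_comparison = mw),
            class = "ForestTypeContrast")
}
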