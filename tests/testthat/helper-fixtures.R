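# Shared fixtures: the default parameter set (read once) and small builders.

PARAMS <- forcingParams()

smallConfig <- function(n = 200, seed = 1, ...) {
  syntheticConfig(n_pixels = n, seed = seed, ...)
}

# ledger with constant annual series at the given component means
constantLedger <- function(means, n_pixels = 1, covariates = NULL) {
  comps <- lapply(means, function(m) matrix(m, n_pixels, 70))
  netForcing(comps, covariates = covariates)
}

# feature table (fire grid + zonation index) used by the recovery models
featureTable <- function(land) {
  cbind(land$fires, zonation_index = land$permafrost$pixels$zonation_index)
}

# chronosequence with features merged in
albedoChrono <- function(land) {
  ch <- buildChronosequence(land$fires, land$observations$albedo, "albedo")
  ch$samples <- merge(ch$samples,
                      featureTable(land)[c("pixel_id", albedoFeatures())],
                      by = "pixel_id")
  ch
}

neeChrono <- function(land) {
  ch <- buildChronosequence(land$fires, land$observations$nee, "nee")
  ch$samples <- merge(ch$samples,
                      featureTable(land)[c("pixel_id", neeFeatures())],
                      by = "pixel_id")
  ch
}
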