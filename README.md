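# borealForcing

Boreal North American forest fires push climate in both directions: combustion
releases well-mixed greenhouse gases, ozone precursors and aerosols; burned
canopies expose spring snow and raise surface albedo for decades; regrowing
vegetation draws CO2 back down; and fire-driven thickening of the permafrost
active layer exposes old soil carbon to decomposition. `borealForcing`
implements a complete accounting framework for these five pathways, expressing
each as a 70-year annual radiative-forcing series in **W m⁻² of burned area**
(the global-mean forcing of a pixel's emissions rescaled by Earth surface area
over the pixel's burned area, so that emission-based and kernel-based
components are directly comparable). It is aimed at ecosystem and carbon-cycle
scientists who want to classify fires as climate-warming or climate-cooling
and dissect what drives the difference.

## The model in brief

For a pixel with combusted carbon `c` (kg C m⁻²):

- **Direct emissions.** Species masses follow `m_s = (c / f_C) · EF_s / 1000`
  with fuel carbon fraction `f_C` and emission factors `EF_s` (g per kg dry
  matter). CO2, CH4 and N2O become global mixing-ratio perturbations decayed
  by, respectively, a multi-exponential impulse response
  `a₀ + Σ aᵢ e^{−t/τᵢ}`, a fixed 12.4-year lifetime, and a burden-dependent
  N2O lifetime `τ(N) = τ_ref (N/N_ref)^s`. Forcing comes from simplified
  radiative expressions (logarithmic in CO2, square-root with band-overlap
  terms for CH4 and N2O) against an SSP2-4.5 background. Ozone forcing is
  linear in CO; NOx and NMVOC are converted to CH4-equivalent masses through
  GWP ratios; organic/black-carbon aerosol forcing (direct plus a configured
  indirect:direct ratio) is time-integrated at the 20-year horizon and
  assigned entirely to post-fire year 1.
- **Albedo.** A space-for-time chronosequence pairs historical burn years with
  dated albedo observations; one regressor per (calendar month, years since
  fire) cell predicts post-fire albedo, and Δα relative to the pre-fire
  monthly mean is converted to forcing with monthly radiative kernels:
  `F(y) = Σ_m K(m) · Δα(m, y)` (negative kernel convention).
- **Vegetation recovery.** Annual NEE models per post-fire year yield a
  fire-attributable uptake trajectory relative to a no-fire counterfactual;
  each year's uptake is a negative CO2 pulse evaluated against a background
  already perturbed by the fire's own emissions.
- **Permafrost thaw.** Active-layer deepening `ALT(t) = ALT₀ (1 + dALT(t))`
  exposes depth-interval SOC (uniform density within 0–30, 30–50, 50–100,
  100–200, 200–300 cm); exposed carbon decomposes along incubation-derived
  release curves, scaled by a frost-free-day seasonality factor and divided by
  the 2.93 lab-to-field factor, split 15.89 % CH4-C / 84.11 % CO2-C, weighted
  by the permafrost zonation index, and routed through the gas pathways.
- **Net forcing and classification.** The per-pixel net series is the exact
  component sum; a fire warms if its 70-year cumulative mean net forcing is
  positive (fire-level labels use the perimeter mean). Group contrasts use
  Welch's t and Mann-Whitney U tests; treeline trends use OLS on 50-km bin
  means.

All physical coefficients live in a versioned YAML file
(`inst/extdata/forcing_params.yaml`); the shipped values are clearly labelled
literature-plausible defaults, not a reproduction of any specific published
table. A synthetic-landscape generator (`syntheticConfig()`,
`genSyntheticLandscape()`) emulates all required inputs with known ground
truth, including combustion drawn from a normal with mean 3.13 and sd 1.20
kg C m⁻² truncated at zero.

## Worked example

```r
library(borealForcing)
cfg <- syntheticConfig(n_pixels = 500, seed = 42)
pp  <- runPipeline(cfg, years = 0:69)
pp$ledger
round(pp$summaries$component_means, 2)
```

```
FireForcingLedger: 500 burned pixels x 70 post-fire years
components: ghg_precursor, permafrost, albedo, aerosol, nee
net cumulative mean forcing: -1.437 W m-2 of burned area (mean)
classification: 150 warming (30.0%), 350 cooling

ghg_precursor    permafrost        albedo       aerosol           nee
         7.32          1.01         -5.86         -3.63         -0.28
          net
        -1.44
```

Direct greenhouse-gas and precursor emissions warm (+7.32 W m⁻² of burned
area, 70-year mean), permafrost thaw adds +1.01, and the albedo increase
(−5.86), aerosols (−3.63) and vegetation recovery (−0.28) cool, for a net
cooling of −1.44 with 30 % of pixels classified climate-warming. Dropping the
permafrost component (`pp$summaries$net_without_permafrost`) deepens the
cooling to −2.45. Per-zone permafrost forcing rises monotonically from
isolated (0.13) through sporadic (0.73) and discontinuous (1.55) to continuous
permafrost (2.30), and warming-classified fires combust more carbon than
cooling ones (3.9 vs 2.8 kg C m⁻², Welch p ≈ 9e-25) — the structural patterns
the framework is designed to expose.

`writeLedgerOutputs(pp$ledger, "out/", cfg)` writes the pixel table, the long
net-forcing series and a JSON run manifest (seed, config hash).

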