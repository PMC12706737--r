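# pcbair

Source attribution of airborne polychlorinated biphenyls (PCBs) around
contaminated harbors. The package asks a single question end to end: **can
volatilization from a harbor's water column explain the PCB concentrations
measured in the surrounding community's air?** It is aimed at environmental
fate modelers and exposure scientists working with congener-resolved PCB
data: dissolved water concentrations from monitoring programs, passive air
sampler (PUF–PAS) campaigns, and routine surface meteorology.

## What it computes

**Air–water exchange.** Congener-specific volatilization flux follows the
gradient-flux law

    F_i = v_aw,i · C_w,i

with `C_w,i` the truly dissolved concentration (pg L⁻¹ ≡ ng m⁻³) and the
overall transfer velocity from the Whitman two-film model,

    1 / v_aw,i = 1 / k_w,i + 1 / (k_a,i · H'_i(T)) ,

where `k_w,i` is a quadratic wind-speed gas-exchange velocity scaled by
`(Sc_i/600)^-1/2` (Hayduk–Laudie aqueous diffusivity), `k_a,i` a linear
wind-speed water-vapor velocity scaled by a Fuller diffusivity ratio to the
0.61 power, and `H'` the dimensionless Henry's law constant adjusted to the
water temperature by the van 't Hoff relation. Velocities are computed
hourly and averaged. All coefficients are explicit in `flux_config()` and
replaceable. A seeded Monte Carlo (`monte_carlo_flux()`) propagates
concentration, Henry constant, and meteorology uncertainty.

**Dispersion.** Fluxes over the water surface become area emissions
(`emissions_from_flux()`), and a steady-state Gaussian plume area-source
model (Pasquill–Gifford–Turner stability, Briggs urban/rural sigmas,
reflected ground-source kernel) predicts period-average concentrations at
receptors (`period_average()`).

**Passive sampling.** PUF–PAS sorbed masses invert to airborne
concentrations via effective volumes
`Veff = K'·v_puf·(1 − exp(−Rs·t/(K'·v_puf)))`, with site-specific sampling
rates `Rs` from depuration-compound loss (valid only for 20–80% loss),
surrogate recovery correction, and a blank-based limit of quantification
(upper one-sided 99% confidence limit of log₁₀ blank masses).

**Statistics.** Congener-profile cosine similarity against Aroclor
references, distance-decay regression on log₁₀ distance, Moran's I with
permutation inference, ordinary kriging with leave-one-out cross-validation,
and Wilcoxon rank-sum comparison of near-water vs. far sites.

**Synthetic study.** `generate_water_samples()`, `generate_met()` and
`generate_puf_dataset()` emulate the study conditions (21 water samples at 7
sites, totals 80–184 pg L⁻¹ dominated ~48% by the silicone-byproduct peaks
PCB 44+47+65, 45+51, 68; August meteorology with 23 °C daily mean and winds
in 3.60–8.80 m s⁻¹ about a third of hours; 28 PUF deployments of 40 days
with 25 ng depuration spikes), so the whole pipeline runs with no downloads.

The shipped congener property table and Aroclor 1016/1242 profiles are
**synthetic compilations** (homolog-level correlations; see
`?default_congener_table`); substitute measured tables with
`load_congener_table()` / `load_aroclor_profile()` for site work.

## Worked example

```r
library(pcbair)

props <- default_congener_table()
cfg   <- synthetic_config(seed = 1)
met   <- generate_met(cfg)
water <- generate_water_samples(cfg, props)

worst <- select_worst_case(water, 3)      # mean of the 3 highest-total samples
conc  <- worst / sum(worst) * 132         # scale to a 132 pg/L worst-case total
fl    <- compute_fluxes(conc, met, props)
attr(fl, "total_flux")
#> [1] 58.23316
sum(fl$emission)                          # g/s over the 15 km2 water surface
#> [1] 1.010992e-05

res <- run_pipeline(pipeline_config(seed = 1, mc_iter = 0), verbose = FALSE)
round(exp(mean(log(res$measured$sigma_pcb))))    # geometric mean measured air
#> [1] 428
round(res$stats$regression$r2, 2)                # distance-decay R2
#> [1] 0.57
round(res$profiles$cos_air_water, 2)             # air vs water profile cos
#> [1] 0.44
signif(attr(res$attribution, "mean_ratio"), 2)   # predicted / measured
#> [1] 0.0026
```

Read: the worst-case two-film ΣPCB flux is ~58 ng m⁻² d⁻¹ (≈ 1.0 × 10⁻⁵ g/s
over the harbor); the synthetic community air averages ~430 pg m⁻³ with a
clear distance decay, its congener profile matches an Aroclor mixture rather
than the silicone-dominated water, and water-driven plume predictions are a
fraction of a percent of "measured" air — the structural conclusion that the
water is a minor source of the airborne burden.

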