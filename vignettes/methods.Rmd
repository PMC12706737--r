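---
title: "Models and methods in pcbair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pcbair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcbair)
```

pcbair chains four physical models — air–water exchange, area-source
dispersion, passive-sampler uptake, and spatial/profile statistics — into a
source-attribution pipeline for airborne PCBs around a contaminated harbor.
This vignette documents each model's assumptions, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where the design was genuinely open.

## Congener properties

All 209 PCB congeners are handled in 173 chromatographic peaks; coeluting
congeners are quantified together. Every downstream module reads
physicochemical constants only through a `congener_table`, so the property
source can be swapped in one place. Each peak carries the property values of
its **lowest-numbered member congener** — a deterministic convention chosen
because the measurement cannot apportion a peak among its members; any other
fixed representative would serve equally and can be expressed by editing the
table.

The shipped table is a *synthetic compilation*: exact molecular weights
(biphenyl + 34.445 g/mol per chlorine), LeBas molar volumes
(184.6 + 20.9 · n~Cl~ cm³/mol), and Henry's law constants, transfer energies
(ΔU~aw~, ΔU~OA~) and log K~OA~ generated from smooth homolog trends with a
small deterministic within-homolog spread. These reproduce the magnitudes
and homolog ordering of published compilations but are not measured values —
passing tests demonstrate the machinery, not congener-specific accuracy. For
site work, supply a measured table via `load_congener_table()`. The Aroclor
1016/1242 reference profiles are likewise synthetic reconstructions from
homolog mass distributions and should be replaced with a preferred published
compilation when profile matching matters quantitatively.

Temperature adjustment of the Henry's law constant uses the van 't Hoff
form, `H(T) = H298 · exp((ΔU_aw/R)(1/298.15 − 1/T))`, and the dimensionless
constant is `H' = H/(RT)` evaluated at the water temperature.

## Two-film volatilization flux

Flux is gross volatilization, `F_i = v_aw,i · C_w,i`: there is no
atmospheric back-partitioning term, so flux is nonnegative by construction
and will overestimate net exchange wherever gas-phase concentrations are
appreciable relative to Henry's law equilibrium. The input concentration
must already be the *truly dissolved* fraction; no particle/DOC partitioning
correction is applied.

The overall velocity composes two film resistances in series,
`1/v = 1/k_w + 1/(k_a · H')`. Defaults (all in `flux_config()`, all
replaceable):

| parameter | default | units | role |
|---|---|---|---|
| `kw_a`, `kw_b`, `kw_c` | 0.222, 0.333, 0 | cm/h on u₁₀ (m/s) | quadratic water-side reference velocity (dual-tracer parameterization at Sc = 600) |
| `sc_ref`, `sc_exp` | 600, −0.5 | — | Schmidt-number scaling of the water film |
| `ka_slope`, `ka_intercept` | 0.2, 0.3 | cm/s on u₁₀ | air-side water-vapor velocity |
| `d_exp` | 0.61 | — | diffusivity-ratio exponent of the air film |
| `area` | 1.5 × 10⁷ | m² | water surface for emissions |
| `worst_case_k` | 3 | — | highest-total samples averaged for the worst case |

Aqueous diffusivity comes from the Hayduk–Laudie molar-volume correlation
with Vogel-equation water viscosity (this supplies the temperature scaling of
the Schmidt number); the air-side diffusivity ratio to water vapor uses a
Fuller-type correlation in which temperature cancels. Because the wind
dependence is nonlinear, velocities are computed **hourly and then
averaged**, never from period-averaged meteorology.

Under the default summer meteorology (mean wind ≈ 3.1 m/s) these defaults
give ΣPCB transfer velocities around 0.4–0.5 m/d, the magnitude typical of
published two-film estimates for semivolatile organochlorines at moderate
winds. Site calibrations that imply substantially faster exchange can be
expressed by swapping the coefficient set in `flux_config()`; the package
deliberately does not hard-code any such calibration.

The Monte Carlo stage perturbs per-peak concentrations (lognormal,
`sdlog_conc = 0.3`, matching the generator's replicate spread), Henry's law
constants (lognormal, `sdlog_henry = 0.2`, i.e. about ±20%), and
bootstrap-resamples the meteorology hours. With every spread set to zero it
reproduces the deterministic flux exactly, which the tests assert. The
acceptance script runs 2,000 iterations — the total-flux mean and sd are
stable to well under a percent at that size — while `n_iter = 10000` remains
the function default for production use.

## Gaussian plume dispersion

The dispersion stage is a deliberately desk-scale steady-state model: the
source polygon is discretized into ground-level cells (default 250 m), each
contributing the reflected Gaussian kernel
`Q/(π σy σz u) · exp(−y²/2σy²) · exp(−z²/2σz²)`, with Pasquill–Gifford–Turner
stability classes from wind speed and an hour-of-day insolation proxy, and
Briggs urban (default) or rural dispersion coefficients. Period averages are
taken over all non-calm hours at a constant emission rate.

Numerical choices:

* **Calm threshold 0.5 m/s** — the kernel diverges as u → 0; calm hours are
  excluded and counted in the run QC.
* **Split stability classes** of the classical lookup (A–B, B–C, C–D) are
  resolved toward the less stable member; clear nights are F below 3 m/s, E
  to 5 m/s, D above; overcast is always D. The lookup is deterministic.
* **Self-cell singularities**: receptor–cell pairs closer downwind than half
  a cell are evaluated at half a cell; upwind cells contribute nothing.
* **Cell size**: at 250 m the tests require halving the cell to change
  receptor concentrations by < 2% (grid convergence); the included geometry
  satisfies this for receptors beyond ~1 km.

Assumptions inherited from the formulation: flat terrain, no building
downwash, no deposition or decay, straight steady hourly transport. These
make predictions order-of-magnitude tools, appropriate for asking whether a
water source *could* explain observed air, not for regulatory concentration
estimates.

## PUF–PAS inversion

Sorbed mass inverts to concentration through the effective volume
`Veff = K'·v_puf·(1 − exp(−Rs·t/(K'·v_puf)))`, linear uptake at short times
and saturating at the equilibrium capacity. The PUF–air partition capacity
uses the linear free-energy relation `log10 K_PUF (m³/g) = −3.1774 +
0.6366 · log10 K_OA` with PUF density 0.021 g/cm³ and disk volume
2.1 × 10⁻⁴ m³; K~OA~ is temperature-adjusted through ΔU~OA~. All constants
sit in `puf_config()`.

Site-specific sampling rates come from depuration compounds (¹³C-labelled
congeners 28, 111, 178 spiked at 25 ng): fractional loss f gives
`Rs = −ln(1−f)·K'_DC·v_puf/t`, accepted only for 20% ≤ f ≤ 80%. Outside
that window the estimate is returned but flagged, and the inversion falls
back to a configured model rate (default 4.9 m³/d). With the default
properties only the congener-28 spike depurates into the valid window over a
40-day deployment — heavier spikes retain essentially all mass — which is
exactly why multiple DCs spanning volatility are spiked in practice.

Quality handling: masses are divided by the surrogate recovery only when
recovery is below 100% (recoveries above 100% are measurement artifacts and
correct nothing); the limit of quantification per peak is the back-transformed
**upper one-sided 99% confidence limit of the mean** log₁₀ blank mass. The
phrase "99% confidence interval of the blanks" is ambiguous between a
confidence and a prediction interval — the CI was chosen as the stricter
reading of "uncertainty in the mean blank signal" and the level is a config
parameter. Below-LOQ peaks contribute **zero** to ΣPCB and are flagged;
substituting LOQ/2 is a one-line change on the flagged output if a censoring
convention is preferred.

## Spatial and profile statistics

* **Distance decay**: OLS of concentration on log₁₀ distance to the water
  (`stats::lm`); r² is defined as 0 for a constant response. Distance to
  water is the receptor's minimum distance to the source polygon boundary in
  the synthetic geometry; with user data any distance column can be supplied.
* **Moran's I**: row-standardized inverse-distance weights by default (no
  cutoff), expectation −1/(n−1), two-sided permutation p. Coincident points
  are an error rather than silently jittered.
* **Ordinary kriging**: binned method-of-moments semivariogram, exponential
  model fitted by weighted least squares with Cressie weights, multi-start
  optimization. The range is bounded by the largest binned lag and the sill
  by three times the empirical maximum: beyond those bounds an exponential is
  indistinguishable from a linear ramp and the parameters are unidentified.
  Kriging weights carry the unbiasedness constraint (they sum to one, which
  the tests assert), predictions at data locations are exact at zero nugget,
  and a constant field short-circuits to the constant (its kriging system is
  singular). Accuracy is reported as leave-one-out r² and RMSE.
* **Rank-sum**: `stats::wilcox.test`, exact enumeration for combined n ≤ 12
  without ties, normal approximation with tie and continuity correction
  otherwise.
* **Cosine similarity** on nonnegative profiles lies in [0, 1]; profiles on
  different peak sets are intersected and renormalized with a warning.
  Reference profiles are regridded to the 173-peak measurement basis by
  summing constituent congeners.

A note on variogram parameter recovery: a single realization of an
exponential random field at n = 100 determines its range only to within
roughly ±40–50%. The recovery tests therefore judge the **median of 24
replicate estimates**, which is stable to ~±13% across arbitrary seed
windows; single-realization fits should be interpreted with that spread in
mind.

## The synthetic study

`synthetic_config()` fixes the emulated conditions: 21 water samples at 7
sites with uniform totals in 80–184 pg/L, profiles mixing a
silicone-byproduct component (peaks 44+47+65, 45+51, 68; expected share
0.48) with a light-Aroclor background under lognormal per-peak noise
(sdlog 0.3 — the within-site spread is not constrained by public summaries,
so it is an explicit knob); 40 days of hourly meteorology with a sinusoidal
diurnal cycle around a 23 °C daily mean, water temperature as a 24-h moving
average of air temperature, and Weibull (shape 2) winds whose scale is
calibrated by root finding so that 33% of hours fall in 3.60–8.80 m/s (the
lower of the two roots — realistic surface winds, not the storm regime);
28 PUF deployments of 40 days (two sites in triplicate, five field blanks)
with 25 ng depuration spikes, truncated-normal surrogate recoveries
(0.88 ± 0.13 on (0, 1.5]), and lognormal mass noise (sdlog 0.2).

In the pipeline, the synthetic "measured" air is the plume prediction plus a
non-water background source with an Aroclor 1242 profile and a power-law
distance decay (600 pg/m³ at 100 m, exponent 0.35, lognormal site spread
0.4) — chosen so that measured totals sit in the few-hundred pg/m³ range
with a near/far contrast of roughly 4×. True sampling rates are lognormal
(median 3.2 m³/d, sdlog 0.6, clamped to 0.5–10 m³/d), spanning the spread a
depuration-compound method typically reports.

What the generator does **not** emulate: instrument response and
chromatographic artifacts, storm-event concentration dynamics, wind-direction
persistence (hours are independent draws), within-deployment temperature
trends, and spatially correlated micrometeorology at sheltered sites.
Passing tests therefore demonstrate correctness of the computational chain
and its statistical behavior under the stated model, not field accuracy.

## Reproducibility and problem sizes

Every stochastic stage takes an explicit integer seed; `run_pipeline()`
reruns byte-identically under the same seed (the manifest's timestamp aside)
and writes a manifest with the config hash, seed, and package version. The
test suite and `scripts/acceptance.R` use desk-scale problem sizes chosen as
adequate for the quantities they check: 960 meteorology hours, 250 m source
cells (with a 125 m convergence check), 1,000–2,000 Monte Carlo iterations,
999 Moran permutations, and 24 variogram-recovery replicates.

## Known limitations

* Gross (not net) volatilization; no sediment–water exchange; no deposition.
* The plume stand-in omits boundary-layer similarity theory, terrain, and
  downwash; agreement with a regulatory dispersion model is expected only at
  the order-of-magnitude level.
* Shipped property and reference tables are synthetic compilations intended
  as replaceable defaults.
* The two-film coefficient set is a modeling choice; transfer velocities —
  and hence fluxes and emissions — scale with it. Conclusions should be
  checked against at least one alternative parameterization via
  `flux_config()`.
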