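# Congener-specific air-water exchange: two-film transfer velocities,
# volatilization fluxes (gradient-flux law), area emissions, Monte Carlo
# uncertainty.

#' Configuration for the two-film flux model
#'
#' All gas-exchange coefficients are explicit and replaceable. Defaults:
#' water-side reference velocity (Schmidt number 600) quadratic in 10-m wind,
#' `k_ref = 0.222 u^2 + 0.333 u` cm/h (dual-tracer parameterization), scaled
#' by `(Sc_i/600)^-1/2` with aqueous diffusivity from the Hayduk-Laudie
#' molar-volume correlation and water viscosity from the Vogel equation;
#' air-side water-vapor velocity linear in wind, `k_a,H2O = 0.2 u + 0.3` cm/s,
#' scaled by the Fuller diffusivity ratio to the power 0.61.
#'
#' @param kw_a,kw_b,kw_c Quadratic water-side coefficients (cm/h on u10 m/s).
#' @param sc_ref Reference Schmidt number of the water-side parameterization.
#' @param sc_exp Schmidt-number exponent (water side).
#' @param ka_slope,ka_intercept Air-side water-vapor velocity (cm/s on u10).
#' @param d_exp Diffusivity-ratio exponent (air side).
#' @param area Water surface area for emissions, m2 (default 1.5e7, i.e.
#'   15 km2 of harbor water).
#' @param worst_case_k Number of highest-total samples averaged for the
#'   worst-case water concentration (default 3).
#' @return A list of class `flux_config`.
#' @export
flux_config <- function(kw_a = 0.222, kw_b = 0.333, kw_c = 0,
                        sc_ref = 600, sc_exp = -0.5,
                        ka_slope = 0.2, ka_intercept = 0.3, d_exp = 0.61,
                        area = 1.5e7, worst_case_k = 3) {
  structure(list(kw_a = kw_a, kw_b = kw_b, kw_c = kw_c, sc_ref = sc_ref,
                 sc_exp = sc_exp, ka_slope = ka_slope,
                 ka_intercept = ka_intercept, d_exp = d_exp, area = area,
                 worst_case_k = worst_case_k),
            class = "flux_config")
}

# dynamic viscosity of water, Pa s (Vogel equation), T in Kelvin
water_viscosity <- function(t_k) 2.414e-5 * 10^(247.8 / (t_k - 140))

# aqueous diffusivity, cm2/s (Hayduk-Laudie), molar volume cm3/mol
diffusivity_water <- function(molar_volume, t_k) {
  eta_cp <- water_viscosity(t_k) * 1000
  13.26e-5 / (eta_cp^1.14 * molar_volume^0.589)
}

# Schmidt number in water: kinematic viscosity / diffusivity
schmidt_water <- function(molar_volume, t_k) {
  nu_cm2s <- water_viscosity(t_k) / 998 * 1e4
  nu_cm2s / diffusivity_water(molar_volume, t_k)
}

# Fuller-type gas diffusivity ratio D_i / D_H2O (temperature cancels)
air_diffusivity_ratio <- function(mw, molar_volume) {
  f <- function(m, v) sqrt(1 / 28.97 + 1 / m) / (v^(1 / 3) + 19.7^(1 / 3))^2
  f(mw, molar_volume) / f(18.02, 12.7)
}

#' Water-side film transfer velocity
#'
#' `k_w = k_ref(u10) * (Sc_i / sc_ref)^sc_exp` in m/d, with `k_ref` the
#' configured quadratic wind parameterization (cm/h) and `Sc_i` the congener
#' Schmidt number at the water temperature.
#'
#' @param rec One-row `congener_table` (needs `molar_volume`).
#' @param met Data frame with columns `u10` (m/s) and `t_water` (deg C);
#'   vectorised over rows.
#' @param config A [flux_config()].
#' @return Water-side velocity, m/d.
#' @export
water_side_velocity <- function(rec, met, config = flux_config()) {
  if (any(met$u10 < 0)) stop("u10 must be nonnegative")
  if (is.null(rec$molar_volume) || !is.finite(rec$molar_volume)) {
    stop("missing molar volume for peak ", rec$peak_id)
  }
  t_k <- met$t_water + 273.15
  k_ref_cmh <- config$kw_a * met$u10^2 + config$kw_b * met$u10 + config$kw_c
  sc <- schmidt_water(rec$molar_volume, t_k)
  k_ref_cmh * (sc / config$sc_ref)^config$sc_exp * 0.24  # cm/h -> m/d
}

#' Air-side film transfer velocity
#'
#' `k_a = k_a,H2O(u10) * (D_i / D_H2O)^d_exp` in m/d, with `k_a,H2O` the
#' configured linear wind correlation (cm/s) and the diffusivity ratio from a
#' Fuller-type molar-volume correlation.
#'
#' @inheritParams water_side_velocity
#' @return Air-side velocity, m/d.
#' @export
air_side_velocity <- function(rec, met, config = flux_config()) {
  if (any(met$u10 < 0)) stop("u10 must be nonnegative")
  if (is.null(rec$molar_volume) || !is.finite(rec$molar_volume)) {
    stop("missing molar volume for peak ", rec$peak_id)
  }
  ka_h2o_cms <- config$ka_slope * met$u10 + config$ka_intercept
  dr <- air_diffusivity_ratio(rec$mw, rec$molar_volume)
  ka_h2o_cms * dr^config$d_exp * 864  # cm/s -> m/d
}

#' Overall air-water mass transfer coefficient
#'
#' Two-film resistances in series:
#' `1/V = 1/k_w + 1/(k_a * H')`.
#'
#' @param k_w Water-side velocity, m/d (> 0).
#' @param k_a Air-side velocity, m/d (> 0).
#' @param h_prime Dimensionless Henry's law constant (> 0).
#' @return Overall transfer velocity, m/d; always below `min(k_w, k_a h')`.
#' @examples
#' overall_mtc(3, 500, 0.01)  # 1/(1/3 + 1/5) = 1.875
#' @export
overall_mtc <- function(k_w, k_a, h_prime) {
  if (any(k_w <= 0) || any(k_a <= 0) || any(h_prime <= 0)) {
    stop("k_w, k_a and h_prime must be positive")
  }
  1 / (1 / k_w + 1 / (k_a * h_prime))
}

# per-peak x per-hour matrices of the two film conductances
velocity_components <- function(props, met, config = flux_config()) {
  t_wk <- met$t_water + 273.15
  u <- met$u10
  k_ref_cmh <- config$kw_a * u^2 + config$kw_b * u + config$kw_c
  nu_cm2s <- water_viscosity(t_wk) / 998 * 1e4
  eta_cp <- water_viscosity(t_wk) * 1000
  # Sc matrix: peaks x hours
  dw <- outer(props$molar_volume^0.589, eta_cp^1.14,
              function(v, e) 13.26e-5 / (e * v))
  sc <- sweep(1 / dw, 2, nu_cm2s, "*")
  k_w <- sweep((sc / config$sc_ref)^config$sc_exp, 2, k_ref_cmh * 0.24, "*")
  ka_h2o <- (config$ka_slope * u + config$ka_intercept) * 864
  dr <- air_diffusivity_ratio(props$mw, props$molar_volume)^config$d_exp
  k_a <- outer(dr, ka_h2o)
  h_t <- outer(props$h298, rep(1, length(t_wk))) *
    exp(outer(props$du_aw / 8.314, 1 / 298.15 - 1 / t_wk))
  h_prime <- sweep(h_t, 2, 8.314 * t_wk, "/")
  list(k_w = k_w, ka_h = k_a * h_prime)
}

#' Per-peak transfer velocities averaged over a meteorology record
#'
#' Velocities are computed hourly (the wind dependence is nonlinear) and then
#' averaged over the record.
#'
#' @param props A `congener_table`.
#' @param met Hourly meteorology data frame (`u10`, `t_water` deg C).
#' @param config A [flux_config()].
#' @return Named vector of overall transfer velocities (m/d), one per peak.
#' @export
transfer_velocity <- function(props, met, config = flux_config()) {
  vc <- velocity_components(props, met, config)
  v <- 1 / (1 / vc$k_w + 1 / vc$ka_h)
  stats::setNames(rowMeans(v), props$peak_id)
}

#' Volatilization flux from the gradient-flux law
#'
#' `F = V * C`, with the dissolved concentration in pg/L read as ng/m3
#' (numerically identical), giving flux in ng m-2 d-1. Gross volatilization:
#' no atmospheric back-partitioning term.
#'
#' @param v_aw Overall transfer velocity, m/d (>= 0).
#' @param c_w Truly dissolved water concentration, pg/L (>= 0).
#' @return Flux, ng m-2 d-1.
#' @export
congener_flux <- function(v_aw, c_w) {
  if (any(v_aw < 0) || any(c_w < 0)) stop("v_aw and c_w must be nonnegative")
  v_aw * c_w
}

#' Worst-case water concentration: mean of the highest-total samples
#'
#' Ranks samples by total (sum over peaks) dissolved concentration and
#' averages the top `k` per peak.
#'
#' @param samples Water-sample data frame: metadata columns plus one numeric
#'   column per peak (pg/L).
#' @param k Number of highest samples to average (default 3).
#' @return Named per-peak mean concentration vector (pg/L), with attribute
#'   `sites` naming the selected samples' sites.
#' @export
select_worst_case <- function(samples, k = 3) {
  pk <- peak_columns(samples)
  if (nrow(samples) < k) stop("need at least k = ", k, " samples")
  totals <- rowSums(samples[, pk, drop = FALSE])
  top <- order(totals, decreasing = TRUE)[seq_len(k)]
  out <- colMeans(samples[top, pk, drop = FALSE])
  if (!is.null(samples$site)) attr(out, "sites") <- samples$site[top]
  out
}

# numeric per-peak columns of a wide samples table
peak_columns <- function(df) {
  meta <- c("site", "date", "flow_regime", "sample_id", "lat", "lon",
            "x", "y", "height", "t_start", "t_end")
  setdiff(names(df)[vapply(df, is.numeric, TRUE)], meta)
}

#' Convert a flux over a water surface to an emission rate
#'
#' `E = F * area` with ng -> g and d -> s conversions.
#'
#' @param flux Flux, ng m-2 d-1.
#' @param area Water surface area, m2 (> 0).
#' @return Emission rate, g/s.
#' @examples
#' emissions_from_flux(450, 15e6)  # 7.8e-5 g/s
#' @export
emissions_from_flux <- function(flux, area) {
  if (any(area <= 0)) stop("area must be positive")
  if (any(flux < 0)) stop("flux must be nonnegative")
  flux * area * 1e-9 / 86400
}

#' Deterministic congener-specific flux table
#'
#' Combines hourly-averaged two-film velocities with a per-peak dissolved
#' concentration into fluxes and area emissions.
#'
#' @param conc Named per-peak dissolved concentration (pg/L), e.g. from
#'   [select_worst_case()].
#' @param met Hourly meteorology data frame.
#' @param props A `congener_table`.
#' @param config A [flux_config()].
#' @return Data frame with `peak_id`, `v_aw` (m/d), `conc` (pg/L), `flux`
#'   (ng m-2 d-1), `emission` (g/s); total flux as attribute `total_flux`.
#' @export
compute_fluxes <- function(conc, met, props, config = flux_config()) {
  v <- transfer_velocity(props, met, config)
  conc <- conc[props$peak_id]
  conc[is.na(conc)] <- 0
  fl <- congener_flux(v, as.numeric(conc))
  out <- data.frame(
    peak_id = props$peak_id,
    v_aw = as.numeric(v),
    conc = as.numeric(conc),
    flux = as.numeric(fl),
    emission = emissions_from_flux(as.numeric(fl), config$area),
    stringsAsFactors = FALSE
  )
  attr(out, "total_flux") <- sum(out$flux)
  out
}

#' Monte Carlo uncertainty for congener-specific fluxes
#'
#' Resamples the inputs and propagates them through the two-film model:
#' per-peak concentrations perturbed by lognormal factors (`sdlog_conc`),
#' Henry's law constants by lognormal factors (`sdlog_henry`, default 0.2,
#' i.e. about +-20%), and meteorology hours bootstrap-resampled
#' (`resample_met`).
#'
#' @inheritParams compute_fluxes
#' @param n_iter Number of iterations (>= 100; default 10000).
#' @param seed Integer seed (required for reproducibility).
#' @param sdlog_conc Lognormal sigma for concentration perturbation.
#' @param sdlog_henry Lognormal sigma for the Henry constant perturbation.
#' @param resample_met Bootstrap the meteorology hours per iteration.
#' @return List with `per_peak` (data frame `peak_id`, `mc_mean`, `mc_sd`, in
#'   ng m-2 d-1), `total_mean`, `total_sd`, and `n_iter`.
#' @export
monte_carlo_flux <- function(conc, met, props, n_iter = 10000, seed,
                             config = flux_config(), sdlog_conc = 0.3,
                             sdlog_henry = 0.2, resample_met = TRUE) {
  if (n_iter < 100) stop("n_iter must be >= 100 for a stable sd")
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  conc <- conc[props$peak_id]
  conc[is.na(conc)] <- 0
  conc <- as.numeric(conc)
  vc <- velocity_components(props, met, config)
  inv_kw <- 1 / vc$k_w
  ka_h <- vc$ka_h
  np <- nrow(props); nh <- ncol(ka_h)
  totals <- numeric(n_iter)
  mean_pp <- numeric(np); m2_pp <- numeric(np)
  for (i in seq_len(n_iter)) {
    idx <- if (resample_met) sample.int(nh, nh, replace = TRUE) else seq_len(nh)
    fh <- if (sdlog_henry > 0) exp(stats::rnorm(np, 0, sdlog_henry)) else rep(1, np)
    v <- 1 / (inv_kw[, idx, drop = FALSE] +
                1 / (ka_h[, idx, drop = FALSE] * fh))
    fc <- if (sdlog_conc > 0) exp(stats::rnorm(np, 0, sdlog_conc)) else rep(1, np)
    flux_pp <- rowMeans(v) * conc * fc
    totals[i] <- sum(flux_pp)
    d <- flux_pp - mean_pp
    mean_pp <- mean_pp + d / i
    m2_pp <- m2_pp + d * (flux_pp - mean_pp)
  }
  sd_pp <- sqrt(m2_pp / (n_iter - 1))
  list(
    per_peak = data.frame(peak_id = props$peak_id, mc_mean = mean_pp,
                          mc_sd = sd_pp, stringsAsFactors = FALSE),
    total_mean = mean(totals),
    total_sd = stats::sd(totals),
    n_iter = n_iter
  )
}
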