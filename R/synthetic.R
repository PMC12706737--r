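# Synthetic study generator: harbor water monitoring samples, summer
# meteorology, and a PUF-PAS field campaign with the statistical structure
# the analysis assumes, so the full pipeline runs with no external data.

#' Configuration of the synthetic study
#'
#' Defaults emulate the study conditions: 21 water samples at 7 sites with
#' totals of 80-184 pg/L dominated (about 48%) by the silicone-byproduct
#' peaks PCB 44+47+65, 45+51 and 68; August meteorology with a daily mean of
#' 23 deg C and winds inside 3.60-8.80 m/s about a third of hours; 28 PUF
#' deployments of 40 days spiked with 25 ng of depuration compounds; 5 field
#' blanks; 2 sites in triplicate.
#'
#' @param seed Integer seed; the same seed reproduces every generated table.
#' @param n_water_samples,n_sites Water sampling design.
#' @param total_conc_range Range of per-sample total dissolved PCB, pg/L.
#' @param silicone_fraction Expected mass share of the silicone-byproduct
#'   peaks in water.
#' @param met_start,met_end Meteorology period (Date or string); the default
#'   spans the 40-day deployment.
#' @param mean_daily_temp Daily mean air temperature, deg C.
#' @param diurnal_amplitude Half-range of the sinusoidal diurnal cycle, deg C.
#' @param daily_temp_sd Day-to-day temperature anomaly sd, deg C.
#' @param wind_band,wind_band_freq Wind-speed band (m/s) and the target
#'   fraction of hours inside it.
#' @param wind_shape Weibull shape of the hourly wind distribution
#'   (2 = Rayleigh-like).
#' @param n_pufs,deployment_days,dc_spike PUF campaign design (spike in ng).
#' @param n_blanks Number of field blanks.
#' @param water_noise_sdlog Lognormal sigma of per-peak water concentration
#'   noise.
#' @param puf_noise_sdlog Lognormal sigma of sorbed-mass noise.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, n_water_samples = 21, n_sites = 7,
                             total_conc_range = c(80, 184),
                             silicone_fraction = 0.48,
                             met_start = "2018-08-01", met_end = "2018-09-10",
                             mean_daily_temp = 23, diurnal_amplitude = 5,
                             daily_temp_sd = 1.2,
                             wind_band = c(3.60, 8.80), wind_band_freq = 0.33,
                             wind_shape = 2, n_pufs = 28,
                             deployment_days = 40, dc_spike = 25,
                             n_blanks = 5, water_noise_sdlog = 0.3,
                             puf_noise_sdlog = 0.2) {
  stopifnot(total_conc_range[2] > total_conc_range[1],
            silicone_fraction >= 0, silicone_fraction <= 1,
            wind_band[2] > wind_band[1],
            wind_band_freq >= 0, wind_band_freq <= 1)
  structure(as.list(environment()), class = "synthetic_config")
}

# Weibull scale whose band probability matches the target (lower root:
# realistic surface winds rather than the storm-regime upper root)
calibrate_wind_scale <- function(band, target, shape) {
  g <- function(l) {
    stats::pweibull(band[2], shape, l) - stats::pweibull(band[1], shape, l)
  }
  peak <- stats::optimize(g, c(0.01, 100), maximum = TRUE)
  if (target > peak$objective) {
    stop("wind band frequency ", target, " unattainable (max ",
         round(peak$objective, 3), " for shape ", shape, ")")
  }
  if (target <= 0) return(band[1] / 10)
  stats::uniroot(function(l) g(l) - target, c(1e-3, peak$maximum))$root
}

#' Generate hourly synthetic meteorology
#'
#' Sinusoidal diurnal air temperature (afternoon peak) around the stated
#' daily mean with day-to-day anomalies; water temperature as a 24-h moving
#' average of air temperature; hourly Weibull wind speeds with the scale
#' calibrated by root finding so the expected fraction of hours inside the
#' wind band matches the target; wind direction concentrated around
#' northwest; near-constant pressure.
#'
#' @param cfg A [synthetic_config()].
#' @return Data frame with `timestamp`, `u10` (m/s), `wdir` (deg from),
#'   `t_air`, `t_water` (deg C), `pressure` (kPa).
#' @export
generate_met <- function(cfg = synthetic_config()) {
  t0 <- as.POSIXct(paste(cfg$met_start, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(cfg$met_end, "00:00:00"), tz = "UTC")
  n <- as.numeric(difftime(t1, t0, units = "hours"))
  if (n <= 0) stop("met_end must be after met_start")
  set.seed(cfg$seed + 1L)
  ts <- t0 + (seq_len(n) - 1) * 3600
  hour <- as.POSIXlt(ts)$hour
  day <- rep(seq_len(ceiling(n / 24)), each = 24)[seq_len(n)]
  anom <- stats::rnorm(max(day), 0, cfg$daily_temp_sd)
  t_air <- cfg$mean_daily_temp + anom[day] +
    cfg$diurnal_amplitude * sin(2 * pi * (hour - 9) / 24)
  t_water <- as.numeric(stats::filter(t_air, rep(1 / 24, 24), sides = 1))
  warm <- which(is.na(t_water))
  t_water[warm] <- cumsum(t_air[warm]) / seq_along(warm)
  scale <- calibrate_wind_scale(cfg$wind_band, cfg$wind_band_freq,
                                cfg$wind_shape)
  u10 <- stats::rweibull(n, cfg$wind_shape, scale)
  wdir <- (315 + stats::rnorm(n, 0, 45)) %% 360
  data.frame(timestamp = ts, u10 = u10, wdir = wdir, t_air = t_air,
             t_water = t_water, pressure = 101.3 + stats::rnorm(n, 0, 0.4))
}

# silicone-byproduct peaks: coeluting 44+47+65, 45+51, and 68
silicone_peaks <- function(props) {
  ids <- vapply(c(44, 45, 68), function(k) {
    hit <- which(vapply(props$iupac, function(g) k %in% g, TRUE))
    if (length(hit) != 1L) {
      stop("silicone-byproduct congener PCB", k, " missing from property table")
    }
    props$peak_id[hit]
  }, "")
  stats::setNames(c(0.55, 0.27, 0.18), ids)
}

#' Generate synthetic dissolved-phase water samples
#'
#' Per-sample totals are uniform over `total_conc_range`; each congener
#' profile is a mixture of a silicone-byproduct component (peaks 44+47+65,
#' 45+51, 68) with expected share `silicone_fraction` and a light-Aroclor
#' background, under multiplicative lognormal per-peak noise. The three
#' largest totals are assigned to the first three sites (the named
#' worst-case locations).
#'
#' @param cfg A [synthetic_config()].
#' @param props A `congener_table`.
#' @return Wide data frame: `site`, `date`, `flow_regime`, then one pg/L
#'   column per peak.
#' @export
generate_water_samples <- function(cfg = synthetic_config(),
                                   props = default_congener_table()) {
  set.seed(cfg$seed)
  sil <- silicone_peaks(props)
  aro <- default_aroclor_profiles()
  bg <- (unclass(aro$Aroclor1016) + unclass(aro$Aroclor1242)) / 2
  bg <- bg[intersect(names(bg), props$peak_id)]
  bg <- bg / sum(bg)
  base <- stats::setNames(rep(0, nrow(props)), props$peak_id)
  base[names(bg)] <- (1 - cfg$silicone_fraction) * bg
  base[names(sil)] <- base[names(sil)] + cfg$silicone_fraction * sil
  sites <- c("Willamette River North", "NW Front Ave",
             "Kingsley Community Garden", "Swan Island", "Cathedral Park",
             "Willamette Cove", "River Mile 11E")
  sites <- rep(sites, length.out = cfg$n_sites)[seq_len(cfg$n_sites)]
  n <- cfg$n_water_samples
  site <- rep(sites, length.out = n)
  regime <- rep(c("high", "low", "storm"), length.out = n)
  totals <- stats::runif(n, cfg$total_conc_range[1], cfg$total_conc_range[2])
  ord <- order(totals, decreasing = TRUE)
  totals <- c(totals[ord[1:3]], sample(totals[ord[-(1:3)]]))
  conc <- matrix(0, n, nrow(props), dimnames = list(NULL, props$peak_id))
  for (i in seq_len(n)) {
    noisy <- base * exp(stats::rnorm(length(base), 0, cfg$water_noise_sdlog))
    conc[i, ] <- noisy / sum(noisy) * totals[i]
  }
  out <- data.frame(
    site = site,
    date = as.Date(cfg$met_start) + (seq_len(n) - 1) %% 21,
    flow_regime = regime,
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(conc, check.names = FALSE))
}

# default PUF receptor geometry: deployments scattered 50 m - 5 km from the
# water on both banks (x is the cross-river axis, source centered at x = 0)
default_puf_receptors <- function(n) {
  k <- seq_len(n)
  dist <- 50 * (5000 / 50)^((k - 1) / (n - 1))     # log-spaced 50 m..5 km
  side <- rep(c(1, -1), length.out = n)
  data.frame(
    x = side * (dist + 300),                       # 300 m = half river width
    y = seq(-8000, 8000, length.out = n),
    z = 2,
    distance_to_water = dist
  )
}

#' Generate a synthetic PUF-PAS field dataset
#'
#' Sorbed masses are `true_air x Veff(rs_true, K', t)` under multiplicative
#' lognormal noise; depuration-compound (13C-PCB 28, 111, 178) final masses
#' decay as `exp(-rs t / (K' v_puf))`; field blanks are drawn from a
#' lognormal floor; surrogate recoveries are Normal(0.88, 0.13) truncated to
#' (0, 1.5]. The first six deployments form two triplicate sites.
#'
#' @param cfg A [synthetic_config()].
#' @param props A `congener_table`.
#' @param true_air True airborne concentrations, pg/m3: matrix deployments x
#'   peaks, or a single named per-peak vector recycled to all deployments.
#' @param rs_true True sampling rate(s), m3/d (scalar or per deployment).
#' @param receptors Optional data frame (`x`, `y`, `z`,
#'   `distance_to_water`), one row per deployment; a default log-spaced
#'   geometry is used otherwise.
#' @param puf A [puf_config()].
#' @return List with `deployments`, `masses` (pg/PUF), `blanks`, `dc`,
#'   `true_air`, and `rs_true` - the shape consumed by
#'   [invert_puf_dataset()].
#' @export
generate_puf_dataset <- function(cfg = synthetic_config(),
                                 props = default_congener_table(),
                                 true_air, rs_true = 3.5, receptors = NULL,
                                 puf = puf_config()) {
  n <- cfg$n_pufs
  if (is.null(dim(true_air))) {
    true_air <- matrix(true_air, n, length(true_air), byrow = TRUE,
                       dimnames = list(NULL, names(true_air)))
  }
  if (nrow(true_air) != n) stop("true_air must have one row per deployment")
  if (any(true_air < 0)) stop("true_air must be nonnegative")
  rs_true <- rep_len(rs_true, n)
  if (any(rs_true <= 0)) stop("rs_true must be positive")
  pk <- colnames(true_air)
  if (is.null(pk)) stop("true_air needs peak_id column names")
  pr <- props[match(pk, props$peak_id), , drop = FALSE]
  if (anyNA(pr$peak_id)) stop("true_air has peaks absent from property table")
  set.seed(cfg$seed + 2L)
  if (is.null(receptors)) receptors <- default_puf_receptors(n)
  site_id <- c(rep(c("PH-T1", "PH-T2"), each = 3),
               sprintf("PH%02d", seq_len(max(n - 6, 0)) + 2))[seq_len(n)]
  rec <- truncnorm_sample(n, 0.88, 0.13, lower = 0, upper = 1.5)
  dep <- data.frame(
    sample_id = sprintf("PUF%02d", seq_len(n)),
    site_id = site_id,
    x = receptors$x, y = receptors$y, height = receptors$z,
    distance_to_water = receptors$distance_to_water,
    t_start = as.Date(cfg$met_start),
    t_end = as.Date(cfg$met_start) + cfg$deployment_days,
    days = cfg$deployment_days,
    t_avg_c = cfg$mean_daily_temp,
    recovery = rec,
    stringsAsFactors = FALSE
  )
  t_avg_k <- cfg$mean_daily_temp + 273.15
  masses <- matrix(0, n, length(pk), dimnames = list(dep$sample_id, pk))
  for (i in seq_len(n)) {
    ve <- effective_volume(pr, rs_true[i], cfg$deployment_days,
                           t_avg = t_avg_k, config = puf)
    noise <- if (cfg$puf_noise_sdlog > 0) {
      exp(stats::rnorm(length(pk), 0, cfg$puf_noise_sdlog))
    } else 1
    # extraction loss attenuates the sorbed mass; the recovery correction in
    # the inversion undoes exactly this factor (recoveries above 1 are
    # measurement artifacts and attenuate nothing)
    loss <- min(dep$recovery[i], 1)
    masses[i, ] <- true_air[i, ] * ve * noise * loss
  }
  dcs <- c(28, 111, 178)
  dc <- do.call(rbind, lapply(dcs, function(cg) {
    kv <- k_puf(congener_record(props, cg), t_avg_k, puf) * puf$v_puf
    fin <- cfg$dc_spike * exp(-rs_true * cfg$deployment_days / kv)
    if (cfg$puf_noise_sdlog > 0) {
      fin <- pmin(fin * exp(stats::rnorm(n, 0, 0.02)), cfg$dc_spike)
    }
    data.frame(sample_id = dep$sample_id, compound = cg,
               initial = cfg$dc_spike, final = fin,
               stringsAsFactors = FALSE)
  }))
  mu <- stats::runif(length(pk), -1.6, 1.0)
  blanks <- matrix(
    10^(rep(mu, each = cfg$n_blanks) +
          stats::rnorm(cfg$n_blanks * length(pk), 0, 0.25)),
    cfg$n_blanks, length(pk),
    dimnames = list(sprintf("FB%02d", seq_len(cfg$n_blanks)), pk)
  )
  list(deployments = dep, masses = masses, blanks = blanks, dc = dc,
       true_air = true_air, rs_true = rs_true)
}

# rejection-free truncated normal via inverse CDF
truncnorm_sample <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}
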