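# Steady-state Gaussian plume dispersion from a water-surface area source,
# with Pasquill-Gifford-Turner stability classes and Briggs dispersion
# coefficients. A desk-scale stand-in for a full regulatory model: flat
# terrain, no downwash, no deposition.

#' Configuration for the plume model
#'
#' @param cell Source discretization cell size, m (default 250).
#' @param calm_threshold Wind speed below which an hour is treated as calm
#'   and excluded (m/s; the plume kernel diverges as u -> 0).
#' @param urban Use Briggs urban dispersion coefficients (default TRUE).
#' @param overcast Treat all hours as overcast (stability class D).
#' @return A list of class `plume_config`.
#' @export
plume_config <- function(cell = 250, calm_threshold = 0.5, urban = TRUE,
                         overcast = FALSE) {
  structure(list(cell = cell, calm_threshold = calm_threshold, urban = urban,
                 overcast = overcast),
            class = "plume_config")
}

#' Daytime insolation category from the hour of day
#'
#' A deterministic proxy for solar input: strong insolation near midday,
#' moderate/slight at the shoulders, night otherwise.
#'
#' @param hour Local hour of day (0-23).
#' @param overcast If TRUE every hour is "overcast".
#' @return One of "strong", "moderate", "slight", "night".
#' @export
insolation_proxy <- function(hour, overcast = FALSE) {
  if (overcast) return(rep("overcast", length(hour)))
  ifelse(hour >= 10 & hour <= 15, "strong",
         ifelse(hour %in% c(8, 9, 16, 17), "moderate",
                ifelse(hour %in% c(7, 18), "slight", "night")))
}

#' Pasquill stability class from wind speed and insolation
#'
#' Turner-style lookup. Split classes of the classical table are resolved
#' toward the less stable member; overcast hours are class D; clear nights
#' are F below 3 m/s, E at 3-5 m/s, D above.
#'
#' @param u10 Wind speed at 10 m, m/s.
#' @param insolation "strong", "moderate", "slight", "overcast", or "night"
#'   (see [insolation_proxy()]).
#' @return Stability class letter(s) "A"-"F".
#' @export
stability_class <- function(u10, insolation) {
  if (any(u10 < 0)) stop("u10 must be nonnegative")
  n <- max(length(u10), length(insolation))
  u10 <- rep_len(u10, n); insolation <- rep_len(insolation, n)
  out <- character(n)
  for (i in seq_len(n)) {
    ins <- insolation[i]; u <- u10[i]
    out[i] <- if (ins == "overcast") "D"
    else if (ins == "night") {
      if (u < 3) "F" else if (u < 5) "E" else "D"
    } else {
      ub <- findInterval(u, c(0, 2, 3, 5, 6))  # 1..5
      switch(ins,
             strong   = c("A", "A", "B", "C", "C")[ub],
             moderate = c("A", "B", "B", "C", "D")[ub],
             slight   = c("B", "C", "C", "D", "D")[ub],
             stop("unknown insolation category: ", ins))
    }
  }
  out
}

#' Briggs dispersion coefficients
#'
#' Crosswind (`sigma_y`) and vertical (`sigma_z`) plume spread as a function
#' of downwind distance, interpolated with the Briggs urban (McElroy-Pooler)
#' or rural (open-country) formulas. Both are monotone increasing in
#' distance.
#'
#' @param pclass Stability class "A"-"F" (urban formulas pool A/B and E/F).
#' @param distance Downwind distance, m (> 0); vectorised.
#' @param urban Use the urban coefficient set (default TRUE).
#' @return List with numeric vectors `sigma_y` and `sigma_z` (m).
#' @export
sigma_yz <- function(pclass, distance, urban = TRUE) {
  if (any(distance <= 0)) stop("downwind distance must be positive")
  x <- distance
  if (urban) {
    sy <- switch(pclass,
                 A = , B = 0.32 * x / sqrt(1 + 0.0004 * x),
                 C = 0.22 * x / sqrt(1 + 0.0004 * x),
                 D = 0.16 * x / sqrt(1 + 0.0004 * x),
                 E = , F = 0.11 * x / sqrt(1 + 0.0004 * x),
                 stop("unknown stability class: ", pclass))
    sz <- switch(pclass,
                 A = , B = 0.24 * x * sqrt(1 + 0.001 * x),
                 C = 0.20 * x,
                 D = 0.14 * x / sqrt(1 + 0.0003 * x),
                 E = , F = 0.08 * x / sqrt(1 + 0.0015 * x))
  } else {
    sy <- switch(pclass,
                 A = 0.22 * x / sqrt(1 + 0.0001 * x),
                 B = 0.16 * x / sqrt(1 + 0.0001 * x),
                 C = 0.11 * x / sqrt(1 + 0.0001 * x),
                 D = 0.08 * x / sqrt(1 + 0.0001 * x),
                 E = 0.06 * x / sqrt(1 + 0.0001 * x),
                 F = 0.04 * x / sqrt(1 + 0.0001 * x),
                 stop("unknown stability class: ", pclass))
    sz <- switch(pclass,
                 A = 0.20 * x,
                 B = 0.12 * x,
                 C = 0.08 * x / sqrt(1 + 0.0002 * x),
                 D = 0.06 * x / sqrt(1 + 0.0015 * x),
                 E = 0.03 * x / (1 + 0.0003 * x),
                 F = 0.016 * x / (1 + 0.0003 * x))
  }
  list(sigma_y = sy, sigma_z = sz)
}

# even-odd ray-casting point-in-polygon (planar, simple polygon)
point_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]; xj <- poly_x[j]; yj <- poly_y[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Discretize a planar source polygon into grid cells
#'
#' @param polygon Data frame of projected vertices (`x`, `y`, m), a simple
#'   closed polygon (last vertex need not repeat the first).
#' @param emission_flux Per-peak emission flux, ng m-2 d-1 (named vector), or
#'   a single total.
#' @param cell Cell size, m.
#' @return An `area_source`: list with `cells` (data frame of cell centers),
#'   `cell_area` (m2), `flux`, and `polygon`.
#' @export
make_area_source <- function(polygon, emission_flux, cell = 250) {
  if (any(emission_flux < 0)) stop("emission_flux must be nonnegative")
  gx <- seq(min(polygon$x) + cell / 2, max(polygon$x), by = cell)
  gy <- seq(min(polygon$y) + cell / 2, max(polygon$y), by = cell)
  grid <- expand.grid(x = gx, y = gy)
  keep <- point_in_polygon(grid$x, grid$y, polygon$x, polygon$y)
  cells <- grid[keep, , drop = FALSE]
  if (nrow(cells) == 0L) stop("no source cells: polygon smaller than one cell?")
  structure(list(cells = cells, cell_area = cell^2, cell = cell,
                 flux = emission_flux, polygon = polygon),
            class = "area_source")
}

# kernel transfer factor (s/m) from all source cells to receptors for one
# hour of meteorology; multiply by flux in ng m-2 s-1 to get ng/m3
plume_transfer <- function(src, rx, ry, rz, u10, wdir, pclass,
                           config = plume_config()) {
  b <- (wdir + 180) * pi / 180          # bearing the wind blows toward
  twx <- sin(b); twy <- cos(b)
  dx <- outer(src$cells$x, rx, function(s, r) r - s)
  dy <- outer(src$cells$y, ry, function(s, r) r - s)
  t_down <- dx * twx + dy * twy
  crossw <- dx * twy - dy * twx
  ok <- t_down > 0
  x_eff <- pmax(t_down, src$cell / 2)
  sig <- sigma_yz(pclass, pmax(x_eff, 1e-6), urban = config$urban)
  kern <- src$cell_area / (pi * sig$sigma_y * sig$sigma_z * u10) *
    exp(-crossw^2 / (2 * sig$sigma_y^2))
  kern <- kern * exp(-sweep(1 / (2 * sig$sigma_z^2), 2, rz^2, "*"))
  kern[!ok] <- 0
  colSums(kern)
}

#' Concentration at receptors from an area source for one meteorology hour
#'
#' The source polygon is discretized into ground-level cells; each cell
#' contributes the reflected Gaussian kernel
#' `Q / (pi sigma_y sigma_z u) * exp(-y^2/(2 sigma_y^2)) * exp(-z^2/(2 sigma_z^2))`
#' and contributions are summed. Linear in the emission flux; receptors
#' upwind of all cells receive zero; near-source singularities are handled by
#' clamping the downwind distance to half a cell.
#'
#' @param src An `area_source` from [make_area_source()].
#' @param receptors Data frame with `x`, `y` (m) and `z` (receptor height, m).
#' @param met One meteorology row: `u10` (m/s), `wdir` (degrees, direction
#'   the wind blows from), `timestamp` (or a `pclass` column overriding the
#'   stability lookup).
#' @param config A [plume_config()].
#' @return Matrix receptors x peaks of concentrations, ng/m3 (single column
#'   when `flux` is a total).
#' @export
area_source_concentration <- function(src, receptors, met,
                                      config = plume_config()) {
  if (met$u10 < config$calm_threshold) {
    stop("calm hour (u10 < ", config$calm_threshold, " m/s)")
  }
  pclass <- if (!is.null(met$pclass)) met$pclass else {
    hr <- as.POSIXlt(met$timestamp)$hour
    stability_class(met$u10, insolation_proxy(hr, config$overcast))
  }
  tf <- plume_transfer(src, receptors$x, receptors$y, receptors$z,
                       met$u10, met$wdir, pclass, config)
  flux_ng_m2_s <- src$flux / 86400
  out <- outer(tf, flux_ng_m2_s)
  rownames(out) <- receptors$id
  out
}

#' Period-average plume concentrations at receptors
#'
#' Hourly kernels are computed for every non-calm hour and averaged; calm
#' hours are excluded and counted. The emission flux is held constant over
#' the period (steady source).
#'
#' @inheritParams area_source_concentration
#' @param met Hourly meteorology data frame (`u10`, `wdir`, `timestamp`).
#' @return List with `per_peak` (matrix receptors x peaks, ng/m3),
#'   `sigma_pcb_pg_m3` (per-receptor totals in pg/m3), `n_hours_used`,
#'   `n_calm`.
#' @export
period_average <- function(src, receptors, met, config = plume_config()) {
  live <- met$u10 >= config$calm_threshold
  n_calm <- sum(!live)
  if (!any(live)) stop("all hours calm; no plume transport")
  met <- met[live, , drop = FALSE]
  pclass <- if (!is.null(met$pclass)) met$pclass else {
    hr <- as.POSIXlt(met$timestamp)$hour
    stability_class(met$u10, insolation_proxy(hr, config$overcast))
  }
  tf_sum <- numeric(nrow(receptors))
  for (i in seq_len(nrow(met))) {
    tf_sum <- tf_sum + plume_transfer(src, receptors$x, receptors$y,
                                      receptors$z, met$u10[i], met$wdir[i],
                                      pclass[i], config)
  }
  tf_mean <- tf_sum / nrow(met)
  per_peak <- outer(tf_mean, src$flux / 86400)  # ng/m3
  rownames(per_peak) <- receptors$id
  list(per_peak = per_peak,
       sigma_pcb_pg_m3 = rowSums(per_peak) * 1000,
       n_hours_used = nrow(met), n_calm = n_calm)
}
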