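test_that("overall transfer velocity composes the two film resistances", {
  # hand arithmetic: 1/(1/3 + 1/(500*0.01)) = 1/(1/3 + 1/5) = 1.875
  expect_equal(overall_mtc(3, 500, 0.01), 1.875)
  # symmetric two-resistance case
  expect_equal(overall_mtc(2, 200, 0.01), 1)
  # water-side-limited asymptote as H' grows
  expect_equal(overall_mtc(3, 500, 1e9), 3, tolerance = 1e-6)
  # always below the smaller conductance
  expect_lt(overall_mtc(3, 500, 0.01), 3)
  expect_error(overall_mtc(0, 500, 0.01), "positive")
  expect_error(overall_mtc(3, 500, 0), "positive")
})

test_that("film velocities respond to wind and molecular size as expected", {
  props <- small_props()
  light <- props[1, ]   # trichloro: smaller molar volume
  heavy <- props[8, ]   # heptachloro
  met5 <- data.frame(u10 = 5, t_water = 20)
  met0 <- data.frame(u10 = 0, t_water = 20)
  # calm-limit intercepts: quadratic water side has zero intercept,
  # air side keeps the stagnant-air term
  expect_equal(water_side_velocity(light, met0), 0)
  expect_gt(air_side_velocity(light, met0), 0)
  # heavier congener (larger Schmidt number) transfers more slowly
  expect_lt(water_side_velocity(heavy, met5), water_side_velocity(light, met5))
  expect_lt(air_side_velocity(heavy, met5), air_side_velocity(light, met5))
  # monotone nondecreasing in wind
  u <- data.frame(u10 = c(0, 2, 5, 9), t_water = 20)
  expect_true(all(diff(water_side_velocity(light, u)) >= 0))
  expect_true(all(diff(air_side_velocity(light, u)) >= 0))
  expect_error(water_side_velocity(light, data.frame(u10 = -1, t_water = 20)),
               "nonnegative")
})

test_that("single hour/peak flux matches a brute-force recomputation", {
  props <- small_props()
  rec <- props[3, ]  # PCB44+47+65
  u <- 4; tw <- 22; c_w <- 50
  met <- data.frame(u10 = u, t_water = tw)
  # independent recomputation of the resistance chain, outside the module
  t_k <- tw + 273.15
  eta <- 2.414e-5 * 10^(247.8 / (t_k - 140))          # Pa s
  d_w <- 13.26e-5 / ((eta * 1000)^1.14 * rec$molar_volume^0.589)
  sc <- (eta / 998 * 1e4) / d_w
  kw_hand <- (0.222 * u^2 + 0.333 * u) * (sc / 600)^-0.5 * 0.24
  fuller <- function(m, v) sqrt(1 / 28.97 + 1 / m) / (v^(1 / 3) + 19.7^(1 / 3))^2
  dr <- fuller(rec$mw, rec$molar_volume) / fuller(18.02, 12.7)
  ka_hand <- (0.2 * u + 0.3) * dr^0.61 * 864
  h_prime <- rec$h298 * exp((rec$du_aw / 8.314) * (1 / 298.15 - 1 / t_k)) /
    (8.314 * t_k)
  v_hand <- 1 / (1 / kw_hand + 1 / (ka_hand * h_prime))

  expect_equal(water_side_velocity(rec, met), kw_hand, tolerance = 1e-12)
  expect_equal(air_side_velocity(rec, met), ka_hand, tolerance = 1e-12)
  v_mod <- overall_mtc(water_side_velocity(rec, met),
                       air_side_velocity(rec, met),
                       dimensionless_henry(henry_at_temperature(rec, t_k), t_k))
  expect_equal(v_mod, v_hand, tolerance = 1e-12)
  expect_equal(congener_flux(v_mod, c_w), v_hand * c_w, tolerance = 1e-12)
  # the vectorised whole-table path agrees with the scalar chain
  v_tab <- transfer_velocity(props, met)
  expect_equal(unname(v_tab[rec$peak_id]), v_hand, tolerance = 1e-10)
})

test_that("gradient-flux law is linear with the pg/L = ng/m3 identity", {
  expect_equal(congener_flux(3.4, 132), 448.8)
  expect_equal(congener_flux(3.4, 0), 0)
  expect_equal(congener_flux(3.4, 264), 2 * congener_flux(3.4, 132))
  expect_error(congener_flux(-1, 10), "nonnegative")
})

test_that("worst case averages the highest-total samples per peak", {
  props <- small_props()
  pk <- props$peak_id
  base <- matrix(1, 5, length(pk), dimnames = list(NULL, pk))
  base <- base * c(1, 5, 2, 4, 3)  # totals rank: rows 2, 4, 5 are top 3
  df <- cbind(data.frame(site = paste0("s", 1:5)),
              as.data.frame(base, check.names = FALSE))
  wc <- select_worst_case(df, 3)
  expect_equal(unname(wc), rep(4, length(pk)), ignore_attr = TRUE)  # mean of 5, 4, 3
  expect_setequal(attr(wc, "sites"), c("s2", "s4", "s5"))
  # degenerate ranking: identical samples
  df1 <- df; df1[, pk] <- 2
  expect_equal(unname(select_worst_case(df1, 3)), rep(2, length(pk)),
               ignore_attr = TRUE)
  # k = n reduces to the plain mean
  expect_equal(unname(select_worst_case(df, 5)), rep(3, length(pk)),
               ignore_attr = TRUE)
  expect_error(select_worst_case(df, 6), "at least")
})

test_that("emission conversion handles ng -> g and d -> s", {
  # 450 ng/m2/d over 15 km2 = 6.75 g/d = 7.8125e-5 g/s
  expect_equal(emissions_from_flux(450, 15e6), 6.75 / 86400)
  expect_equal(emissions_from_flux(0, 15e6), 0)
  expect_equal(emissions_from_flux(450, 30e6), 2 * emissions_from_flux(450, 15e6))
  expect_error(emissions_from_flux(450, 0), "positive")
})

test_that("total flux is additive over peaks and monotone in wind and water temperature", {
  props <- small_props()
  conc <- stats::setNames(rep(10, nrow(props)), props$peak_id)
  met <- const_met(n = 12, u10 = 4, t_water = 20)
  fl <- compute_fluxes(conc, met, props)
  expect_equal(attr(fl, "total_flux"), sum(fl$flux))
  expect_true(all(fl$flux >= 0))
  # monotone in wind speed
  fl_hi_u <- compute_fluxes(conc, const_met(n = 12, u10 = 7, t_water = 20), props)
  expect_true(all(fl_hi_u$flux >= fl$flux))
  # monotone in water temperature (via H(T) and Schmidt number)
  fl_hi_t <- compute_fluxes(conc, const_met(n = 12, u10 = 4, t_water = 26), props)
  expect_true(all(fl_hi_t$flux >= fl$flux))
})

test_that("Monte Carlo collapses to the deterministic flux under zero spread", {
  props <- small_props()
  conc <- stats::setNames(rep(10, nrow(props)), props$peak_id)
  met <- const_met(n = 24, u10 = 4, t_water = 20)
  det <- compute_fluxes(conc, met, props)
  mc <- monte_carlo_flux(conc, met, props, n_iter = 200, seed = 11,
                         sdlog_conc = 0, sdlog_henry = 0, resample_met = FALSE)
  expect_equal(mc$per_peak$mc_sd, rep(0, nrow(props)), tolerance = 1e-12)
  expect_equal(mc$per_peak$mc_mean, det$flux, tolerance = 1e-12)
  expect_equal(mc$total_sd, 0, tolerance = 1e-12)
  # seeded determinism
  m1 <- monte_carlo_flux(conc, met, props, n_iter = 150, seed = 5)
  m2 <- monte_carlo_flux(conc, met, props, n_iter = 150, seed = 5)
  expect_identical(m1$total_mean, m2$total_mean)
  expect_identical(m1$per_peak, m2$per_peak)
  expect_error(monte_carlo_flux(conc, met, props, n_iter = 50, seed = 1),
               "n_iter")
})
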