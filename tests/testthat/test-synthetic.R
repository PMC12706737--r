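test_that("synthetic water samples match the configured study design", {
  props <- default_congener_table()
  cfg <- synthetic_config(seed = 1)
  w <- generate_water_samples(cfg, props)
  expect_identical(nrow(w), 21L)
  expect_identical(length(unique(w$site)), 7L)
  pk <- setdiff(names(w), c("site", "date", "flow_regime"))
  totals <- rowSums(w[, pk])
  expect_true(all(totals >= 80 & totals <= 184))
  expect_true(all(as.matrix(w[, pk]) >= 0))
  # the three named worst-case sites carry the three highest totals
  wc <- select_worst_case(w, 3)
  expect_setequal(attr(wc, "sites"),
                  c("Willamette River North", "NW Front Ave",
                    "Kingsley Community Garden"))
  # reproducibility: same seed, identical table
  expect_identical(w, generate_water_samples(cfg, props))
  # different seed, different noise
  expect_false(identical(w, generate_water_samples(synthetic_config(seed = 2),
                                                   props)))
})

test_that("silicone-byproduct share behaves as a mixture weight", {
  props <- default_congener_table()
  sil_peaks <- c("PCB44+47+65", "PCB45+51", "PCB68")
  # boundary: all mass on the silicone peaks
  w1 <- generate_water_samples(synthetic_config(seed = 3, silicone_fraction = 1),
                               props)
  pk <- setdiff(names(w1), c("site", "date", "flow_regime"))
  other <- setdiff(pk, sil_peaks)
  expect_equal(max(as.matrix(w1[, other])), 0)
  # default: silicone share near the configured expectation
  w <- generate_water_samples(synthetic_config(seed = 3), props)
  share <- rowSums(w[, sil_peaks]) / rowSums(w[, pk])
  expect_equal(mean(share), 0.48, tolerance = 0.05)
  # missing silicone peaks in the property table is an error
  lean <- small_props()
  lean2 <- lean[lean$peak_id != "PCB68", ]
  expect_error(generate_water_samples(synthetic_config(seed = 1), lean2),
               "PCB68")
})

test_that("synthetic meteorology hits the temperature and wind-band design", {
  cfg <- synthetic_config(seed = 1)
  met <- generate_met(cfg)
  expect_identical(nrow(met), 960L)  # 40 days of hourly records
  daily <- tapply(met$t_air, rep(1:40, each = 24), mean)
  expect_lt(abs(mean(daily) - 23), 0.5)
  band <- mean(met$u10 >= 3.60 & met$u10 <= 8.80)
  expect_lt(abs(band - 0.33), 0.05)
  expect_true(all(met$u10 >= 0))
  # water temperature is a smoothed version of air temperature
  expect_lt(stats::sd(met$t_water), stats::sd(met$t_air))
  # reproducibility and boundary cases
  expect_identical(met, generate_met(cfg))
  met0 <- generate_met(synthetic_config(seed = 1, wind_band_freq = 0))
  expect_equal(mean(met0$u10 >= 3.60 & met0$u10 <= 8.80), 0)
  expect_error(generate_met(synthetic_config(met_start = "2018-08-02",
                                             met_end = "2018-08-01")),
               "after")
  expect_error(generate_met(synthetic_config(wind_band_freq = 0.9)),
               "unattainable")
})

test_that("noiseless PUF dataset inverts back to the true air exactly", {
  props <- small_props()
  cfg <- synthetic_config(seed = 4, puf_noise_sdlog = 0, n_pufs = 8)
  truth <- stats::setNames(c(5, 10, 20, 15, 8, 3, 2, 1), props$peak_id)
  pd <- generate_puf_dataset(cfg, props, truth, rs_true = 3.5)
  inv <- invert_puf_dataset(pd, props, rs = pd$rs_true, apply_loq = FALSE)
  expect_equal(max(abs(sweep(inv$concentrations, 2, truth, "/") - 1)), 0,
               tolerance = 1e-9)
  # the DC route recovers the same rate the masses were generated with
  dc28 <- pd$dc[pd$dc$compound == 28, ]
  est <- dc_sampling_rate(dc28$initial[1], dc28$final[1], cfg$deployment_days,
                          congener_record(props, 28),
                          t_avg = cfg$mean_daily_temp + 273.15)
  expect_equal(est$rs, 3.5, tolerance = 1e-9)
})

test_that("DC spikes depurate according to the configured sampling rate", {
  props <- small_props()
  cfg <- synthetic_config(seed = 5, puf_noise_sdlog = 0, n_pufs = 6)
  truth <- stats::setNames(rep(5, nrow(props)), props$peak_id)
  kv28 <- k_puf(congener_record(props, 28), cfg$mean_daily_temp + 273.15) *
    puf_config()$v_puf
  # a rate chosen for 50% loss lands mid-range of the 20-80% validity rule
  rs_half <- log(2) * kv28 / cfg$deployment_days
  pd <- generate_puf_dataset(cfg, props, truth, rs_true = rs_half)
  inv <- invert_puf_dataset(pd, props, apply_loq = FALSE)
  expect_true(all(inv$rs_table$valid))
  expect_equal(inv$rs_table$dc_loss_fraction, rep(0.5, 6), tolerance = 1e-9)
  # a near-stagnant sampler retains >95% of the spike: flagged invalid
  pd2 <- generate_puf_dataset(cfg, props, truth, rs_true = 0.05)
  dc28 <- pd2$dc[pd2$dc$compound == 28, ]
  expect_true(all(dc28$final / dc28$initial > 0.95))
  inv2 <- invert_puf_dataset(pd2, props, apply_loq = FALSE)
  expect_false(any(inv2$rs_table$valid))
  # invalid DC falls back to the configured model rate
  expect_equal(unique(inv2$rs_table$rs_used), puf_config()$fallback_rs)
})

test_that("20% mass noise keeps the median inversion error under 25%", {
  props <- default_congener_table()
  cfg <- synthetic_config(seed = 6, puf_noise_sdlog = 0.2)
  aro <- unclass(default_aroclor_profiles()$Aroclor1242)
  truth <- stats::setNames(300 * aro[props$peak_id], props$peak_id)
  set.seed(60)
  rs_true <- exp(stats::rnorm(cfg$n_pufs, log(3.2), 0.6))
  pd <- generate_puf_dataset(cfg, props, truth, rs_true = rs_true)
  inv <- invert_puf_dataset(pd, props, rs = rs_true, apply_loq = FALSE)
  rel <- abs(sweep(inv$concentrations, 2, truth, "/") - 1)
  rel <- rel[, truth > 0]
  expect_lt(stats::median(rel), 0.25)
  # per-site totals recovered well too
  tot_err <- abs(inv$sigma_pcb / sum(truth) - 1)
  expect_lt(stats::median(tot_err), 0.25)
})

test_that("surrogate recoveries stay in the truncated design range", {
  props <- small_props()
  cfg <- synthetic_config(seed = 7)
  truth <- stats::setNames(rep(5, nrow(props)), props$peak_id)
  pd <- generate_puf_dataset(cfg, props, truth)
  expect_true(all(pd$deployments$recovery > 0 &
                    pd$deployments$recovery <= 1.5))
  expect_equal(mean(pd$deployments$recovery), 0.88, tolerance = 0.12)
  # two triplicate sites in the design
  expect_identical(sum(table(pd$deployments$site_id) == 3L), 2L)
  expect_identical(nrow(pd$blanks), 5L)
})
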