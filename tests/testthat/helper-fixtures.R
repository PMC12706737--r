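# In-code fixtures: a small congener table covering the peaks the synthetic
# generators and DC methods rely on, and constant-meteorology builders.

small_props_csv <- function(path = tempfile(fileext = ".csv")) {
  hl <- c(3, 3, 4, 4, 4, 5, 6, 7)
  df <- data.frame(
    peak_id = c("PCB18+30", "PCB28", "PCB44+47+65", "PCB45+51", "PCB68",
                "PCB111", "PCB153+168", "PCB178"),
    iupac_numbers = c("18;30", "28", "44;47;65", "45;51", "68",
                      "111", "153;168", "178"),
    homolog = hl,
    mw = 154.212 + 34.445 * hl,
    h298 = c(30, 28, 24, 25, 23, 18, 15, 12),
    du_aw = 47000 + 1700 * hl,
    log_koa_298 = 5.75 + 0.60 * hl,
    du_oa = 60000 + 3000 * hl,
    molar_volume = 184.6 + 20.9 * hl,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  path
}

small_props <- function() load_congener_table(small_props_csv())

# constant hourly meteorology (optionally with a fixed stability class)
const_met <- function(n = 24, u10 = 4, t_air = 23, t_water = 22, wdir = 0,
                      pclass = NULL) {
  m <- data.frame(
    timestamp = as.POSIXct("2018-08-01 00:00", tz = "UTC") + 3600 * (seq_len(n) - 1),
    u10 = u10, wdir = wdir, t_air = t_air, t_water = t_water, pressure = 101.3
  )
  if (!is.null(pclass)) m$pclass <- pclass
  m
}

# single-cell area source: one 500 m x 500 m cell centered at the origin
single_cell_source <- function(flux = 100, cell = 500) {
  poly <- data.frame(x = c(-250, 250, 250, -250), y = c(-250, -250, 250, 250))
  make_area_source(poly, flux, cell = cell)
}
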