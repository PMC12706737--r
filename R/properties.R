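# Physicochemical properties of PCB congeners and coeluting peaks.

# universal gas constant, Pa m3 mol-1 K-1
.R_GAS <- 8.314

#' Load and validate a congener property table
#'
#' Reads a CSV with one row per chromatographic peak. Coeluting congeners are
#' quantified together as one peak; each peak carries the property values of
#' its representative congener (by convention the lowest IUPAC number in the
#' peak). The packaged default table (`default_congener_table()`) covers all
#' 209 congeners in 173 peaks.
#'
#' @param path Path to a CSV file with columns `peak_id`, `iupac_numbers`
#'   (semicolon-separated IUPAC numbers), `homolog` (chlorine count 1-10),
#'   `mw` (g/mol), `h298` (Henry's law constant at 298.15 K, Pa m3/mol),
#'   `du_aw` (internal energy of air-water transfer, J/mol), `log_koa_298`,
#'   `du_oa` (J/mol), and `molar_volume` (LeBas, cm3/mol).
#' @return A `data.frame` of class `congener_table`, one row per peak, with
#'   `iupac` as a list-column of integer vectors.
#' @examples
#' props <- default_congener_table()
#' nrow(props)                       # 173 peaks
#' sum(lengths(props$iupac))         # 209 congeners
#' @export
load_congener_table <- function(path) {
  if (!file.exists(path)) stop("congener table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("no records in congener table: ", path)
  required <- c("peak_id", "iupac_numbers", "homolog", "mw", "h298",
                "du_aw", "log_koa_298", "molar_volume")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("congener table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(raw$du_oa)) raw$du_oa <- 70000  # fallback K_PUF temperature energy
  iupac <- lapply(strsplit(as.character(raw$iupac_numbers), "[;+ ]+"),
                  function(x) as.integer(x[nzchar(x)]))
  if (any(lengths(iupac) == 0L)) {
    stop("empty iupac_numbers in row(s): ",
         paste(which(lengths(iupac) == 0L), collapse = ", "))
  }
  all_nums <- unlist(iupac)
  if (anyNA(all_nums) || any(all_nums < 1L | all_nums > 209L)) {
    stop("IUPAC numbers must be integers in 1..209")
  }
  dup <- unique(all_nums[duplicated(all_nums)])
  if (length(dup) > 0L) {
    rows <- which(vapply(iupac, function(g) any(g %in% dup), TRUE))
    stop("duplicate IUPAC number(s) ", paste(dup, collapse = ", "),
         " in row(s): ", paste(rows, collapse = ", "))
  }
  bad <- which(!is.finite(raw$h298) | raw$h298 <= 0)
  if (length(bad) > 0L) {
    stop("non-positive h298 in row(s): ", paste(bad, collapse = ", "))
  }
  bad <- which(raw$mw < 188.6 | raw$mw > 498.8)
  if (length(bad) > 0L) {
    stop("mw outside the PCB range [188.7, 498.7] in row(s): ",
         paste(bad, collapse = ", "))
  }
  # homolog consistent with the representative congener's IUPAC range
  rep_n <- vapply(iupac, min, 1)
  expect_hl <- findInterval(rep_n, c(1, 4, 16, 40, 82, 128, 170, 194, 206, 209))
  bad <- which(raw$homolog != expect_hl)
  if (length(bad) > 0L) {
    stop("homolog inconsistent with IUPAC number in row(s): ",
         paste(bad, collapse = ", "))
  }
  out <- data.frame(
    peak_id = as.character(raw$peak_id),
    representative = as.integer(rep_n),
    homolog = as.integer(raw$homolog),
    mw = as.numeric(raw$mw),
    h298 = as.numeric(raw$h298),
    du_aw = as.numeric(raw$du_aw),
    log_koa_298 = as.numeric(raw$log_koa_298),
    du_oa = as.numeric(raw$du_oa),
    molar_volume = as.numeric(raw$molar_volume),
    stringsAsFactors = FALSE
  )
  out$iupac <- iupac
  class(out) <- c("congener_table", "data.frame")
  out
}

#' Packaged default congener property table
#'
#' A synthetic compilation: exact molecular weights and LeBas molar volumes,
#' with Henry's law constants, transfer energies, and log KOA generated from
#' homolog-level correlations. Intended as a fully documented, replaceable
#' default; substitute a measured table via [load_congener_table()] for
#' site-specific work.
#'
#' @return A `congener_table` (see [load_congener_table()]).
#' @export
default_congener_table <- function() {
  load_congener_table(system.file("extdata", "congener_properties_synthetic.csv",
                                  package = "pcbair", mustWork = TRUE))
}

#' Write a congener table back to CSV
#'
#' Inverse of [load_congener_table()]: `load_congener_table(write_congener_table(x, f))`
#' returns a table identical to `x`.
#'
#' @param props A `congener_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_congener_table <- function(props, path) {
  out <- props
  out$iupac_numbers <- vapply(props$iupac, paste, "", collapse = ";")
  out$iupac <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Look up the peak record containing a given congener
#'
#' @param props A `congener_table`.
#' @param iupac A single IUPAC congener number (1-209).
#' @return The one-row `congener_table` for the peak containing `iupac`.
#' @export
congener_record <- function(props, iupac) {
  hit <- which(vapply(props$iupac, function(g) iupac %in% g, TRUE))
  if (length(hit) != 1L) stop("congener PCB", iupac, " not found in table")
  props[hit, , drop = FALSE]
}

#' Henry's law constant at a given water temperature
#'
#' Van 't Hoff adjustment from the 298.15 K reference value:
#' `H(T) = h298 * exp((du_aw / R) * (1/298.15 - 1/T))`.
#'
#' @param rec A one-row `congener_table` (or any list with `h298`, `du_aw`).
#' @param t_water Water temperature in Kelvin (270-320).
#' @return Henry's law constant at `t_water`, Pa m3/mol. Vectorised over
#'   `t_water` and over rows of `rec`.
#' @examples
#' rec <- default_congener_table()[1, ]
#' henry_at_temperature(rec, 298.15) == rec$h298
#' @export
henry_at_temperature <- function(rec, t_water) {
  if (any(t_water <= 270 | t_water >= 320)) {
    stop("t_water must be in Kelvin, within (270, 320)")
  }
  rec$h298 * exp((rec$du_aw / .R_GAS) * (1 / 298.15 - 1 / t_water))
}

#' Dimensionless Henry's law constant
#'
#' `H' = H / (R * T)` with R = 8.314 Pa m3 mol-1 K-1.
#'
#' @param h_t Henry's law constant at the water temperature, Pa m3/mol.
#' @param t_water Water temperature, K.
#' @return Dimensionless Henry's law constant.
#' @export
dimensionless_henry <- function(h_t, t_water) {
  if (any(!is.finite(h_t) | h_t <= 0)) stop("h_t must be positive")
  h_t / (.R_GAS * t_water)
}

#' Load an Aroclor (or other) reference congener profile
#'
#' @param path CSV with columns `peak_id` and `fraction`. Fractions are
#'   renormalized to sum to one.
#' @param name Label for the profile; defaults to the file name.
#' @return A `profile` object (see [normalize_profile()]).
#' @export
load_aroclor_profile <- function(path, name = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("peak_id", "fraction") %in% names(raw))) {
    stop("profile CSV needs columns peak_id, fraction")
  }
  if (is.null(name)) name <- sub("\\.csv$", "", basename(path))
  v <- stats::setNames(as.numeric(raw$fraction), raw$peak_id)
  normalize_profile(v, label = name)
}

#' Packaged synthetic Aroclor reference profiles
#'
#' Profiles for Aroclor 1016 and 1242 on the 173-peak basis, built from
#' homolog-level mass distributions (synthetic stand-ins for published
#' reference profiles; replaceable via [load_aroclor_profile()]).
#'
#' @return Named list of `profile` objects.
#' @export
default_aroclor_profiles <- function() {
  list(
    Aroclor1016 = load_aroclor_profile(
      system.file("extdata", "aroclor_1016_synthetic.csv", package = "pcbair",
                  mustWork = TRUE), name = "Aroclor1016"),
    Aroclor1242 = load_aroclor_profile(
      system.file("extdata", "aroclor_1242_synthetic.csv", package = "pcbair",
                  mustWork = TRUE), name = "Aroclor1242")
  )
}
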