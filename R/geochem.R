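# Physical constants (CODATA): gas constant J/(mol K), Faraday C/mol.
.R_GAS <- 8.31446
.FARADAY <- 96485.33
.LN10 <- log(10)

#' Nernst slope dEh/dpH
#'
#' The theoretical pH dependence of electrode potential,
#' -ln(10) R T / F, expressed in mV per pH unit: -59.16 at 25 degrees C.
#'
#' @param T_C Temperature in degrees Celsius (default 25).
#' @return Slope in mV per pH unit (negative).
#' @examples
#' nernst_slope(25)  # -59.16
#' @export
nernst_slope <- function(T_C = 25) {
  if (any(!is.finite(T_C)) || any(T_C <= -273.15))
    stop("temperature must be above absolute zero")
  -.LN10 * .R_GAS * (T_C + 273.15) / .FARADAY * 1000
}

#' Correct Eh to pH 7 (Eh7)
#'
#' Eh7 = Eh + (dEh/dpH) (7 - pH), with the Nernst slope evaluated at the
#' sample temperature. Missing pH or temperature defaults to pH 7 / 25
#' degrees C, which leaves Eh unchanged in the pH case.
#'
#' @param Eh_mV Measured redox potential, mV vs SHE.
#' @param pH Sample pH; NA means "assume 7".
#' @param T_C Temperature in degrees C; NA means "assume 25".
#' @return Eh7 in mV vs SHE. Vectorized over all arguments.
#' @examples
#' eh_to_eh7(0, pH = 5)     # -118.32
#' eh_to_eh7(-100, pH = 9)  # +18.32
#' @export
eh_to_eh7 <- function(Eh_mV, pH = NA, T_C = NA) {
  pH <- ifelse(is.na(pH), 7, pH)
  T_C <- ifelse(is.na(T_C), 25, T_C)
  if (any(pH < 0 | pH > 14))
    warning("pH outside [0, 14]")
  Eh_mV + nernst_slope(T_C) * (7 - pH)
}

#' Invert the Eh7 correction
#'
#' Recovers the raw Eh at a given pH from an Eh7 value; exact inverse of
#' [eh_to_eh7()].
#'
#' @inheritParams eh_to_eh7
#' @param Eh7_mV Corrected potential, mV vs SHE.
#' @return Eh in mV vs SHE.
#' @export
eh7_to_eh <- function(Eh7_mV, pH = NA, T_C = NA) {
  pH <- ifelse(is.na(pH), 7, pH)
  T_C <- ifelse(is.na(T_C), 25, T_C)
  Eh7_mV - nernst_slope(T_C) * (7 - pH)
}

# Molar mass of O2, g/mol.
.O2_MOLAR_MASS <- 31.9988

#' Convert dissolved O2 from mg/L to micromolar
#'
#' @param x O2 concentration in mg/L; values reported as zero or below
#'   detection should be passed as 0.
#' @return Concentration in umol/L.
#' @examples
#' o2_mgL_to_uM(1)  # 31.25
#' @export
o2_mgL_to_uM <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("O2 concentration cannot be negative")
  x * 1000 / .O2_MOLAR_MASS
}

#' Henry's-law constant for O2 in water
#'
#' Van't Hoff correlation KH(T) = KH0 exp(C (1/T - 1/T0)) with
#' KH0 = 1.2e-3 mol/(L bar) at 298.15 K and C = 1700 K (compilation values
#' for O2). Valid over roughly 0-50 degrees C liquid water.
#'
#' @param T_C Temperature in degrees C.
#' @return KH in mol/(L bar).
#' @export
henry_o2_vant_hoff <- function(T_C) {
  if (any(T_C < 0 | T_C > 50))
    stop("Henry correlation valid for 0-50 degrees C only")
  T_K <- T_C + 273.15
  1.2e-3 * exp(1700 * (1 / T_K - 1 / 298.15))
}

# Atmospheric O2 partial pressure at sea level, bar (0.21 atm).
.P_O2_BAR <- 0.2128

#' Convert O2 percent saturation to micromolar
#'
#' Saturated O2 concentration is Henry's constant at the sample temperature
#' times the atmospheric O2 partial pressure (0.2128 bar); the percentage
#' scales it. The Henry correlation is pluggable so an alternative
#' temperature dependence can be swapped in.
#'
#' @param pct Percent of air saturation (>= 0).
#' @param T_C Temperature in degrees C; NA means "assume 25".
#' @param henry Function of T_C returning KH in mol/(L bar).
#' @return Concentration in umol/L.
#' @examples
#' o2_percent_sat_to_uM(100, 25)  # ~255 uM
#' @export
o2_percent_sat_to_uM <- function(pct, T_C = NA,
                                 henry = henry_o2_vant_hoff) {
  if (any(pct < 0, na.rm = TRUE)) stop("percent saturation cannot be negative")
  T_C <- ifelse(is.na(T_C), 25, T_C)
  sat_uM <- henry(T_C) * .P_O2_BAR * 1e6
  sat_uM * pct / 100
}

#' Normalize mixed-unit O2 metadata to micromolar
#'
#' @param value Numeric O2 values.
#' @param unit One of `"mg_L"`, `"uM"`, `"pct_sat"` per value.
#' @param T_C Temperatures for the percent-saturation conversion.
#' @return Concentrations in umol/L.
#' @export
o2_to_uM <- function(value, unit, T_C = NA) {
  stopifnot(length(unit) %in% c(1L, length(value)))
  unit <- rep_len(unit, length(value))
  T_C <- rep_len(T_C, length(value))
  out <- rep(NA_real_, length(value))
  for (u in unique(unit)) {
    i <- which(unit == u & !is.na(value))
    if (!length(i)) next
    out[i] <- switch(u,
      mg_L = o2_mgL_to_uM(value[i]),
      uM = value[i],
      pct_sat = o2_percent_sat_to_uM(value[i], T_C[i]),
      stop("unknown O2 unit: ", u))
  }
  out
}

#' Read a sample metadata CSV
#'
#' Expected columns: sample_id, dataset, environment, Eh_mV, pH, T_C,
#' O2_value, O2_unit (mg_L|uM|pct_sat). pH and T_C may be missing (NA).
#' Adds Eh7_mV (via [eh_to_eh7()]) and O2_uM columns.
#'
#' @param path CSV path.
#' @return data.frame with derived Eh7_mV and O2_uM columns.
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "dataset", "environment", "Eh_mV")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  for (col in c("pH", "T_C", "O2_value")) if (is.null(md[[col]]))
    md[[col]] <- NA_real_
  if (is.null(md$O2_unit)) md$O2_unit <- "uM"
  md$Eh7_mV <- eh_to_eh7(md$Eh_mV, md$pH, md$T_C)
  md$O2_uM <- o2_to_uM(md$O2_value, md$O2_unit, md$T_C)
  md
}
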