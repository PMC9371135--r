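#' Saturation vapor pressure (Tetens form)
#'
#' `Psat(T) = 0.6108 * exp(17.27 T / (T + 237.3))` kPa, the FAO-56 Tetens
#' formulation.  Strictly increasing and positive for all `T > -237.3`.
#'
#' @param T temperature in degC (vectorized).
#' @return saturation vapor pressure in kPa.
#' @examples
#' sat_vapor_pressure(0)   # 0.6108
#' sat_vapor_pressure(25)  # ~3.168
#' @export
sat_vapor_pressure <- function(T) {
  if (any(T <= -237.3, na.rm = TRUE)) stop_arg("temperature out of domain (must be > -237.3 degC)")
  0.6108 * exp(17.27 * T / (T + 237.3))
}

#' Leaf-to-air vapor pressure deficit, kPa
#'
#' `VPD = Psat(Tc) - (RH/100) * Psat(Ta)`: the saturation term is evaluated
#' at the crop (leaf) temperature and the actual-vapor term at the air
#' temperature.  Can be negative when the leaf is much cooler than the air
#' at high humidity; values are returned as computed, not clipped.
#'
#' @param Tc crop (leaf) temperature, degC.
#' @param Ta air temperature, degC.
#' @param RH relative humidity, percent (0--100).  Whether ambient or crop
#'   humidity is supplied is the caller's choice; batch helpers default to
#'   ambient with a switch to crop.
#' @return VPD in kPa.
#' @examples
#' vpd_kpa(25, 25, 50)  # ~1.584
#' @export
vpd_kpa <- function(Tc, Ta, RH) {
  if (any(RH < 0 | RH > 100, na.rm = TRUE)) stop_arg("RH must be in [0, 100]")
  sat_vapor_pressure(Tc) - (RH / 100) * sat_vapor_pressure(Ta)
}

#' Leaf-to-air vapor pressure deficit, Pa (base-10 exponential form)
#'
#' `VPD = 610.7 * (10^(7.5 Tc / (Tc + 237.3)) - (RH/100) * 10^(7.5 Ta / (Ta
#' + 237.3)))`.  Since `17.27 / ln(10) = 7.5006`, this form agrees with
#' 1000 x [vpd_kpa()] to within about 0.2 % over the physiological range; it
#' is retained for cross-validation, while the kPa form is the one reported.
#'
#' @inheritParams vpd_kpa
#' @return VPD in Pa.
#' @export
vpd_pa <- function(Tc, Ta, RH) {
  if (any(RH < 0 | RH > 100, na.rm = TRUE)) stop_arg("RH must be in [0, 100]")
  610.7 * (10^(7.5 * Tc / (Tc + 237.3)) - (RH / 100) * 10^(7.5 * Ta / (Ta + 237.3)))
}

#' Crop-air temperature difference
#'
#' `DT_la = Tc - Ta`: positive when the leaf runs hotter than the air.
#'
#' @inheritParams vpd_kpa
#' @return temperature difference in degC.
#' @export
dtla <- function(Tc, Ta) Tc - Ta

#' Classify water stress from the crop-air temperature difference
#'
#' Arid and semi-arid field bands: a crop is under water stress when the
#' leaf runs 4--6 degC above the air, and free of water stress when it runs
#' 1--4 degC below.  The bands do not cover the whole line; everything else
#' (including the gap (-1, 4) and values beyond either band) is
#' `"indeterminate"`.
#'
#' @param d temperature difference `Tc - Ta` in degC (vectorized).
#' @return character vector: `"stress"`, `"no_stress"` or `"indeterminate"`.
#' @export
classify_dtla <- function(d) {
  out <- rep("indeterminate", length(d))
  out[!is.na(d) & d >= 4 & d <= 6] <- "stress"
  out[!is.na(d) & d >= -4 & d <= -1] <- "no_stress"
  out[is.na(d)] <- NA_character_
  out
}

#' Classify water stress from VPD
#'
#' A VPD above 1 kPa is potentially harmful (stomatal closure); 0.5--1 kPa
#' is the favorable window; below 0.5 kPa is intermediate.  "Above 1" is
#' read strictly, so exactly 1 kPa is favorable.
#'
#' @param v VPD in kPa (vectorized).
#' @return character vector: `"harmful"`, `"favorable"` or `"intermediate"`.
#' @export
classify_vpd <- function(v) {
  out <- rep("intermediate", length(v))
  out[!is.na(v) & v >= 0.5 & v <= 1] <- "favorable"
  out[!is.na(v) & v > 1] <- "harmful"
  out[is.na(v)] <- NA_character_
  out
}

#' Compute the full set of water-stress markers for a telemetry table
#'
#' Appends `Psat_c`, `Psat_a`, `VPD` (kPa), `VPD_pa` (Pa), `DTla` and the
#' two categorical stress labels to a climate data.frame.  Negative VPD
#' values (leaf much cooler than air at high humidity) are reported as
#' computed and flagged in the `vpd_negative` column rather than clipped.
#'
#' @param df data.frame with columns `Ta`, `RHa`, `Tc` and optionally
#'   `RHc` and `t`.
#' @param rh_source which humidity feeds the VPD actual-vapor term:
#'   `"ambient"` (default, column `RHa`) or `"crop"` (column `RHc`).
#' @return `df` with the marker columns appended.
#' @export
compute_stress_markers <- function(df, rh_source = c("ambient", "crop")) {
  rh_source <- match.arg(rh_source)
  need <- c("Ta", "RHa", "Tc")
  if (rh_source == "crop") need <- c(need, "RHc")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_arg("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  RH <- if (rh_source == "crop") df$RHc else df$RHa
  df$Psat_c <- sat_vapor_pressure(df$Tc)
  df$Psat_a <- sat_vapor_pressure(df$Ta)
  df$VPD <- df$Psat_c - (RH / 100) * df$Psat_a
  df$VPD_pa <- vpd_pa(df$Tc, df$Ta, RH)
  df$DTla <- dtla(df$Tc, df$Ta)
  df$stress_dtla <- classify_dtla(df$DTla)
  df$stress_vpd <- classify_vpd(df$VPD)
  df$vpd_negative <- df$VPD < 0
  df
}

#' Summary statistics of a telemetry series
#'
#' Minimum, maximum, mean, sample standard deviation (n-1 denominator) and
#' the clock times of the extrema, in the layout of the monitoring system's
#' variable-analysis table.  Ties among equal extrema break to the earliest
#' timestamp.
#'
#' @param t timestamps (POSIXct), or a two-column data.frame `(t, value)`.
#' @param value numeric series (ignored when `t` is a data.frame).
#' @param variable optional variable name carried into the output.
#' @return one-row data.frame with columns `variable`, `minimum`, `maximum`,
#'   `mean`, `std`, `time_of_max`, `time_of_min` (POSIXct) and the
#'   clock-time renderings `clock_max`, `clock_min` ("HH:MM").
#' @export
summarize_series <- function(t, value = NULL, variable = NA_character_) {
  if (is.data.frame(t)) {
    value <- t[[2]]
    t <- t[[1]]
  }
  if (length(value) == 0) stop_arg("series must be non-empty")
  if (length(t) != length(value)) stop_arg("t and value must have equal length")
  ok <- !is.na(value)
  if (!any(ok)) stop_arg("series must contain at least one non-missing value")
  t <- t[ok]; value <- value[ok]
  i_max <- which(value == max(value))[1]
  i_min <- which(value == min(value))[1]
  clock <- function(x) format(as_time(x), "%H:%M")
  data.frame(
    variable = variable,
    minimum = min(value), maximum = max(value),
    mean = mean(value),
    std = if (length(value) > 1) stats::sd(value) else 0,
    time_of_max = as_time(t[i_max]), time_of_min = as_time(t[i_min]),
    clock_max = clock(t[i_max]), clock_min = clock(t[i_min]),
    stringsAsFactors = FALSE
  )
}
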