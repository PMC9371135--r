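# Report suite: the variable-to-report mapping and the twelve report kinds
# of the monitoring app, plus manual-measurement recording.

.report_kinds <- c("ambient", "crop", "difference_temperature", "luminosity",
                   "solution", "reservoir", "inspection", "vpd",
                   "solution_parameters", "crop_parameters",
                   "requests_per_hour", "requests_per_channel")

# variable -> (channel, field) location in the default deployment
.var_location <- list(
  Ta = c("environmental", "Ta_htu"), RHa = c("environmental", "RHa"),
  Tc = c("environmental", "Tc"), RHc = c("environmental", "RHc"),
  Lum = c("environmental", "Lum"),
  T_sol = c("services", "T_sol"), L_sol = c("services", "L_sol"),
  T_res = c("environmental", "T_res"), L_res = c("environmental", "L_res"),
  S_irr = c("services", "S_irr"), S_res = c("services", "S_res"),
  S_cam = c("services", "S_cam"),
  pH = c("manual", "pH"), EC = c("manual", "EC"),
  Fw = c("manual", "Fw"), L_l = c("manual", "L_l"), W_l = c("manual", "W_l"),
  HNO3 = c("manual", "HNO3"), A_sol = c("manual", "A_sol"),
  B_sol = c("manual", "B_sol")
)

#' The variable-to-report mapping of the report suite
#'
#' Transcribes which monitored variables feed each of the twelve reports.
#' The VPD report is fed by ambient temperature and crop humidity (as the
#' deployment's report table marks it) even though the VPD computation
#' itself uses crop temperature, air temperature and humidity; the report
#' surfaces both.
#'
#' @return named list: report kind -> character vector of variable names.
#' @export
report_variable_map <- function() {
  all_vars <- names(.var_location)
  list(
    ambient = c("Ta", "RHa"),
    crop = c("Tc", "RHc"),
    difference_temperature = c("Ta", "Tc"),
    luminosity = "Lum",
    solution = c("T_sol", "T_res"),
    reservoir = c("L_res", "S_irr", "S_res"),
    inspection = "S_cam",
    vpd = c("Ta", "RHc"),
    solution_parameters = c("pH", "EC", "HNO3", "A_sol", "B_sol"),
    crop_parameters = c("Fw", "L_l", "W_l"),
    requests_per_hour = all_vars,
    requests_per_channel = all_vars
  )
}

#' Generate one of the twelve monitoring reports
#'
#' Collects the variables the report mapping marks for `kind` from the
#' channel store (default window: the last three days of stored data), and
#' augments the derived-marker reports: the temperature-difference report
#' adds the computed `DTla` series and its stress classification, the VPD
#' report adds the computed VPD (kPa) series.  A mapped variable with no
#' stored data yields an explicit all-NA column and an entry in the
#' `missing` attribute -- never a silent omission.
#'
#' @param kind one of `ambient`, `crop`, `difference_temperature`,
#'   `luminosity`, `solution`, `reservoir`, `inspection`, `vpd`,
#'   `solution_parameters`, `crop_parameters`, `requests_per_hour`,
#'   `requests_per_channel`.
#' @param store a [channel_store()] laid out as [default_deployment()].
#' @param window optional `c(start, end)` POSIXct; default: last 3 days.
#' @param rh_source humidity fed to the VPD computation, `"ambient"` or
#'   `"crop"`.
#' @return data.frame report (for the request-counter kinds, the counter
#'   table), with attributes `kind` and `missing`.
#' @export
generate_report <- function(kind, store, window = NULL,
                            rh_source = c("ambient", "crop")) {
  if (length(kind) != 1 || !(kind %in% .report_kinds)) {
    stop_arg("unknown report kind: ", paste(kind, collapse = ", "),
             " (expected one of ", paste(.report_kinds, collapse = ", "), ")")
  }
  rh_source <- match.arg(rh_source)
  if (is.null(window)) {
    # last three days of stored data
    t_all <- unlist(lapply(names(store$channels),
                           function(nm) as.numeric(channel_data(store, nm)$t)))
    t_max <- if (length(t_all)) max(t_all) else as.numeric(Sys.time())
    window <- as.POSIXct(c(t_max - 3 * 86400, t_max + 1), origin = "1970-01-01", tz = "UTC")
  }

  if (kind == "requests_per_hour") {
    out <- request_counters(store, window)$per_hour
    attr(out, "kind") <- kind; attr(out, "missing") <- character(0)
    return(out)
  }
  if (kind == "requests_per_channel") {
    out <- request_counters(store, window)$per_channel
    attr(out, "kind") <- kind; attr(out, "missing") <- character(0)
    return(out)
  }

  vars <- report_variable_map()[[kind]]
  missing_vars <- character(0)
  pieces <- list()
  for (v in vars) {
    loc <- .var_location[[v]]
    d <- if (loc[1] %in% names(store$channels)) {
      channel_data(store, loc[1], window)
    } else {
      NULL
    }
    if (is.null(d) || nrow(d) == 0 || all(is.na(d[[loc[2]]]))) {
      missing_vars <- c(missing_vars, v)
      pieces[[v]] <- NULL
    } else {
      pieces[[v]] <- stats::setNames(d[c("t", loc[2])], c("t", v))
    }
  }
  out <- NULL
  for (v in names(pieces)) {
    out <- if (is.null(out)) pieces[[v]] else merge(out, pieces[[v]], by = "t", all = TRUE)
  }
  if (is.null(out)) {
    out <- data.frame(t = as_time(character(0)))
  }
  for (v in missing_vars) out[[v]] <- rep(NA_real_, nrow(out))
  out <- out[c("t", vars)]

  # derived markers
  env <- channel_data(store, "environmental", window)
  if (kind == "difference_temperature" && nrow(out)) {
    idx <- match(as.numeric(out$t), as.numeric(env$t))
    Tc <- env$Tc[idx]; Ta <- env$Ta_htu[idx]
    out$DTla <- dtla(Tc, Ta)
    out$stress_dtla <- classify_dtla(out$DTla)
  }
  if (kind == "vpd" && nrow(out)) {
    idx <- match(as.numeric(out$t), as.numeric(env$t))
    Tc <- env$Tc[idx]; Ta <- env$Ta_htu[idx]
    RH <- if (rh_source == "crop") env$RHc[idx] else env$RHa[idx]
    out$VPD <- vpd_kpa(Tc, Ta, RH)
    out$stress_vpd <- classify_vpd(out$VPD)
  }
  rownames(out) <- NULL
  attr(out, "kind") <- kind
  attr(out, "missing") <- missing_vars
  out
}

#' Record a manual measurement
#'
#' Validates a manual crop/solution record (pH, electrical conductivity,
#' fresh weight, leaf dimensions, and the readjustment doses of nitric acid
#' and stock solutions A/B) and appends it to the manual-measurements
#' channel under the store's quota policy.  Validation reports every
#' offending field at once.
#'
#' @param rec named list or one-row data.frame with `t` and any of `pH`
#'   (in (0, 14)), `EC`, `Fw`, `L_l`, `W_l`, `HNO3`, `A_sol`, `B_sol` (all
#'   non-negative).
#' @param store a [channel_store()] with a `manual` channel.
#' @return the [channel_write()] result.
#' @export
record_manual <- function(rec, store) {
  rec <- as.list(rec)
  if (is.null(rec$t)) stop_arg("manual record needs a timestamp 't'")
  fields <- c("pH", "EC", "Fw", "L_l", "W_l", "HNO3", "A_sol", "B_sol")
  bad <- character(0)
  if (!is.null(rec$pH) && !is.na(rec$pH) && (rec$pH <= 0 || rec$pH >= 14)) {
    bad <- c(bad, "pH (must be in (0, 14))")
  }
  for (f in setdiff(fields, "pH")) {
    if (!is.null(rec[[f]]) && !is.na(rec[[f]]) && rec[[f]] < 0) {
      bad <- c(bad, paste0(f, " (must be non-negative)"))
    }
  }
  if (length(bad)) {
    stop_arg("invalid manual record: ", paste(bad, collapse = "; "))
  }
  values <- unlist(rec[intersect(fields, names(rec))])
  channel_write(store, "manual", rec$t, values)
}
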