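#' Simulation configuration for the synthetic greenhouse
#'
#' Bundles every tunable of the synthetic device layer: the diurnal climate
#' ranges, the nutrient-tank geometry and pump rates, noise levels, and the
#' root seed.  Defaults are the deployment the monitoring system describes:
#' the observed climate extrema of a seven-day lettuce run (ambient
#' temperature 6.47--34.19 degC peaking at 12:52, relative humidity
#' 5.87--97.43 %, luminosity up to 9118 lux peaking at 12:23, crop-air
#' temperature difference between -4.63 and +0.24 degC), an 83.5 L main tank
#' charged with 50 L of nutrient solution, a 21.5 L recirculation tank and a
#' 160 L/h mixing pump.
#'
#' @param t_start,t_end simulation window (POSIXct or parseable string).
#'   Samples are produced on the half-open interval `[t_start, t_end)` so one
#'   day at the default 30 s step yields exactly 2880 samples.
#' @param step_s sampling cadence in seconds (default 30).
#' @param Ta_min,Ta_max ambient temperature range, degC.
#' @param RHa_min,RHa_max ambient relative humidity range, percent.
#' @param Lum_max peak luminosity, lux.
#' @param peak_time_Ta,trough_time_Ta clock times ("HH:MM") at which ambient
#'   temperature attains its maximum and minimum.
#' @param peak_time_Lum clock time of peak luminosity.
#' @param daylight_start,daylight_end clock times bounding the daylight
#'   window; luminosity is zero outside it.
#' @param dtla_min,dtla_max band (degC) within which the crop-air temperature
#'   difference is generated.
#' @param noise_sd named numeric vector of gaussian noise standard deviations
#'   for streams `Ta`, `RHa`, `RHc`, `Lum`, `Tsol`, `Tres`.  Unnamed entries
#'   fall back to defaults; set all to 0 for noiseless curves.
#' @param main_tank_capacity_l,recirc_tank_capacity_l tank capacities, liters.
#' @param L_sol0,L_res0 initial tank levels, liters.
#' @param irrigation_flow_l_per_h sprinkler draw while irrigating, L/h.  The
#'   per-sprinkler flow is not specified by the deployment; the default 6 L/h
#'   is a free parameter.
#' @param return_fraction fraction of irrigated volume that drains back into
#'   the recirculation tank (0--1).
#' @param mix_pump_flow_l_per_h recirculation transfer pump flow, L/h
#'   (default 160).
#' @param uptake_l_per_h constant plant uptake / evaporative loss, L/h,
#'   tracked in an explicit accumulator so that mass conservation is testable
#'   (default 0).
#' @param recirc_threshold_l level above which the recirculation pump switches
#'   on (default 16 L).
#' @param recirc_low_setpoint_l hysteresis low setpoint at which it switches
#'   back off (default 0.5 L).
#' @param mix_time_s how long the mixing pump runs after a transfer, seconds.
#' @param tank_tau_s first-order time constant coupling tank temperatures to
#'   ambient temperature, seconds.
#' @param seed integer root seed; every random stream derives its own seed
#'   from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_greenhouse()], [step_tanks()], [fault_plan()]
#' @export
sim_config <- function(t_start = "2021-11-01 00:00:00",
                       t_end = "2021-11-02 00:00:00",
                       step_s = 30,
                       Ta_min = 6.47, Ta_max = 34.19,
                       RHa_min = 5.87, RHa_max = 97.43,
                       Lum_max = 9118,
                       peak_time_Ta = "12:52", trough_time_Ta = "07:01",
                       peak_time_Lum = "12:23",
                       daylight_start = "06:30", daylight_end = "19:00",
                       dtla_min = -4.63, dtla_max = 0.24,
                       noise_sd = NULL,
                       main_tank_capacity_l = 83.5,
                       recirc_tank_capacity_l = 21.5,
                       L_sol0 = 50, L_res0 = 0,
                       irrigation_flow_l_per_h = 6,
                       return_fraction = 0.95,
                       mix_pump_flow_l_per_h = 160,
                       uptake_l_per_h = 0,
                       recirc_threshold_l = 16,
                       recirc_low_setpoint_l = 0.5,
                       mix_time_s = 120,
                       tank_tau_s = 3600,
                       seed = 1L) {
  noise_default <- c(Ta = 0.3, RHa = 2, RHc = 2, dtla = 0.15, Lum = 100,
                     Tsol = 0.2, Tres = 0.2)
  if (!is.null(noise_sd)) {
    if (is.null(names(noise_sd)) && length(noise_sd) == 1) {
      noise_default[] <- noise_sd
    } else {
      bad <- setdiff(names(noise_sd), names(noise_default))
      if (length(bad)) stop_arg("unknown noise_sd entries: ", paste(bad, collapse = ", "))
      noise_default[names(noise_sd)] <- noise_sd
    }
  }
  cfg <- list(
    t_start = as_time(t_start), t_end = as_time(t_end), step_s = step_s,
    Ta_min = Ta_min, Ta_max = Ta_max, RHa_min = RHa_min, RHa_max = RHa_max,
    Lum_max = Lum_max,
    peak_time_Ta = tod_seconds(peak_time_Ta),
    trough_time_Ta = tod_seconds(trough_time_Ta),
    peak_time_Lum = tod_seconds(peak_time_Lum),
    daylight_start = tod_seconds(daylight_start),
    daylight_end = tod_seconds(daylight_end),
    dtla_min = dtla_min, dtla_max = dtla_max,
    noise_sd = noise_default,
    main_tank_capacity_l = main_tank_capacity_l,
    recirc_tank_capacity_l = recirc_tank_capacity_l,
    L_sol0 = L_sol0, L_res0 = L_res0,
    irrigation_flow_l_per_h = irrigation_flow_l_per_h,
    return_fraction = return_fraction,
    mix_pump_flow_l_per_h = mix_pump_flow_l_per_h,
    uptake_l_per_h = uptake_l_per_h,
    recirc_threshold_l = recirc_threshold_l,
    recirc_low_setpoint_l = recirc_low_setpoint_l,
    mix_time_s = mix_time_s,
    tank_tau_s = tank_tau_s,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!(Ta_min < Ta_max)) stop_arg("sim_config: Ta_min must be < Ta_max")
    if (!(0 <= RHa_min && RHa_min < RHa_max && RHa_max <= 100)) {
      stop_arg("sim_config: need 0 <= RHa_min < RHa_max <= 100")
    }
    if (!(step_s > 0)) stop_arg("sim_config: step_s must be > 0")
    if (!(return_fraction >= 0 && return_fraction <= 1)) {
      stop_arg("sim_config: return_fraction must be in [0, 1]")
    }
    if (!(main_tank_capacity_l > 0 && recirc_tank_capacity_l > 0)) {
      stop_arg("sim_config: tank capacities must be positive")
    }
    if (!(dtla_min <= dtla_max)) stop_arg("sim_config: dtla_min must be <= dtla_max")
    if (Lum_max < 0) stop_arg("sim_config: Lum_max must be >= 0")
    if (t_end <= t_start) stop_arg("sim_config: t_end must be after t_start")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  window : %s -- %s (step %gs)\n",
              format(x$t_start), format(x$t_end), x$step_s))
  cat(sprintf("  Ta     : %.2f--%.2f degC (peak %s)\n", x$Ta_min, x$Ta_max,
              sprintf("%02d:%02d", x$peak_time_Ta %/% 3600,
                      (x$peak_time_Ta %% 3600) %/% 60)))
  cat(sprintf("  RHa    : %.2f--%.2f %%\n", x$RHa_min, x$RHa_max))
  cat(sprintf("  tanks  : main %.1f L (start %.1f), recirc %.1f L\n",
              x$main_tank_capacity_l, x$L_sol0, x$recirc_tank_capacity_l))
  cat(sprintf("  seed   : %d\n", x$seed))
  invisible(x)
}

#' Fault-injection plan
#'
#' Declares windows during which simulated sensors, fog services or cameras
#' misbehave.  Sensor faults drop the corresponding health-register bit to 0
#' and blank the reading; service faults suppress the service's activity
#' pulses; camera faults fail one camera so the capture status code degrades.
#'
#' @param sensor_faults data.frame with columns `sensor_index` (0--7),
#'   `t_on`, `t_off`.
#' @param service_faults data.frame with columns `service` (one of
#'   `"irrigation"`, `"recirculation"`, `"camera"`, `"sensor"`), `t_on`,
#'   `t_off`.
#' @param camera_faults data.frame with columns `camera` (`"frontal"` or
#'   `"upper"`), `t_on`, `t_off`.
#' @return an object of class `fault_plan`.
#' @export
fault_plan <- function(sensor_faults = NULL, service_faults = NULL,
                       camera_faults = NULL) {
  empty <- function(cols) {
    df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    df
  }
  norm_window <- function(df, keycol, keyvals = NULL, keyint = FALSE) {
    if (is.null(df) || nrow(df) == 0) return(empty(c(keycol, "t_on", "t_off")))
    df <- as.data.frame(df)
    need <- c(keycol, "t_on", "t_off")
    if (!all(need %in% names(df))) {
      stop_arg("fault plan entries need columns: ", paste(need, collapse = ", "))
    }
    df$t_on <- as_time(df$t_on); df$t_off <- as_time(df$t_off)
    if (any(df$t_on >= df$t_off)) stop_arg("fault plan: t_on must be < t_off")
    if (keyint) {
      if (any(df[[keycol]] < 0 | df[[keycol]] > 7)) {
        stop_arg("fault plan: sensor_index must be in [0, 7]")
      }
    } else if (!is.null(keyvals) && !all(df[[keycol]] %in% keyvals)) {
      stop_arg("fault plan: ", keycol, " must be one of ",
               paste(keyvals, collapse = ", "))
    }
    df[need]
  }
  plan <- list(
    sensor_faults = norm_window(sensor_faults, "sensor_index", keyint = TRUE),
    service_faults = norm_window(service_faults, "service",
                                 c("irrigation", "recirculation", "camera", "sensor")),
    camera_faults = norm_window(camera_faults, "camera", c("frontal", "upper"))
  )
  class(plan) <- "fault_plan"
  plan
}

in_window <- function(t, df) {
  if (nrow(df) == 0) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(df))) {
    out <- out | (t >= df$t_on[i] & t < df$t_off[i])
  }
  out
}

#' Read and write simulation configuration as JSON
#'
#' @param cfg a [sim_config()] object.
#' @param path file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- unclass(cfg)
  out$t_start <- format(cfg$t_start, "%Y-%m-%dT%H:%M:%S")
  out$t_end <- format(cfg$t_end, "%Y-%m-%dT%H:%M:%S")
  out$noise_sd <- as.list(cfg$noise_sd)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$t_start <- as_time(sub("T", " ", raw$t_start))
  raw$t_end <- as_time(sub("T", " ", raw$t_end))
  raw$noise_sd <- unlist(raw$noise_sd)
  # clock-time fields were serialized in seconds already
  do.call(sim_config, raw)
}
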