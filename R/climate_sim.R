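#' Actuator state snapshot
#'
#' On/off state of the irrigation, recirculation and mixing pumps plus the
#' camera status code (3 both cameras ok, 2 upper-camera flaw, 1
#' frontal-camera flaw, 0 camera service down, NA no scheduled capture).
#'
#' @param S_irr,S_res,S_mix logical pump states.
#' @param S_cam integer status code in `{0, 1, 2, 3}` or NA.
#' @return an `actuator_state` list.
#' @export
actuator_state <- function(S_irr = FALSE, S_res = FALSE, S_mix = FALSE,
                           S_cam = NA_integer_) {
  if (!is.na(S_cam) && !(S_cam %in% 0:3)) stop_arg("S_cam must be in {0,1,2,3} or NA")
  structure(list(S_irr = isTRUE(S_irr), S_res = isTRUE(S_res),
                 S_mix = isTRUE(S_mix), S_cam = S_cam),
            class = "actuator_state")
}

# Piecewise half-cosine diurnal curve attaining vmax exactly at `peak` and
# vmin exactly at `trough` (seconds of day).  Smooth, periodic, and free of
# the 12 h peak/trough spacing a plain sinusoid would force.
diurnal_curve <- function(tod, vmin, vmax, peak, trough) {
  rise <- (peak - trough) %% 86400
  fall <- 86400 - rise
  s <- (tod - trough) %% 86400
  up <- s <= rise
  frac <- ifelse(up, s / rise, (s - rise) / fall)
  shape <- ifelse(up, (1 - cos(pi * frac)) / 2, (1 + cos(pi * frac)) / 2)
  vmin + (vmax - vmin) * shape
}

# Daylight arch in [0, 1]: zero outside the daylight window, rising to 1 at
# `peak` by half-cosines anchored at the window edges.
daylight_arch <- function(tod, start, end, peak) {
  out <- numeric(length(tod))
  inside <- tod >= start & tod <= end
  rising <- inside & tod <= peak
  falling <- inside & tod > peak
  out[rising] <- (1 - cos(pi * (tod[rising] - start) / (peak - start))) / 2
  out[falling] <- (1 + cos(pi * (tod[falling] - peak) / (end - peak))) / 2
  out
}

#' Simulate greenhouse climate and nutrient-tank telemetry
#'
#' The synthetic device layer.  Ambient temperature follows a smooth
#' piecewise-cosine diurnal curve attaining `Ta_max` at `peak_time_Ta` and
#' `Ta_min` at `trough_time_Ta`; ambient humidity is anti-correlated with
#' temperature within its configured range; crop temperature is ambient plus
#' a bounded leaf-to-air offset that dips during daylight (transpirative
#' cooling); luminosity is a daylight arch peaking at `peak_time_Lum` and
#' zero at night.  Tank levels integrate the irrigation draw, the
#' return-drain into the recirculation tank and the threshold-triggered
#' transfer pump; tank temperatures relax toward ambient.  All noise streams
#' derive independent seeds from `config$seed`, so output is bit-identical
#' for identical inputs.
#'
#' @param config a [sim_config()].
#' @param faults a [fault_plan()]; service faults suppress autonomous
#'   actuator activity, camera faults degrade the capture status code.
#' @param actuator_log optional data.frame (`t`, `S_irr`, `S_res`, `S_mix`)
#'   overriding the autonomous services; must cover the simulation grid.
#' @param irrigation an [irrigation_config()] driving the autonomous
#'   irrigation service (default: every 24 min, 30 s on).
#' @param schedule a [camera_schedule()] for the autonomous camera service.
#' @return list with elements `climate` (data.frame `t`, `Ta`, `RHa`, `Tc`,
#'   `RHc`, `Lum`), `tanks` (`t`, `T_sol`, `L_sol`, `T_res`, `L_res`,
#'   `loss_l` cumulative uptake/loss accumulator), `actuators` (`t`,
#'   `S_irr`, `S_res`, `S_mix`, `S_cam`), plus the `config` and `faults`
#'   used.
#' @export
simulate_greenhouse <- function(config = sim_config(), faults = fault_plan(),
                                actuator_log = NULL,
                                irrigation = irrigation_config(),
                                schedule = camera_schedule()) {
  validate_sim_config(config)
  n <- floor(as.numeric(config$t_end - config$t_start, units = "secs") / config$step_s)
  if (n < 1) stop_arg("simulation window shorter than one step")
  t <- config$t_start + (seq_len(n) - 1) * config$step_s
  tod <- tod_of(t)
  ns <- config$noise_sd

  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

  Ta_base <- diurnal_curve(tod, config$Ta_min, config$Ta_max,
                           config$peak_time_Ta, config$trough_time_Ta)
  Ta <- clamp(Ta_base + with_stream_seed(config$seed, "ta", stats::rnorm(n, 0, ns[["Ta"]])),
              config$Ta_min, config$Ta_max)

  rh_base <- config$RHa_max - (config$RHa_max - config$RHa_min) *
    (Ta_base - config$Ta_min) / (config$Ta_max - config$Ta_min)
  RHa <- clamp(rh_base + with_stream_seed(config$seed, "rha", stats::rnorm(n, 0, ns[["RHa"]])),
               config$RHa_min, config$RHa_max)

  arch <- daylight_arch(tod, config$daylight_start, config$daylight_end,
                        config$peak_time_Lum)
  d_base <- config$dtla_max - (config$dtla_max - config$dtla_min) * arch
  d <- clamp(d_base + with_stream_seed(config$seed, "dtla", stats::rnorm(n, 0, ns[["dtla"]])),
             config$dtla_min, config$dtla_max)
  Tc <- Ta + d

  RHc <- clamp(RHa + with_stream_seed(config$seed, "rhc", stats::rnorm(n, 0, ns[["RHc"]])),
               0, 100)

  Lum <- clamp(arch * config$Lum_max +
                 ifelse(arch > 0, with_stream_seed(config$seed, "lum",
                                                   stats::rnorm(n, 0, ns[["Lum"]])), 0),
               0, config$Lum_max)

  climate <- data.frame(t = t, Ta = Ta, RHa = RHa, Tc = Tc, RHc = RHc, Lum = Lum)

  # ---- actuators --------------------------------------------------------
  if (is.null(actuator_log)) {
    days <- unique(day_index(t))
    ev <- do.call(rbind, lapply(days, function(d0) {
      plan_irrigation(irrigation, as.POSIXct(d0 * 86400, origin = "1970-01-01", tz = "UTC"))
    }))
    irr_fault <- faults$service_faults[faults$service_faults$service == "irrigation", ]
    if (nrow(irr_fault) && nrow(ev)) {
      keep <- !in_window(ev$t_on, irr_fault)
      ev <- ev[keep, , drop = FALSE]
    }
    S_irr <- rep(FALSE, n)
    if (nrow(ev)) {
      for (i in seq_len(nrow(ev))) {
        S_irr <- S_irr | (t >= ev$t_on[i] & t < ev$t_off[i])
      }
    }
    S_res <- S_mix <- rep(FALSE, n)
    S_cam <- rep(NA_integer_, n)
  } else {
    actuator_log <- as.data.frame(actuator_log)
    if (nrow(actuator_log) < n) stop_arg("actuator_log does not cover the simulation window")
    S_irr <- rep_len(as.logical(actuator_log$S_irr), n)
    S_res <- rep_len(as.logical(actuator_log$S_res), n)
    S_mix <- rep_len(as.logical(actuator_log$S_mix %||% FALSE), n)
    S_cam <- rep(NA_integer_, n)
  }

  res_fault <- faults$service_faults[faults$service_faults$service == "recirculation", ]
  cam_service_fault <- faults$service_faults[faults$service_faults$service == "camera", ]
  frontal_fault <- faults$camera_faults[faults$camera_faults$camera == "frontal", ]
  upper_fault <- faults$camera_faults[faults$camera_faults$camera == "upper", ]
  res_faulted <- in_window(t, res_fault)
  cam_service_ok <- !in_window(t, cam_service_fault)
  frontal_ok <- !in_window(t, frontal_fault)
  upper_ok <- !in_window(t, upper_fault)

  # ---- tank integration -------------------------------------------------
  temp_noise <- with_stream_seed(config$seed, "tanks",
                                 matrix(stats::rnorm(2 * n, 0, c(ns[["Tsol"]], ns[["Tres"]])),
                                        nrow = n, byrow = TRUE))
  state <- list(t = t[1], T_sol = Ta[1], L_sol = config$L_sol0,
                T_res = Ta[1], L_res = config$L_res0, loss_l = 0)
  pump_on <- FALSE
  mix_until <- -Inf
  T_sol <- L_sol <- T_res <- L_res <- loss <- numeric(n)
  for (i in seq_len(n)) {
    if (is.null(actuator_log)) {
      want_on <- reservoir_service(state$L_res, pump_on,
                                   threshold_l = config$recirc_threshold_l,
                                   low_setpoint_l = config$recirc_low_setpoint_l)
      if (res_faulted[i]) want_on <- FALSE
      if (pump_on && !want_on) mix_until <- as.numeric(t[i]) + config$mix_time_s
      pump_on <- want_on
      S_res[i] <- pump_on
      S_mix[i] <- !pump_on && as.numeric(t[i]) < mix_until
    }
    # camera service pulse (status only; captures handled by camera_service)
    cam <- camera_service(schedule, t[i],
                          camera_health = c(frontal = frontal_ok[i], upper = upper_ok[i]),
                          service_up = cam_service_ok[i])
    S_cam[i] <- cam$status

    act <- actuator_state(S_irr[i], S_res[i], S_mix[i], S_cam[i])
    state <- step_tanks(state, act, config$step_s, config, ambient_T = Ta[i])
    T_sol[i] <- state$T_sol + temp_noise[i, 1]
    L_sol[i] <- state$L_sol
    T_res[i] <- state$T_res + temp_noise[i, 2]
    L_res[i] <- state$L_res
    loss[i] <- state$loss_l
  }

  list(
    climate = climate,
    tanks = data.frame(t = t, T_sol = T_sol, L_sol = L_sol,
                       T_res = T_res, L_res = L_res, loss_l = loss),
    actuators = data.frame(t = t, S_irr = S_irr, S_res = S_res,
                           S_mix = S_mix, S_cam = S_cam),
    config = config, faults = faults
  )
}

#' Advance the nutrient-tank state by one time step
#'
#' Volume bookkeeping for the two-tank aeroponic loop: while irrigating, the
#' main tank drains at the sprinkler flow and `return_fraction` of the drawn
#' volume collects in the recirculation tank; while the recirculation pump
#' runs, solution transfers back to the main tank at the 160 L/h mixing-pump
#' flow.  Transfers are limited by source volume and destination headroom, so
#' total liquid is conserved exactly: `L_sol + L_res + loss_l` is invariant,
#' where `loss_l` accumulates plant uptake, the non-returned irrigation
#' fraction and any overflow.
#'
#' @param state list with `t`, `T_sol`, `L_sol`, `T_res`, `L_res`, `loss_l`.
#' @param actuators an [actuator_state()].
#' @param dt_s time step in seconds (> 0).
#' @param config a [sim_config()] supplying flows and capacities.
#' @param ambient_T optional ambient temperature (degC) toward which tank
#'   temperatures relax with time constant `config$tank_tau_s`; if `NULL`,
#'   temperatures are left untouched.
#' @return the updated state list.
#' @export
step_tanks <- function(state, actuators, dt_s, config, ambient_T = NULL) {
  if (!is.numeric(dt_s) || dt_s <= 0) stop_arg("dt_s must be a positive number")
  L_sol <- state$L_sol; L_res <- state$L_res; loss <- state$loss_l %||% 0

  if (isTRUE(actuators$S_irr)) {
    take <- min(config$irrigation_flow_l_per_h * dt_s / 3600, L_sol)
    L_sol <- L_sol - take
    ret <- config$return_fraction * take
    to_res <- min(ret, config$recirc_tank_capacity_l - L_res)
    L_res <- L_res + to_res
    loss <- loss + (take - to_res)
  }
  if (isTRUE(actuators$S_res)) {
    m <- min(config$mix_pump_flow_l_per_h * dt_s / 3600, L_res,
             config$main_tank_capacity_l - L_sol)
    L_res <- L_res - m
    L_sol <- L_sol + m
  }
  if (config$uptake_l_per_h > 0) {
    u <- min(config$uptake_l_per_h * dt_s / 3600, L_sol)
    L_sol <- L_sol - u
    loss <- loss + u
  }

  T_sol <- state$T_sol; T_res <- state$T_res
  if (!is.null(ambient_T)) {
    a <- min(dt_s / config$tank_tau_s, 1)
    T_sol <- T_sol + a * (ambient_T - T_sol)
    T_res <- T_res + a * (ambient_T - T_res)
  }

  list(t = state$t + dt_s, T_sol = T_sol, L_sol = L_sol,
       T_res = T_res, L_res = L_res, loss_l = loss)
}
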