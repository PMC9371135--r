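# Fog-layer microservices: irrigation and camera scheduling, reservoir
# hysteresis, sensor polling/packing, failure detection and alerts.

.env_fields <- c("Ta_htu", "Ta_mlx", "Tc", "RHa", "RHc", "Lum", "T_res", "L_res")

#' Irrigation service configuration
#'
#' Sprinklers switch on every `frequency_min` minutes for `on_time_s`
#' seconds, around the clock.  A daytime window may override both settings
#' (outside it the base/night values apply).  The default is the deployment
#' schedule: every 24 min day and night with a 30 s activation.
#'
#' @param frequency_min minutes between activations.
#' @param on_time_s seconds each activation lasts; must be shorter than the
#'   period.
#' @param day_window optional `c(start, end)` clock times ("HH:MM") of the
#'   daytime regime.
#' @param day_frequency_min,day_on_time_s optional daytime overrides.
#' @return an `irrigation_config` list.
#' @export
irrigation_config <- function(frequency_min = 24, on_time_s = 30,
                              day_window = NULL,
                              day_frequency_min = NULL, day_on_time_s = NULL) {
  check <- function(f, s, what) {
    if (!(s > 0 && f * 60 > s)) {
      stop_arg("irrigation_config: need 0 < on_time_s < frequency_min*60 (", what, ")")
    }
  }
  check(frequency_min, on_time_s, "base")
  if (!is.null(day_window)) {
    day_window <- tod_seconds(day_window)
    if (length(day_window) != 2 || day_window[1] >= day_window[2]) {
      stop_arg("irrigation_config: day_window must be two increasing clock times")
    }
    check(day_frequency_min %||% frequency_min, day_on_time_s %||% on_time_s, "day")
  }
  structure(list(frequency_min = frequency_min, on_time_s = on_time_s,
                 day_window = day_window,
                 day_frequency_min = day_frequency_min,
                 day_on_time_s = day_on_time_s),
            class = "irrigation_config")
}

#' Plan one day of irrigation events
#'
#' Events are anchored at the start of the day (first activation at offset
#' 0) and repeat at the regime's period; inside the daytime window the day
#' overrides apply.  A uniform period that divides 24 h yields exactly
#' `1440 / frequency_min` activations.
#'
#' @param config an [irrigation_config()].
#' @param day a `Date` or midnight POSIXct anchoring the plan.
#' @return data.frame with POSIXct columns `t_on`, `t_off`.
#' @export
plan_irrigation <- function(config = irrigation_config(), day = Sys.Date()) {
  if (!inherits(config, "irrigation_config")) stop_arg("config must be an irrigation_config")
  day0 <- if (inherits(day, "Date")) {
    as.POSIXct(as.numeric(day) * 86400, origin = "1970-01-01", tz = "UTC")
  } else {
    as_time(day)
  }
  regime <- function(tod) {
    if (!is.null(config$day_window) &&
        tod >= config$day_window[1] && tod < config$day_window[2]) {
      c(config$day_frequency_min %||% config$frequency_min,
        config$day_on_time_s %||% config$on_time_s)
    } else {
      c(config$frequency_min, config$on_time_s)
    }
  }
  cur <- 0
  t_on <- t_off <- numeric(0)
  while (cur < 86400) {
    r <- regime(cur)
    t_on <- c(t_on, cur)
    t_off <- c(t_off, cur + r[2])
    cur <- cur + r[1] * 60
  }
  data.frame(t_on = day0 + t_on, t_off = day0 + t_off)
}

#' Reservoir (recirculation) service decision
#'
#' The transfer pump switches on when the recirculation-tank level strictly
#' exceeds `threshold_l` (16 L in the deployment) and, once running, stays
#' on until the level falls to `low_setpoint_l` (hysteresis; the deployment
#' states only the turn-on threshold, the low setpoint is this package's
#' own, configurable).
#'
#' @param level_l current recirculation-tank level, liters (>= 0).
#' @param pump_on is the pump currently running?
#' @param threshold_l turn-on threshold, liters.
#' @param low_setpoint_l hysteresis low setpoint, liters.
#' @return logical: should the pump run during the next interval?
#' @export
reservoir_service <- function(level_l, pump_on = FALSE,
                              threshold_l = 16, low_setpoint_l = 0.5) {
  if (any(level_l < 0)) stop_arg("level_l must be >= 0")
  if (isTRUE(pump_on)) level_l > low_setpoint_l else level_l > threshold_l
}

#' Camera capture schedule
#'
#' Ordered clock times at which the camera service attempts a frontal and an
#' upper capture.  The default is the deployment's nine daily shots.
#'
#' @param capture_times character vector of strictly increasing clock times.
#' @return a `camera_schedule` object (seconds-of-day vector).
#' @export
camera_schedule <- function(capture_times = c("06:00", "07:00", "08:00",
                                              "11:00", "12:00", "13:00",
                                              "17:30", "18:30", "19:30")) {
  s <- tod_seconds(capture_times)
  if (length(s) && any(diff(s) <= 0)) {
    stop_arg("camera_schedule: capture times must be strictly increasing")
  }
  structure(s, class = "camera_schedule")
}

#' Camera service tick
#'
#' At a scheduled time, attempts captures from both cameras and emits a
#' status pulse: 3 both succeeded (normal operation), 2 upper-camera flaw,
#' 1 frontal-camera flaw, 0 service down (or both cameras dead).  Between
#' scheduled times no pulse is emitted (`status` NA) -- failure of the whole
#' service shows up downstream as pulse absence.
#'
#' @param schedule a [camera_schedule()].
#' @param t current timestamp.
#' @param camera_health named logical vector `c(frontal = , upper = )`.
#' @param service_up is the camera service itself running?
#' @param tol_s schedule-matching tolerance in seconds (default: half the
#'   default 30 s tick).
#' @return list with `captures` (character subset of `c("frontal",
#'   "upper")`) and `status` (integer or NA off-schedule).
#' @export
camera_service <- function(schedule, t, camera_health = c(frontal = TRUE, upper = TRUE),
                           service_up = TRUE, tol_s = 15) {
  tod <- tod_of(as_time(t))
  scheduled <- length(schedule) && any(abs(tod - unclass(schedule)) < tol_s)
  if (!scheduled) return(list(captures = character(0), status = NA_integer_))
  if (!isTRUE(service_up)) return(list(captures = character(0), status = 0L))
  frontal <- isTRUE(camera_health[["frontal"]])
  upper <- isTRUE(camera_health[["upper"]])
  status <- if (frontal && upper) 3L else if (!upper && frontal) 2L
            else if (!frontal && upper) 1L else 0L
  list(captures = c("frontal", "upper")[c(frontal, upper)], status = status)
}

#' Poll the environmental sensors into one packed channel write
#'
#' The sensor service groups the eight environmental-channel readings into a
#' single packed write and encodes the per-sensor success flags into the
#' health register: failed sensors contribute a missing value (NA, never 0)
#' and a 0 bit.
#'
#' @param values named numeric vector of exactly the eight environmental
#'   fields (`Ta_htu`, `Ta_mlx`, `Tc`, `RHa`, `RHc`, `Lum`, `T_res`,
#'   `L_res`).
#' @param sensor_health logical vector of length 8, one flag per field in
#'   the same order (bit 0 = first field).
#' @return list with `values` (readings, NA where failed), `register`
#'   (integer 0--255) and `flags`.
#' @export
sensor_service_poll <- function(values, sensor_health = rep(TRUE, 8)) {
  if (length(values) != 8) {
    stop_arg("environmental channel is packed as exactly 8 fields, got ", length(values))
  }
  if (is.null(names(values))) names(values) <- .env_fields
  if (!identical(names(values), .env_fields)) {
    stop_arg("values must be named with the environmental fields in order: ",
             paste(.env_fields, collapse = ", "))
  }
  if (length(sensor_health) != 8) stop_arg("sensor_health must have length 8")
  out <- values
  out[!sensor_health] <- NA_real_
  list(values = out, register = encode_health(sensor_health),
       flags = as.logical(sensor_health))
}

#' Detect service, sensor and camera failures from status telemetry
#'
#' Mirrors the visual diagnostics of the services channel: a service has
#' failed when no pulse appears within `miss_factor` times its expected
#' period (pulse absence); sensor `k` is flagged when its health-register
#' bit sits at 0 in at least `theta` of the samples in the window ("a bit
#' frequently remains on 0"); a camera flaw is reported when the capture
#' status stagnates at 2 (upper) or 1 (frontal) for `stagnation_n`
#' consecutive pulses.
#'
#' @param pulses data.frame with columns `service`, `t` and optionally
#'   `value` (required for the camera status codes).
#' @param register data.frame with columns `t`, `value` (health-register
#'   series), or NULL to skip sensor checks.
#' @param expectations named list, one entry per service appearing in
#'   `pulses` (and for every service that should be pulsing), each either
#'   `list(period_s = ...)` or, for the camera service, `list(schedule =
#'   camera_schedule())` whose median spacing defines the expected period.
#' @param window `c(start, end)` POSIXct analysis window.
#' @param miss_factor multiple of the expected period beyond which silence
#'   is a failure (default 2).
#' @param theta zero-bit fraction at or above which a sensor is flagged
#'   (default 0.5).
#' @param stagnation_n consecutive degraded statuses that constitute a
#'   camera flaw (default 2).
#' @return a `failure_report` list: `service_failures` (`service`,
#'   `t_start`, `t_end`), `sensor_failures` (`sensor_index`,
#'   `zero_fraction`), `camera_failures` (`camera`, `t_start`, `t_end`).
#' @export
detect_failures <- function(pulses, register = NULL, expectations,
                            window, miss_factor = 2, theta = 0.5,
                            stagnation_n = 2) {
  pulses <- as.data.frame(pulses)
  window <- as_time(window)
  if (nrow(pulses)) {
    missing_exp <- setdiff(unique(pulses$service), names(expectations))
    if (length(missing_exp)) {
      stop_arg("no expectation configured for service(s): ",
               paste(missing_exp, collapse = ", "))
    }
  }
  service_failures <- data.frame(service = character(0),
                                 t_start = as_time(character(0)),
                                 t_end = as_time(character(0)))
  camera_failures <- data.frame(camera = character(0),
                                t_start = as_time(character(0)),
                                t_end = as_time(character(0)))

  for (svc in names(expectations)) {
    exp_svc <- expectations[[svc]]
    tp <- sort(as.numeric(pulses$t[pulses$service == svc]))
    if (!is.null(exp_svc$period_s)) {
      # periodic service: silence longer than miss_factor periods is a failure
      period <- exp_svc$period_s
      edges <- c(as.numeric(window[1]), tp, as.numeric(window[2]))
      gaps <- diff(edges)
      bad <- which(gaps > miss_factor * period)
      for (b in bad) {
        service_failures <- rbind(service_failures, data.frame(
          service = svc,
          t_start = as.POSIXct(edges[b], origin = "1970-01-01", tz = "UTC"),
          t_end = as.POSIXct(edges[b + 1], origin = "1970-01-01", tz = "UTC")
        ))
      }
    } else if (!is.null(exp_svc$schedule)) {
      # scheduled service (irregular cadence): a run of >= miss_factor
      # consecutive missed scheduled pulses is a failure window
      days <- seq(day_index(window[1]), day_index(window[2] - 1))
      expected <- sort(unlist(lapply(days * 86400, function(d0) d0 + unclass(exp_svc$schedule))))
      expected <- expected[expected >= as.numeric(window[1]) &
                             expected < as.numeric(window[2])]
      missed <- vapply(expected, function(e) !any(abs(tp - e) < 60), logical(1))
      r <- rle(missed)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (j in which(r$values & r$lengths >= miss_factor)) {
        service_failures <- rbind(service_failures, data.frame(
          service = svc,
          t_start = as.POSIXct(expected[starts[j]], origin = "1970-01-01", tz = "UTC"),
          t_end = as.POSIXct(expected[ends[j]], origin = "1970-01-01", tz = "UTC")
        ))
      }
    } else {
      stop_arg("expectation for ", svc, " needs period_s or schedule")
    }
    # camera status stagnation at 2 (upper flaw) or 1 (frontal flaw)
    if (!is.null(exp_svc$schedule) && "value" %in% names(pulses)) {
      sub <- pulses[pulses$service == svc, ]
      sub <- sub[order(sub$t), ]
      for (code in c(2L, 1L)) {
        r <- rle(sub$value == code)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        runs <- which(r$values & r$lengths >= stagnation_n)
        for (j in runs) {
          camera_failures <- rbind(camera_failures, data.frame(
            camera = if (code == 2L) "upper" else "frontal",
            t_start = as_time(sub$t[starts[j]]),
            t_end = as_time(sub$t[ends[j]])
          ))
        }
      }
    }
  }

  sensor_failures <- data.frame(sensor_index = integer(0), zero_fraction = numeric(0))
  if (!is.null(register) && nrow(register)) {
    bits <- vapply(register$value, decode_health, logical(8))  # 8 x n
    zero_frac <- rowMeans(!bits)
    flagged <- which(zero_frac >= theta)
    if (length(flagged)) {
      sensor_failures <- data.frame(sensor_index = flagged - 1L,
                                    zero_fraction = zero_frac[flagged])
    }
  }

  structure(list(service_failures = service_failures,
                 sensor_failures = sensor_failures,
                 camera_failures = camera_failures,
                 window = window),
            class = "failure_report")
}

#' @export
print.failure_report <- function(x, ...) {
  n <- nrow(x$service_failures) + nrow(x$sensor_failures) + nrow(x$camera_failures)
  cat(sprintf("<failure_report> %d finding(s)\n", n))
  if (nrow(x$service_failures)) { cat("service failures:\n"); print(x$service_failures) }
  if (nrow(x$sensor_failures)) { cat("sensor failures:\n"); print(x$sensor_failures) }
  if (nrow(x$camera_failures)) { cat("camera failures:\n"); print(x$camera_failures) }
  invisible(x)
}

#' Alert transport writing JSON-lines to a log file
#'
#' The default pluggable alert sink: each event is appended as one JSON
#' object per line.  The transport carries the set of already-alerted keys,
#' which makes [alert_service()] idempotent, and a retry queue for events
#' whose delivery failed.
#'
#' @param path log file path.
#' @return a transport environment with a `send(event)` function.
#' @export
log_transport <- function(path = tempfile(fileext = ".jsonl")) {
  tr <- new.env(parent = emptyenv())
  tr$path <- path
  tr$seen <- character(0)
  tr$queue <- list()
  tr$send <- function(event) {
    line <- jsonlite::toJSON(event, auto_unbox = TRUE)
    cat(line, "\n", sep = "", file = tr$path, append = TRUE)
    invisible(TRUE)
  }
  class(tr) <- "alert_transport"
  tr
}

#' Dispatch alerts for newly detected failures
#'
#' Emits one alert event per failure in the report that has not been alerted
#' before on this transport (idempotent across repeated identical reports).
#' If delivery throws, the event is queued on the transport and retried on
#' the next call.
#'
#' @param report a `failure_report` from [detect_failures()].
#' @param transport an alert transport such as [log_transport()].
#' @return invisibly, the list of newly emitted alert events (each with `t`,
#'   `service`, `message`, `delivered_via`).
#' @export
alert_service <- function(report, transport = log_transport()) {
  stopifnot(inherits(report, "failure_report"))
  events <- list()
  add <- function(key, service, t, message) {
    if (key %in% transport$seen) return()
    events[[length(events) + 1]] <<- list(
      t = format(as_time(t), "%Y-%m-%dT%H:%M:%S"),
      service = service, message = message,
      delivered_via = class(transport)[1]
    )
    transport$seen <- c(transport$seen, key)
  }
  sf <- report$service_failures
  for (i in seq_len(nrow(sf))) {
    add(sprintf("svc|%s|%s|%s", sf$service[i], sf$t_start[i], sf$t_end[i]),
        sf$service[i], sf$t_start[i],
        sprintf("service '%s' silent from %s to %s",
                sf$service[i], format(sf$t_start[i]), format(sf$t_end[i])))
  }
  sn <- report$sensor_failures
  t_ref <- if (!is.null(report$window)) report$window[1] else Sys.time()
  for (i in seq_len(nrow(sn))) {
    add(sprintf("sensor|%d", sn$sensor_index[i]), "sensor", t_ref,
        sprintf("sensor %d bit at 0 in %.0f%% of samples; possible replacement needed",
                sn$sensor_index[i], 100 * sn$zero_fraction[i]))
  }
  cf <- report$camera_failures
  for (i in seq_len(nrow(cf))) {
    add(sprintf("cam|%s|%s", cf$camera[i], cf$t_start[i]), "camera", cf$t_start[i],
        sprintf("%s camera flaw (status stagnation) from %s",
                cf$camera[i], format(cf$t_start[i])))
  }
  # retry anything previously queued, then deliver new events
  pending <- c(transport$queue, events)
  transport$queue <- list()
  for (ev in pending) {
    ok <- tryCatch({ transport$send(ev); TRUE },
                   error = function(e) {
                     warning("alert delivery failed, queued for retry: ",
                             conditionMessage(e), call. = FALSE)
                     FALSE
                   })
    if (!ok) transport$queue <- c(transport$queue, list(ev))
  }
  invisible(events)
}
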