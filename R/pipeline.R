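#' Run the full monitoring stack end to end
#'
#' Simulates the greenhouse for `days` days, runs the fog services over the
#' simulated telemetry (sensor polling into the environmental channel,
#' service snapshots into the services channel, camera and irrigation
#' pulses), applies the channel store's rate/quota accounting, computes the
#' water-stress markers, detects failures against the injected fault plan,
#' dispatches alerts, generates and enhances a root image, and writes every
#' artifact -- telemetry CSVs, stress CSV, the twelve reports, the alert
#' log and the PNG images -- under `out_dir`.  Deterministic for a given
#' seed.
#'
#' The recirculation pump is intentionally absent from the
#' failure-detection expectations: its cadence depends on how fast the
#' recirculation tank fills (days, at the default irrigation duty cycle),
#' so silence is not evidence of failure.
#'
#' @param config a [sim_config()]; its window is overridden to `days` days
#'   from `t_start`.
#' @param days number of simulated days.
#' @param seed root seed (overrides `config$seed`).
#' @param out_dir artifacts directory (created if needed).
#' @param faults a [fault_plan()].
#' @param irrigation an [irrigation_config()].
#' @param schedule a [camera_schedule()].
#' @param policy a [quota_policy()].
#' @param root_image_px side length of the synthetic root image.
#' @param rh_source humidity source for the VPD markers.
#' @return invisibly, a list: `store` (the channel store), `sim` (simulator
#'   output), `markers`, `failures`, `alerts`, `captures` (per-camera
#'   counts), `out_dir`, `files`.
#' @export
run_pipeline <- function(config = sim_config(), days = 1, seed = config$seed,
                         out_dir = tempfile("aerofog_"),
                         faults = fault_plan(),
                         irrigation = irrigation_config(),
                         schedule = camera_schedule(),
                         policy = quota_policy(),
                         root_image_px = 128,
                         rh_source = c("ambient", "crop")) {
  rh_source <- match.arg(rh_source)
  config$seed <- as.integer(seed)
  config$t_end <- config$t_start + days * 86400
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  keep <- function(p) { files <<- c(files, p); p }

  sim <- simulate_greenhouse(config, faults, irrigation = irrigation,
                             schedule = schedule)
  cl <- sim$climate; tk <- sim$tanks; ac <- sim$actuators
  n <- nrow(cl)
  store <- default_deployment(policy)

  sensor_service_fault <- faults$service_faults[faults$service_faults$service == "sensor", ]
  sensor_down <- in_window(cl$t, sensor_service_fault)
  # per-sensor fault windows -> health flags per step (bit order = env fields)
  health <- matrix(TRUE, n, 8)
  sf <- faults$sensor_faults
  for (i in seq_len(nrow(sf))) {
    k <- sf$sensor_index[i] + 1L
    health[cl$t >= sf$t_on[i] & cl$t < sf$t_off[i], k] <- FALSE
  }

  register <- data.frame(t = cl$t, value = NA_integer_)
  for (i in seq_len(n)) {
    if (sensor_down[i]) next  # sensor service silent: no writes, no register
    poll <- sensor_service_poll(
      c(Ta_htu = cl$Ta[i], Ta_mlx = cl$Ta[i], Tc = cl$Tc[i], RHa = cl$RHa[i],
        RHc = cl$RHc[i], Lum = cl$Lum[i], T_res = tk$T_res[i], L_res = tk$L_res[i]),
      sensor_health = health[i, ]
    )
    channel_write(store, "environmental", cl$t[i], poll$values)
    channel_write(store, "services", cl$t[i],
                  c(T_sol = tk$T_sol[i], L_sol = tk$L_sol[i],
                    S_irr = as.numeric(ac$S_irr[i]), S_res = as.numeric(ac$S_res[i]),
                    S_cam = as.numeric(ac$S_cam[i]),
                    sensor_health = poll$register))
    register$value[i] <- poll$register
  }
  register <- register[!is.na(register$value), ]

  # ---- pulse series for failure detection --------------------------------
  rising <- function(x) which(x & !c(FALSE, x[-length(x)]))
  pulses <- rbind(
    data.frame(service = "irrigation", t = cl$t[rising(ac$S_irr)], value = 1),
    data.frame(service = "sensor", t = register$t, value = 1),
    {
      cam_idx <- which(!is.na(ac$S_cam) & ac$S_cam > 0)  # status 0 = absence
      data.frame(service = "camera", t = cl$t[cam_idx], value = ac$S_cam[cam_idx])
    }
  )
  expectations <- list(
    irrigation = list(period_s = irrigation$frequency_min * 60),
    sensor = list(period_s = config$step_s),
    camera = list(schedule = schedule)
  )
  failures <- detect_failures(pulses, register, expectations,
                              window = c(config$t_start, config$t_end))
  transport <- log_transport(keep(file.path(out_dir, "alerts.jsonl")))
  file.create(transport$path)
  alerts <- alert_service(failures, transport)

  # ---- analytics ---------------------------------------------------------
  markers <- compute_stress_markers(cl, rh_source = rh_source)
  utils::write.csv(markers, keep(file.path(out_dir, "stress_markers.csv")),
                   row.names = FALSE)

  # ---- root imaging ------------------------------------------------------
  truth <- synth_root_image(root_image_px, root_image_px, seed = config$seed)
  enh <- enhance_root(truth$image)
  write_image_png(truth$image, keep(file.path(out_dir, "root_rgb.png")))
  write_mask_png(truth$truth_mask, keep(file.path(out_dir, "root_truth_mask.png")))
  write_mask_png(enh$root_mask, keep(file.path(out_dir, "root_mask.png")))
  write_image_png(enh$rgb_enhanced, keep(file.path(out_dir, "root_rgb_enhanced.png")))
  write_image_png(enh$hsv_enhanced_rgb, keep(file.path(out_dir, "root_hsv_enhanced.png")))

  # ---- telemetry + reports ----------------------------------------------
  for (nm in names(store$channels)) {
    export_channel_csv(store, nm, keep(file.path(out_dir, paste0("channel_", nm, ".csv"))))
  }
  window <- c(config$t_start, config$t_end)
  for (kind in .report_kinds) {
    rep_df <- generate_report(kind, store, window, rh_source = rh_source)
    utils::write.csv(rep_df, keep(file.path(out_dir, paste0("report_", kind, ".csv"))),
                     row.names = FALSE)
  }

  cam_ok <- ac$S_cam[!is.na(ac$S_cam)]
  captures <- c(frontal = sum(cam_ok %in% c(2L, 3L)),
                upper = sum(cam_ok %in% c(1L, 3L)))

  invisible(list(store = store, sim = sim, markers = markers,
                 failures = failures, alerts = alerts, captures = captures,
                 dice = dice_score(enh$root_mask, truth$truth_mask),
                 out_dir = out_dir, files = files))
}
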