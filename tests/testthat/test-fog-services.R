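# Irrigation planning, reservoir hysteresis, camera status codes, sensor
# polling, failure detection and alert idempotency.

test_that("irrigation plans match the deployment cadence and a brute-force oracle", {
  day <- as.Date("2021-11-01")
  ev <- plan_irrigation(irrigation_config(frequency_min = 24, on_time_s = 30), day)
  expect_equal(nrow(ev), 60)  # 1440 / 24
  expect_true(all(as.numeric(ev$t_off - ev$t_on, units = "secs") == 30))
  expect_equal(nrow(plan_irrigation(irrigation_config(frequency_min = 1440), day)), 1)

  for (f in c(10, 16, 24, 48, 96, 160, 360, 720)) {  # divisors of 1440
    got <- nrow(plan_irrigation(irrigation_config(frequency_min = f), day))
    expect_identical(got, oracle_activation_count(f))
    expect_identical(got, as.integer(1440 / f))
  }
  expect_error(irrigation_config(frequency_min = 1, on_time_s = 60), "on_time")
})

test_that("day-window overrides apply inside the window only", {
  cfg <- irrigation_config(frequency_min = 60, on_time_s = 30,
                           day_window = c("06:00", "18:00"),
                           day_frequency_min = 30)
  ev <- plan_irrigation(cfg, as.Date("2021-11-01"))
  tod <- as.numeric(ev$t_on) %% 86400
  # night: hourly; day: every 30 min
  expect_true(all(diff(tod[tod < 6 * 3600]) == 3600))
  inside <- tod >= 6 * 3600 & tod < 18 * 3600
  expect_true(all(diff(tod[inside]) == 1800))
})

test_that("reservoir pump switches strictly above 16 L with hysteresis", {
  expect_false(reservoir_service(15.9, FALSE))
  expect_false(reservoir_service(16.0, FALSE))
  expect_true(reservoir_service(16.1, FALSE))
  expect_true(reservoir_service(10, TRUE))    # running, above low setpoint
  expect_true(reservoir_service(0.6, TRUE))
  expect_false(reservoir_service(0.5, TRUE))  # reached low setpoint
  expect_false(reservoir_service(0.4, TRUE))
  expect_error(reservoir_service(-1), ">= 0")
})

test_that("camera service emits the documented status codes and only on schedule", {
  sch <- camera_schedule()
  at <- t_day("12:00:00")
  expect_identical(camera_service(sch, at)$status, 3L)
  expect_identical(camera_service(sch, at, c(frontal = TRUE, upper = FALSE))$status, 2L)
  expect_identical(camera_service(sch, at, c(frontal = FALSE, upper = TRUE))$status, 1L)
  expect_identical(camera_service(sch, at, service_up = FALSE)$status, 0L)
  off <- camera_service(sch, t_day("12:07:00"))
  expect_identical(off$status, NA_integer_)
  expect_length(off$captures, 0)
  expect_setequal(camera_service(sch, at)$captures, c("frontal", "upper"))
  expect_identical(camera_service(sch, at, c(frontal = TRUE, upper = FALSE))$captures, "frontal")
  expect_error(camera_schedule(c("08:00", "07:00")), "increasing")
})

test_that("sensor polling packs eight fields and encodes failures as NA plus a 0 bit", {
  vals <- c(Ta_htu = 20, Ta_mlx = 20.2, Tc = 19, RHa = 55, RHc = 57,
            Lum = 4000, T_res = 18, L_res = 3)
  ok <- sensor_service_poll(vals)
  expect_identical(ok$register, 255)
  expect_identical(unname(ok$values), unname(vals))

  none <- sensor_service_poll(vals, rep(FALSE, 8))
  expect_identical(none$register, 0)
  expect_true(all(is.na(none$values)))

  for (k in 0:7) {
    flags <- rep(FALSE, 8); flags[k + 1] <- TRUE
    one <- sensor_service_poll(vals, flags)
    expect_identical(one$register, 2^k)
    expect_identical(unname(which(!is.na(one$values))), k + 1L)
  }
  expect_error(sensor_service_poll(vals[1:7]), "8 fields")
})

test_that("failure detection recovers injected faults and flags nothing on a healthy day", {
  w <- c(t_day("00:00:00"), t_day("00:00:00") + 86400)
  healthy_irr <- data.frame(service = "irrigation",
                            t = w[1] + seq(0, 86400 - 1, by = 24 * 60), value = 1)
  reg <- data.frame(t = w[1] + seq(0, 86400 - 1, by = 30), value = 255)
  exp_list <- list(irrigation = list(period_s = 24 * 60))
  rep0 <- detect_failures(healthy_irr, reg, exp_list, w)
  expect_identical(nrow(rep0$service_failures), 0L)
  expect_identical(nrow(rep0$sensor_failures), 0L)

  # remove three consecutive irrigation pulses -> one failure window
  drop <- healthy_irr$t >= t_day("10:00:00") & healthy_irr$t < t_day("11:12:00")
  rep1 <- detect_failures(healthy_irr[!drop, ], reg, exp_list, w)
  expect_identical(nrow(rep1$service_failures), 1L)
  expect_true(rep1$service_failures$t_start <= t_day("10:00:00"))
  expect_true(rep1$service_failures$t_end >= t_day("11:12:00"))

  # stuck-at-0 bit 3 for the whole window
  reg_bad <- reg
  reg_bad$value <- 255 - 2^3
  rep2 <- detect_failures(healthy_irr, reg_bad, exp_list, w)
  expect_identical(rep2$sensor_failures$sensor_index, 3L)
  expect_identical(rep2$sensor_failures$zero_fraction, 1)

  # camera status stagnation at 2 -> upper flaw; at 1 -> frontal flaw
  sch <- camera_schedule()
  cam_t <- w[1] + unclass(sch)
  cam <- data.frame(service = "camera", t = cam_t,
                    value = c(3, 3, 3, 2, 2, 2, 1, 1, 3))
  rep3 <- detect_failures(cam, NULL, list(camera = list(schedule = sch)), w)
  expect_setequal(rep3$camera_failures$camera, c("upper", "frontal"))

  expect_error(detect_failures(healthy_irr, reg, list(), w), "expectation")
})

test_that("fault windows injected through the simulator are recovered with full recall and precision", {
  fp <- fault_plan(
    sensor_faults = data.frame(sensor_index = 5, t_on = t_day("00:00:00"),
                               t_off = t_day("00:00:00") + 86400),
    service_faults = data.frame(service = "irrigation",
                                t_on = t_day("09:00:00"), t_off = t_day("13:00:00")),
    camera_faults = data.frame(camera = "upper",
                               t_on = t_day("10:30:00"), t_off = t_day("14:00:00"))
  )
  res <- run_pipeline(sim_config(), days = 1, seed = 3,
                      out_dir = tempfile("flt"), faults = fp)
  fr <- res$failures
  # recall: every injected fault appears
  expect_identical(fr$sensor_failures$sensor_index, 5L)
  irr <- fr$service_failures[fr$service_failures$service == "irrigation", ]
  expect_identical(nrow(irr), 1L)
  expect_true(irr$t_start <= t_day("09:24:00") && irr$t_end >= t_day("13:00:00"))
  expect_identical(fr$camera_failures$camera, "upper")
  # precision: nothing else is flagged
  expect_identical(nrow(fr$service_failures), 1L)
  expect_identical(nrow(fr$sensor_failures), 1L)
  expect_identical(nrow(fr$camera_failures), 1L)
  unlink(res$out_dir, recursive = TRUE)
})

test_that("alerts are one per new failure and idempotent across repeated reports", {
  w <- c(t_day("00:00:00"), t_day("00:00:00") + 86400)
  empty <- detect_failures(data.frame(service = character(0), t = t_day("00:00:00")[0]),
                           NULL, list(irrigation = list(period_s = 1e6)), w)
  tr <- log_transport(tempfile(fileext = ".jsonl"))
  expect_length(alert_service(empty, tr), 0)

  reg_bad <- data.frame(t = w[1] + seq(0, 3600, 30), value = 0)
  rep_bad <- detect_failures(data.frame(service = character(0), t = t_day("00:00:00")[0]),
                             reg_bad, list(irrigation = list(period_s = 1e6)),
                             c(w[1], w[1] + 3630))
  expect_identical(nrow(rep_bad$sensor_failures), 8L)
  ev1 <- alert_service(rep_bad, tr)
  expect_length(ev1, 8)
  ev2 <- alert_service(rep_bad, tr)  # same report again: no duplicates
  expect_length(ev2, 0)
  expect_length(readLines(tr$path), 8)
})
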