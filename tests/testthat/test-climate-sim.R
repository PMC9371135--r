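# Synthetic device layer: diurnal curves, determinism, tank mass balance.

test_that("noiseless simulation attains the configured extrema at the configured times", {
  cfg <- sim_config(noise_sd = 0)
  sim <- simulate_greenhouse(cfg)
  cl <- sim$climate
  expect_equal(nrow(cl), 2880)  # one day at 30 s, half-open window
  tod <- as.numeric(cl$t) %% 86400
  expect_equal(cl$Ta[tod == (12 * 3600 + 52 * 60)], cfg$Ta_max)
  expect_equal(cl$Ta[tod == (7 * 3600 + 60)], cfg$Ta_min)
  expect_equal(max(cl$Lum), cfg$Lum_max)
  expect_true(all(cl$Lum[tod < cfg$daylight_start | tod > cfg$daylight_end] == 0))
})

test_that("a simulated day with default (Table-level) ranges stays near the configured extrema", {
  cfg <- sim_config()  # defaults: Ta 6.47-34.19 with noise sd 0.3
  sim <- simulate_greenhouse(cfg)
  expect_lte(abs(min(sim$climate$Ta) - 6.47), cfg$noise_sd[["Ta"]])
  expect_lte(abs(max(sim$climate$Ta) - 34.19), cfg$noise_sd[["Ta"]])
})

test_that("identical config and seed give bit-identical streams; different seeds differ", {
  cfg <- sim_config(seed = 11)
  a <- simulate_greenhouse(cfg)
  b <- simulate_greenhouse(cfg)
  expect_identical(a$climate, b$climate)
  expect_identical(a$tanks, b$tanks)
  cfg2 <- sim_config(seed = 12)
  c <- simulate_greenhouse(cfg2)
  expect_false(identical(a$climate$Ta, c$climate$Ta))
})

test_that("humidity, temperature and the leaf offset respect configured bounds across seeds", {
  # coarser step keeps the 100-seed property sweep fast; same code path
  for (s in 1:100) {
    cfg <- sim_config(step_s = 300, seed = s)
    cl <- simulate_greenhouse(cfg)$climate
    expect_true(all(cl$Ta >= cfg$Ta_min & cl$Ta <= cfg$Ta_max))
    expect_true(all(cl$RHa >= cfg$RHa_min & cl$RHa <= cfg$RHa_max))
    expect_true(all(cl$RHc >= 0 & cl$RHc <= 100))
    expect_true(all(cl$Lum >= 0 & cl$Lum <= cfg$Lum_max))
    d <- cl$Tc - cl$Ta
    expect_true(all(d >= cfg$dtla_min - 1e-9 & d <= cfg$dtla_max + 1e-9))
  }
})

test_that("tank stepping is an identity with all actuators off and does plain arithmetic", {
  cfg <- sim_config()
  st <- list(t = cfg$t_start, T_sol = 18, L_sol = 50, T_res = 18, L_res = 2, loss_l = 0)
  out <- step_tanks(st, actuator_state(), 30, cfg)
  expect_equal(out[c("T_sol", "L_sol", "T_res", "L_res", "loss_l")],
               st[c("T_sol", "L_sol", "T_res", "L_res", "loss_l")])

  # 30 s of irrigation at 6 L/h with full return moves 0.05 L across
  cfg2 <- sim_config(irrigation_flow_l_per_h = 6, return_fraction = 1)
  out2 <- step_tanks(st, actuator_state(S_irr = TRUE), 30, cfg2)
  expect_equal(out2$L_sol, 50 - 0.05)
  expect_equal(out2$L_res, 2 + 0.05)
  expect_equal(out2$loss_l, 0)
  expect_error(step_tanks(st, actuator_state(), -1, cfg), "positive")
})

test_that("nutrient solution mass is conserved over random actuator sequences", {
  cfg <- sim_config(return_fraction = 0.9, uptake_l_per_h = 0.5)
  st <- list(t = cfg$t_start, T_sol = 18, L_sol = 60, T_res = 18, L_res = 5, loss_l = 0)
  total0 <- st$L_sol + st$L_res + st$loss_l
  set.seed(99)
  for (i in 1:1000) {
    act <- actuator_state(S_irr = runif(1) < 0.4, S_res = runif(1) < 0.2)
    st <- step_tanks(st, act, sample(c(10, 30, 60), 1), cfg)
    expect_true(st$L_sol >= 0 && st$L_sol <= cfg$main_tank_capacity_l)
    expect_true(st$L_res >= 0 && st$L_res <= cfg$recirc_tank_capacity_l)
  }
  expect_lt(abs((st$L_sol + st$L_res + st$loss_l) - total0), 1e-9)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(Ta_min = 30, Ta_max = 20), "Ta_min")
  expect_error(sim_config(RHa_min = -5), "RHa")
  expect_error(sim_config(step_s = 0), "step_s")
  expect_error(sim_config(return_fraction = 1.5), "return_fraction")
  expect_error(sim_config(main_tank_capacity_l = 0), "capacities")
})

test_that("configs round-trip through JSON", {
  cfg <- sim_config(seed = 5, irrigation_flow_l_per_h = 8)
  f <- tempfile(fileext = ".json")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_equal(cfg2$irrigation_flow_l_per_h, 8)
  expect_equal(cfg2$seed, 5L)
  expect_identical(simulate_greenhouse(cfg)$climate, simulate_greenhouse(cfg2)$climate)
})

test_that("fault plans validate their windows", {
  expect_error(fault_plan(sensor_faults = data.frame(
    sensor_index = 9, t_on = t_day("01:00:00"), t_off = t_day("02:00:00"))),
    "sensor_index")
  expect_error(fault_plan(service_faults = data.frame(
    service = "irrigation", t_on = t_day("02:00:00"), t_off = t_day("01:00:00"))),
    "t_on")
  expect_error(fault_plan(service_faults = data.frame(
    service = "nonsense", t_on = t_day("01:00:00"), t_off = t_day("02:00:00"))),
    "service")
})
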