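# Saturation vapor pressure, the two VPD forms, stress bands, summaries.

test_that("Tetens saturation vapor pressure matches frozen oracle values", {
  expect_identical(sat_vapor_pressure(0), 0.6108)
  # frozen from an independent high-precision evaluation of the Tetens form
  expect_equal(sat_vapor_pressure(25), 3.1677777175068473, tolerance = 1e-12)
  expect_equal(sat_vapor_pressure(20), 2.3382812709274460, tolerance = 1e-12)
  expect_error(sat_vapor_pressure(-240), "domain")
})

test_that("Psat is strictly increasing and positive over the valid range", {
  T <- seq(-50, 60, by = 0.5)
  p <- sat_vapor_pressure(T)
  expect_true(all(p > 0))
  expect_true(all(diff(p) > 0))
})

test_that("VPD in kPa mixes crop and air temperature as specified", {
  expect_equal(vpd_kpa(22, 22, 100), 0)
  expect_equal(vpd_kpa(25, 25, 50), 1.5838888587534237, tolerance = 1e-12)
  # saturation term at crop temperature, actual-vapor term at air temperature
  expect_equal(vpd_kpa(20, 25, 50), 0.7543924121740224, tolerance = 1e-12)
  expect_error(vpd_kpa(20, 25, 101), "RH")
  expect_error(vpd_kpa(20, 25, -1), "RH")
})

test_that("VPD in Pa (base-10 form) matches its frozen oracle and zeroes at saturation", {
  expect_equal(vpd_pa(25, 25, 100), 0)
  expect_equal(vpd_pa(25, 25, 50), 1583.537204062544, tolerance = 1e-9)
})

test_that("the kPa and Pa VPD forms agree across the physiological grid", {
  g <- expand.grid(Tc = seq(0, 40, by = 1), Ta = seq(0, 40, by = 1),
                   RH = seq(0, 100, by = 5))
  k <- vpd_kpa(g$Tc, g$Ta, g$RH)
  p <- vpd_pa(g$Tc, g$Ta, g$RH) / 1000
  # 0.2 % relative wherever the deficit is not vanishing, and a tight
  # absolute bound everywhere (the forms cancel together near zero)
  big <- abs(k) >= 0.05
  expect_true(all(abs(p[big] - k[big]) / abs(k[big]) <= 0.002))
  expect_true(all(abs(p - k) <= 0.002))
})

test_that("VPD is strictly decreasing in RH at fixed temperatures", {
  for (Tc in c(10, 20, 30)) {
    v <- vpd_kpa(Tc, Tc + 2, seq(0, 100, by = 5))
    expect_true(all(diff(v) < 0))
  }
})

test_that("temperature-difference stress bands classify as in the field literature", {
  expect_identical(dtla(20, 25), -5)
  expect_identical(dtla(30, 25), 5)
  expect_identical(classify_dtla(c(4, 5, 6)), rep("stress", 3))
  expect_identical(classify_dtla(c(-4, -2.5, -1)), rep("no_stress", 3))
  expect_identical(classify_dtla(c(0, -0.5, 3.9, 6.1, -4.1, 10)),
                   rep("indeterminate", 6))
})

test_that("VPD stress classification has its boundary at 1 kPa", {
  expect_identical(classify_vpd(1.5), "harmful")
  expect_identical(classify_vpd(1.0000001), "harmful")
  expect_identical(classify_vpd(1.0), "favorable")
  expect_identical(classify_vpd(0.7), "favorable")
  expect_identical(classify_vpd(0.5), "favorable")
  expect_identical(classify_vpd(0.49), "intermediate")
  expect_identical(classify_vpd(-0.3), "intermediate")
})

test_that("stress markers batch computation appends consistent columns", {
  df <- data.frame(t = t_day("12:00:00") + 0:9 * 30,
                   Ta = seq(20, 29), RHa = seq(80, 35, by = -5),
                   Tc = seq(19, 28), RHc = seq(82, 37, by = -5))
  m <- compute_stress_markers(df)
  expect_equal(m$VPD, vpd_kpa(df$Tc, df$Ta, df$RHa))
  expect_equal(m$DTla, rep(-1, 10))
  expect_identical(unique(m$stress_dtla), "no_stress")
  expect_true(all(abs(m$VPD_pa / 1000 - m$VPD) <= 0.002))
  # crop-humidity switch feeds RHc instead
  m2 <- compute_stress_markers(df, rh_source = "crop")
  expect_equal(m2$VPD, vpd_kpa(df$Tc, df$Ta, df$RHc))
  expect_error(compute_stress_markers(df[c("Ta", "Tc")]), "missing columns")
})

test_that("series summaries match a brute-force oracle and pin sample std", {
  t <- t_day("00:00:00") + 0:3 * 3600
  s <- summarize_series(t, c(1, 2, 3, 4))
  expect_equal(s$mean, 2.5)
  expect_equal(s$std, 1.2909944487358056, tolerance = 1e-12)  # n-1 denominator

  s0 <- summarize_series(t, rep(7, 4))
  expect_equal(s0$std, 0)
  expect_equal(s0$minimum, 7); expect_equal(s0$maximum, 7); expect_equal(s0$mean, 7)
  # ties break to the earliest timestamp
  expect_identical(s0$time_of_max, t[1])

  set.seed(42)
  for (rep in 1:5) {
    n <- sample(2:500, 1)
    v <- rnorm(n)
    tt <- t_day("00:00:00") + sort(sample.int(1e5, n))
    got <- summarize_series(tt, v)
    want <- oracle_summary(tt, v)
    expect_equal(got$minimum, want$minimum)
    expect_equal(got$maximum, want$maximum)
    expect_equal(got$mean, want$mean)
    expect_equal(got$std, want$std)
    expect_identical(as.numeric(got$time_of_max), as.numeric(want$time_of_max))
    expect_identical(as.numeric(got$time_of_min), as.numeric(want$time_of_min))
  }
  expect_error(summarize_series(t[0], numeric(0)), "non-empty")
})
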