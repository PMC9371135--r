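# Channel store: schemas, rate limit, pooled daily quota, counters, CSV.

test_that("the default deployment exposes four channels and 32 field slots", {
  st <- default_deployment()
  expect_length(st$channels, 4)
  expect_identical(field_slots(st), 32L)
  expect_identical(sum(lengths(st$channels)), 27L)  # allocated fields
  expect_setequal(names(st$channels),
                  c("environmental", "services", "manual", "control"))
  expect_length(st$channels$environmental, 8)
})

test_that("schema limits are enforced at channel creation", {
  st <- channel_store()
  expect_error(create_channel(st, "nine", paste0("f", 1:9)), "between 1 and 8")
  expect_error(create_channel(st, "none", character(0)), "between 1 and 8")
  create_channel(st, "ok", c("a", "b"))
  expect_error(create_channel(st, "ok", "c"), "already exists")
  expect_error(create_channel(st, "dup", c("a", "a")), "unique")
})

test_that("writes respect the 15 s rate limit per channel", {
  st <- default_deployment()
  t0 <- t_day("08:00:00")
  expect_true(channel_write(st, "environmental", t0, c(Ta_htu = 20))$accepted)
  r <- channel_write(st, "environmental", t0 + 10, c(Ta_htu = 21))
  expect_false(r$accepted)
  expect_identical(r$reason, "rate")
  expect_true(channel_write(st, "environmental", t0 + 15, c(Ta_htu = 21))$accepted)
  # another channel has its own clock
  expect_true(channel_write(st, "services", t0 + 16, c(T_sol = 18))$accepted)
  expect_error(channel_write(st, "nope", t0, c(x = 1)), "unknown channel")
  expect_error(channel_write(st, "environmental", t0 + 60, c(bogus = 1)),
               "unknown field")
})

test_that("writes every 30 s for 24 h are all accepted (2880 of 8200)", {
  st <- default_deployment()
  t0 <- t_day("00:00:00")
  acc <- 0L
  for (k in 0:2879) {
    if (channel_write(st, "environmental", t0 + k * 30, c(Ta_htu = 20))$accepted) {
      acc <- acc + 1L
    }
  }
  expect_identical(acc, 2880L)
})

test_that("the pooled daily quota rejects the 8201st accepted-candidate write", {
  st <- default_deployment(quota_policy(min_interval_s = 1, daily_quota = 8200))
  t0 <- t_day("00:00:00")
  chans <- c("environmental", "services", "manual", "control")
  fields <- c("Ta_htu", "T_sol", "pH", "command_word")
  results <- character(0)
  for (k in 0:8200) {
    ch <- (k %% 4) + 1
    r <- channel_write(st, chans[ch], t0 + k, stats::setNames(1, fields[ch]))
    results <- c(results, if (r$accepted) "ok" else r$reason)
  }
  expect_identical(sum(results == "ok"), 8200L)
  expect_identical(results[8201], "quota")
  # the next calendar day opens a fresh budget
  expect_true(channel_write(st, "environmental", t0 + 86400 + 1, c(Ta_htu = 1))$accepted)
})

test_that("quota holds under an adversarial write storm and rejections are never applied", {
  st <- default_deployment(quota_policy(min_interval_s = 15, daily_quota = 500))
  t0 <- t_day("00:00:00")
  set.seed(7)
  ts <- sort(t0 + sample.int(86399, 3000))  # bursty: many closer than 15 s
  for (tt in ts) channel_write(st, "environmental", tt, c(Ta_htu = 1))
  d <- channel_data(st, "environmental")
  expect_lte(nrow(d), 500)
  expect_true(all(diff(as.numeric(d$t)) >= 15))
  # counters agree with stored rows
  rc <- request_counters(st)
  expect_identical(sum(rc$per_hour$count), nrow(d))
  expect_identical(sum(rc$per_channel$count), nrow(d))
})

test_that("request counters split uniform traffic evenly by hour and sum consistently", {
  st <- default_deployment()
  t0 <- t_day("00:00:00")
  for (k in 0:2879) channel_write(st, "environmental", t0 + k * 30, c(Ta_htu = 20))
  rc <- request_counters(st)
  expect_identical(rc$per_hour$count, rep(120L, 24))  # 2880 / 24
  expect_identical(sum(rc$per_channel$count), sum(rc$per_hour$count))
  # empty store: all zeros
  rc0 <- request_counters(default_deployment())
  expect_true(all(rc0$per_hour$count == 0))
  expect_true(all(rc0$per_channel$count == 0))
})

test_that("CSV export/import is a lossless round trip, with NA as empty cells", {
  st <- default_deployment()
  t0 <- t_day("00:00:00")
  set.seed(3)
  vals <- stats::runif(50) * exp(stats::runif(50, -8, 8))
  for (k in seq_along(vals)) {
    v <- c(Ta_htu = vals[k], RHa = if (k %% 7 == 0) NA_real_ else 50 + k)
    channel_write(st, "environmental", t0 + k * 30, v)
  }
  f <- tempfile(fileext = ".csv")
  export_channel_csv(st, "environmental", f)
  st2 <- default_deployment()
  n <- import_channel_csv(st2, "environmental", f)
  expect_identical(n, 50L)
  expect_identical(channel_data(st2, "environmental"),
                   channel_data(st, "environmental"))

  # empty window exports a header-only CSV
  f2 <- tempfile(fileext = ".csv")
  export_channel_csv(st, "environmental", f2,
                     window = c(t0 + 1e6, t0 + 2e6))
  expect_length(readLines(f2), 1)

  # a non-numeric cell is rejected with its line number
  lines <- readLines(f)
  lines[3] <- sub(",[0-9.]+", ",oops", lines[3])
  writeLines(lines, f2)
  expect_error(import_channel_csv(default_deployment(), "environmental", f2),
               "line 3")
})
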