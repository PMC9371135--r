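# Independent oracles used across tests (kept deliberately naive).

# single-pass brute-force summary of a series
oracle_summary <- function(t, v) {
  mn <- Inf; mx <- -Inf; s <- 0; s2 <- 0; n <- 0
  t_mx <- t_mn <- NA
  for (i in seq_along(v)) {
    if (v[i] > mx) { mx <- v[i]; t_mx <- t[i] }
    if (v[i] < mn) { mn <- v[i]; t_mn <- t[i] }
    s <- s + v[i]; n <- n + 1
  }
  m <- s / n
  for (i in seq_along(v)) s2 <- s2 + (v[i] - m)^2
  list(minimum = mn, maximum = mx, mean = m,
       std = if (n > 1) sqrt(s2 / (n - 1)) else 0,
       time_of_max = t_mx, time_of_min = t_mn)
}

# minute-by-minute brute-force count of irrigation activations in one day
oracle_activation_count <- function(frequency_min) {
  on <- logical(1440)
  for (m in 0:1439) if (m %% frequency_min == 0) on[m + 1] <- TRUE
  sum(on)
}

# brute-force 2x2 erosion and dilation on a padded copy
oracle_open_2x2 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  er <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- c(mask[i, j],
              if (j < w) mask[i, j + 1] else FALSE,
              if (i < h) mask[i + 1, j] else FALSE,
              if (i < h && j < w) mask[i + 1, j + 1] else FALSE)
    er[i, j] <- all(vals)
  }
  di <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- c(er[i, j],
              if (j > 1) er[i, j - 1] else FALSE,
              if (i > 1) er[i - 1, j] else FALSE,
              if (i > 1 && j > 1) er[i - 1, j - 1] else FALSE)
    di[i, j] <- any(vals)
  }
  di
}

t_day <- function(x) as.POSIXct(paste("2021-11-01", x), tz = "UTC")
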