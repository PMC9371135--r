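#' Free-tier quota policy for the channel store
#'
#' The emulated cloud tier mirrors the free-license limits: a minimum update
#' interval of 15 s per channel and a pooled daily quota of 8200 accepted
#' messages across all channels (day boundary at local midnight).
#'
#' @param min_interval_s minimum seconds between accepted writes on one
#'   channel (default 15).
#' @param daily_quota accepted messages per calendar day across the store
#'   (default 8200).
#' @return a `quota_policy` list.
#' @export
quota_policy <- function(min_interval_s = 15, daily_quota = 8200) {
  if (min_interval_s <= 0 || daily_quota <= 0) {
    stop_arg("quota_policy: min_interval_s and daily_quota must be positive")
  }
  structure(list(min_interval_s = min_interval_s, daily_quota = daily_quota),
            class = "quota_policy")
}

#' Create a local time-series channel store
#'
#' An in-memory emulation of the cloud layer's channel database: named
#' channels of up to 8 numeric fields each, rate-limit and pooled daily
#' quota accounting, queries, request counters and lossless CSV
#' export/import.  The store is an environment, so writes mutate it in
#' place.
#'
#' @param policy a [quota_policy()].
#' @return a `channel_store` environment.
#' @seealso [create_channel()], [channel_write()], [default_deployment()]
#' @export
channel_store <- function(policy = quota_policy()) {
  store <- new.env(parent = emptyenv())
  store$policy <- policy
  store$channels <- list()    # name -> character vector of field names
  store$units <- list()       # name -> units (possibly "")
  store$rows <- list()        # name -> list of rows (t, values)
  store$nrow <- list()        # name -> count
  store$last_t <- list()      # name -> numeric time of last accepted write
  store$day_counts <- new.env(parent = emptyenv())  # day index -> accepted count
  store$rejected <- list()
  class(store) <- "channel_store"
  store
}

#' @export
print.channel_store <- function(x, ...) {
  cat(sprintf("<channel_store> %d channel(s), %d/%d field slots used\n",
              length(x$channels), sum(lengths(x$channels)),
              8L * length(x$channels)))
  for (nm in names(x$channels)) {
    cat(sprintf("  %-14s %d field(s), %d row(s)\n", nm,
                length(x$channels[[nm]]), x$nrow[[nm]] %||% 0L))
  }
  invisible(x)
}

#' Register a channel
#'
#' @param store a [channel_store()].
#' @param name channel name (unique within the store).
#' @param fields 1--8 unique field names; a named character vector carries
#'   units as values.
#' @return the store, invisibly.
#' @export
create_channel <- function(store, name, fields) {
  stopifnot(inherits(store, "channel_store"))
  if (name %in% names(store$channels)) {
    stop_arg("channel '", name, "' already exists")
  }
  fnames <- if (!is.null(names(fields)) && all(nzchar(names(fields)))) names(fields) else as.character(fields)
  units <- if (!is.null(names(fields)) && all(nzchar(names(fields)))) as.character(fields) else rep("", length(fields))
  if (length(fnames) < 1 || length(fnames) > 8) {
    stop_arg("a channel holds between 1 and 8 fields, got ", length(fnames))
  }
  if (anyDuplicated(fnames)) stop_arg("field names must be unique")
  store$channels[[name]] <- fnames
  store$units[[name]] <- stats::setNames(units, fnames)
  store$rows[[name]] <- vector("list", 1024L)
  store$nrow[[name]] <- 0L
  store$last_t[[name]] <- -Inf
  invisible(store)
}

#' The deployment's four default channels
#'
#' Creates the four channels of the monitoring deployment -- environmental
#' measurements, services, manual measurements and control -- exposing
#' 4 x 8 = 32 field slots of which 27 are allocated:
#' * `environmental`: `Ta_htu`, `Ta_mlx`, `Tc`, `RHa`, `RHc`, `Lum`,
#'   `T_res`, `L_res` (8)
#' * `services`: `T_sol`, `L_sol`, `S_irr`, `S_res`, `S_cam`,
#'   `sensor_health` (6)
#' * `manual`: `pH`, `EC`, `Fw`, `L_l`, `W_l`, `HNO3`, `A_sol`, `B_sol` (8)
#' * `control`: `command_word`, `attended`, `irrigation_frequency_min`,
#'   `irrigation_on_time_s`, `camera_trigger` (5)
#'
#' This allocation is the package's own; the original deployment states
#' only that 27 of its 32 fields were in use.
#'
#' @param policy a [quota_policy()].
#' @return a populated `channel_store`.
#' @export
default_deployment <- function(policy = quota_policy()) {
  store <- channel_store(policy)
  create_channel(store, "environmental",
                 c(Ta_htu = "degC", Ta_mlx = "degC", Tc = "degC", RHa = "%",
                   RHc = "%", Lum = "lux", T_res = "degC", L_res = "L"))
  create_channel(store, "services",
                 c(T_sol = "degC", L_sol = "L", S_irr = "on/off",
                   S_res = "on/off", S_cam = "code", sensor_health = "0-255"))
  create_channel(store, "manual",
                 c(pH = "", EC = "uS/cm", Fw = "g", L_l = "mm", W_l = "mm",
                   HNO3 = "mL/L", A_sol = "mL/L", B_sol = "mL/L"))
  create_channel(store, "control",
                 c(command_word = "decimal", attended = "0/1",
                   irrigation_frequency_min = "min", irrigation_on_time_s = "s",
                   camera_trigger = "0/1"))
  store
}

#' Total field slots exposed by a store
#'
#' Every channel exposes 8 numeric field slots whether or not all are
#' allocated; the default four-channel deployment exposes 32.
#'
#' @param store a [channel_store()].
#' @return integer slot count.
#' @export
field_slots <- function(store) 8L * length(store$channels)

#' Write one packed message to a channel
#'
#' Enforces the free-tier semantics: a write closer than `min_interval_s`
#' to the channel's previous accepted write is rejected with reason
#' `"rate"`; once the pooled count of accepted writes for the calendar day
#' reaches `daily_quota`, further writes are rejected with reason
#' `"quota"`.  Rejected writes are logged and never partially applied.
#' Missing readings are stored as NA (serialized as an empty CSV field),
#' never as 0.
#'
#' @param store a [channel_store()].
#' @param channel channel name.
#' @param t timestamp of the write.
#' @param values named numeric vector; every name must be a schema field
#'   (missing fields are stored as NA).
#' @return list `(accepted = TRUE)` or `(accepted = FALSE, reason =
#'   "rate"|"quota")`.
#' @export
channel_write <- function(store, channel, t, values) {
  fields <- store$channels[[channel]]
  if (is.null(fields)) stop_arg("unknown channel: ", channel)
  if (length(values)) {
    if (is.null(names(values))) stop_arg("values must be named")
    bad <- setdiff(names(values), fields)
    if (length(bad)) {
      stop_arg("value(s) for unknown field(s) in '", channel, "': ",
               paste(bad, collapse = ", "))
    }
  }
  tn <- as.numeric(as_time(t))
  if (tn - store$last_t[[channel]] < store$policy$min_interval_s) {
    store$rejected[[length(store$rejected) + 1]] <- list(channel = channel, t = t, reason = "rate")
    return(list(accepted = FALSE, reason = "rate"))
  }
  day <- as.character(floor(tn / 86400))
  count <- get0(day, store$day_counts, ifnotfound = 0L)
  if (count >= store$policy$daily_quota) {
    store$rejected[[length(store$rejected) + 1]] <- list(channel = channel, t = t, reason = "quota")
    return(list(accepted = FALSE, reason = "quota"))
  }
  row <- stats::setNames(rep(NA_real_, length(fields)), fields)
  row[names(values)] <- as.numeric(values)
  n <- store$nrow[[channel]] + 1L
  if (n > length(store$rows[[channel]])) {
    length(store$rows[[channel]]) <- 2L * length(store$rows[[channel]])
  }
  store$rows[[channel]][[n]] <- c(tn, row)
  store$nrow[[channel]] <- n
  store$last_t[[channel]] <- tn
  assign(day, count + 1L, envir = store$day_counts)
  list(accepted = TRUE)
}

#' Query a channel's accepted writes
#'
#' @param store a [channel_store()].
#' @param channel channel name.
#' @param window optional `c(start, end)` POSIXct filter (half-open).
#' @return data.frame with POSIXct column `t` and one numeric column per
#'   schema field.
#' @export
channel_data <- function(store, channel, window = NULL) {
  fields <- store$channels[[channel]]
  if (is.null(fields)) stop_arg("unknown channel: ", channel)
  n <- store$nrow[[channel]]
  if (n == 0) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(fields) + 1),
                                         c("t", fields)))
    out$t <- as_time(character(0))
    return(out)
  }
  m <- do.call(rbind, store$rows[[channel]][seq_len(n)])
  out <- as.data.frame(m[, -1, drop = FALSE])
  names(out) <- fields
  out <- cbind(t = as.POSIXct(m[, 1], origin = "1970-01-01", tz = "UTC"), out)
  if (!is.null(window)) {
    window <- as_time(window)
    out <- out[out$t >= window[1] & out$t < window[2], , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Accepted-request counters, per clock hour and per channel
#'
#' Mirrors the platform's request-accounting reports; the two breakdowns
#' sum to the same total.
#'
#' @param store a [channel_store()].
#' @param window optional `c(start, end)` POSIXct filter.
#' @return list with `per_hour` (data.frame `hour` 0--23, `count`) and
#'   `per_channel` (data.frame `channel`, `count`).
#' @export
request_counters <- function(store, window = NULL) {
  per_hour <- stats::setNames(integer(24), 0:23)
  per_channel <- stats::setNames(integer(length(store$channels)), names(store$channels))
  for (nm in names(store$channels)) {
    d <- channel_data(store, nm, window)
    per_channel[[nm]] <- nrow(d)
    if (nrow(d)) {
      h <- table(factor(floor(tod_of(d$t) / 3600), levels = 0:23))
      per_hour <- per_hour + as.integer(h)
    }
  }
  list(per_hour = data.frame(hour = 0:23, count = as.integer(per_hour)),
       per_channel = data.frame(channel = names(per_channel),
                                count = as.integer(per_channel)))
}

fmt_num <- function(x) {
  out <- character(length(x))
  ok <- !is.na(x)
  out[ok] <- sprintf("%.17g", x[ok])
  out
}

#' Export and import a channel as CSV
#'
#' The export mirrors downloading the channel database from the cloud tier:
#' header `timestamp,<field1>,...`, ISO-8601 timestamps, numbers printed
#' with 17 significant digits so the export -> import round trip reproduces
#' every value bit for bit.  Missing readings export as empty cells.
#' Import appends rows directly (restoring a database is not live
#' telemetry, so the rate/quota policy is not applied).
#'
#' @param store a [channel_store()].
#' @param channel channel name.
#' @param file CSV path.
#' @param window optional `c(start, end)` POSIXct export filter.
#' @return `export_channel_csv`: `file`, invisibly.  `import_channel_csv`:
#'   the number of rows imported.
#' @export
export_channel_csv <- function(store, channel, file, window = NULL) {
  d <- channel_data(store, channel, window)
  fields <- store$channels[[channel]]
  lines <- c(paste(c("timestamp", fields), collapse = ","))
  if (nrow(d)) {
    body <- cbind(format(d$t, "%Y-%m-%dT%H:%M:%S"),
                  do.call(cbind, lapply(d[fields], fmt_num)))
    lines <- c(lines, apply(body, 1, paste, collapse = ","))
  }
  writeLines(lines, file)
  invisible(file)
}

#' @rdname export_channel_csv
#' @export
import_channel_csv <- function(store, channel, file) {
  fields <- store$channels[[channel]]
  if (is.null(fields)) stop_arg("unknown channel: ", channel)
  lines <- readLines(file)
  if (!length(lines)) stop_arg("empty CSV file: ", file)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!identical(header, c("timestamp", fields))) {
    stop_arg("CSV header does not match channel '", channel, "' schema")
  }
  n_in <- 0L
  for (i in seq_along(lines)[-1]) {
    cells <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    length(cells) <- length(fields) + 1L  # trailing empties
    tn <- as.numeric(as_time(sub("T", " ", cells[1])))
    if (is.na(tn)) stop_arg("line ", i, ": unparseable timestamp '", cells[1], "'")
    vals <- suppressWarnings(as.numeric(cells[-1]))
    bad <- which(!is.na(cells[-1]) & nzchar(cells[-1]) & is.na(vals))
    if (length(bad)) {
      stop_arg("line ", i, ": non-numeric value '", cells[-1][bad[1]],
               "' in field '", fields[bad[1]], "'")
    }
    n <- store$nrow[[channel]] + 1L
    if (n > length(store$rows[[channel]])) {
      length(store$rows[[channel]]) <- 2L * length(store$rows[[channel]])
    }
    store$rows[[channel]][[n]] <- c(tn, stats::setNames(vals, fields))
    store$nrow[[channel]] <- n
    n_in <- n_in + 1L
  }
  n_in
}
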