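#' @name command_codec
#' @title Ten-bit remote-operation command vector
#'
#' @description
#' Remote operation is carried by a single 10-bit word: eight payload bits
#' (one per controllable actuator or service), an "attended" status bit the
#' fog layer sets once it has executed the request, and a parity bit that
#' detects any single-bit transmission corruption.  Even parity is used: the
#' parity bit makes the total number of set bits even.  Words serialize as
#' unsigned decimal integers (0--1023) for storage in the control channel.
#'
#' Bit layout (bit 0 least significant): payload bits 0--7 in the order
#' `irrigation`, `recirculation`, `mixer`, `camera_trigger`, `config_write`,
#' `config_read`, `reserved_a`, `reserved_b`; attended bit 8; parity bit 9.
#' Parity can detect any odd number of flipped bits but no even-count
#' corruption; no error-correction is attempted.
NULL

.payload_names <- c("irrigation", "recirculation", "mixer", "camera_trigger",
                    "config_write", "config_read", "reserved_a", "reserved_b")

#' Construct a command state
#'
#' @param ... named logical payload flags among `irrigation`,
#'   `recirculation`, `mixer`, `camera_trigger`, `config_write`,
#'   `config_read`, `reserved_a`, `reserved_b`; omitted flags are off.
#' @param payload alternatively, a full logical vector of length 8 (named or
#'   in layout order).
#' @param attended logical; has the fog layer attended the request?
#' @return a `command_state` list with elements `payload` (named logical 8)
#'   and `attended`.
#' @seealso [encode_command()], [decode_command()], [mark_attended()]
#' @export
command_state <- function(..., payload = NULL, attended = FALSE) {
  flags <- stats::setNames(rep(FALSE, 8), .payload_names)
  if (!is.null(payload)) {
    if (length(payload) != 8) stop_arg("payload must have length 8")
    if (!is.null(names(payload))) {
      bad <- setdiff(names(payload), .payload_names)
      if (length(bad)) stop_arg("unknown payload flags: ", paste(bad, collapse = ", "))
      flags[names(payload)] <- as.logical(payload)
    } else {
      flags[] <- as.logical(payload)
    }
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .payload_names)
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop_arg("unknown payload flags: ", paste(bad, collapse = ", "))
    }
    for (nm in names(dots)) flags[[nm]] <- isTRUE(dots[[nm]])
  }
  structure(list(payload = flags, attended = isTRUE(attended)),
            class = "command_state")
}

#' @export
print.command_state <- function(x, ...) {
  on <- names(x$payload)[x$payload]
  cat("<command_state> payload:",
      if (length(on)) paste(on, collapse = ", ") else "(none)",
      "| attended:", x$attended,
      "| word:", encode_command(x), "\n")
  invisible(x)
}

#' Encode a command state into its 10-bit word
#'
#' The parity bit is always computed here, never caller-supplied.
#'
#' @param state a [command_state()] (or a named logical payload vector,
#'   which is passed through `command_state()`).
#' @return integer word in 0--1023.
#' @examples
#' encode_command(command_state())                      # 0
#' encode_command(command_state(irrigation = TRUE))     # 513: bit 0 + parity
#' @export
encode_command <- function(state) {
  if (!inherits(state, "command_state")) state <- command_state(payload = state)
  bits <- c(as.integer(state$payload), as.integer(state$attended))
  parity <- sum(bits) %% 2L
  sum(c(bits, parity) * 2L^(0:9))
}

#' Decode a 10-bit command word
#'
#' Verifies even parity; a failed check signals a corruption error of class
#' `aerofog_corruption_error` (single-bit transmission errors are always
#' detected; even-count flips are not detectable by a single parity bit).
#'
#' @param word integer in 0--1023.
#' @return a [command_state()].
#' @export
decode_command <- function(word) {
  if (length(word) != 1 || is.na(word) || word < 0 || word > 1023 ||
      word != trunc(word)) {
    stop_arg("command word must be a single integer in [0, 1023]")
  }
  bits <- as.integer(bitwAnd(bitwShiftR(as.integer(word), 0:9), 1L))
  if (sum(bits) %% 2L != 0L) {
    stop(structure(
      class = c("aerofog_corruption_error", "error", "condition"),
      list(message = sprintf("parity check failed for command word %d", word),
           call = NULL)
    ))
  }
  command_state(payload = stats::setNames(as.logical(bits[1:8]), .payload_names),
                attended = as.logical(bits[9]))
}

#' Mark a command word as attended
#'
#' Decodes (validating parity), sets the attended bit and re-encodes with
#' fresh parity; the payload is unchanged and the operation is idempotent.
#'
#' @param word a valid encoded command word.
#' @return the attended command word (integer).
#' @export
mark_attended <- function(word) {
  state <- decode_command(word)
  state$attended <- TRUE
  encode_command(state)
}

#' Eight-bit sensor-health register
#'
#' One byte summarizing a polling cycle of the environmental channel: bit
#' `k` is 1 when sensor `k` read successfully, 0 otherwise, so the register
#' ranges over 0--255 and all-success encodes to 255.  Bit 0 corresponds to
#' the first environmental-channel field; the field order is `Ta_htu`,
#' `Ta_mlx`, `Tc`, `RHa`, `RHc`, `Lum`, `T_res`, `L_res`.
#'
#' @param flags logical vector of length 8 (success per sensor, bit 0
#'   first).
#' @return `encode_health`: integer in 0--255.  `decode_health`: logical
#'   vector of length 8.  The two are a bijection.
#' @examples
#' encode_health(rep(TRUE, 8))   # 255
#' decode_health(5)              # sensors 0 and 2 healthy
#' @export
encode_health <- function(flags) {
  if (length(flags) != 8 || any(is.na(flags))) {
    stop_arg("flags must be 8 non-missing logicals")
  }
  sum(as.integer(flags) * 2L^(0:7))
}

#' @rdname encode_health
#' @param value integer register value in 0--255.
#' @export
decode_health <- function(value) {
  if (length(value) != 1 || is.na(value) || value < 0 || value > 255 ||
      value != trunc(value)) {
    stop_arg("health register value must be a single integer in [0, 255]")
  }
  as.logical(bitwAnd(bitwShiftR(as.integer(value), 0:7), 1L))
}
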