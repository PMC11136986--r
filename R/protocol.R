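#' Construct an acquisition protocol
#'
#' An acquisition protocol is the ordered table of (echo time, b-value,
#' gradient-direction index) settings, one row per acquired 3-D volume. The
#' row order is canonical: it defines the 4th-dimension order of any volume
#' series acquired with the protocol. The signal model is isotropic in
#' diffusion, so the direction index carries no model information; repeated
#' directions at one (TE, b) act as replicate measurements.
#'
#' @param echo_time Numeric vector of echo times in seconds.
#' @param b_value Numeric vector of diffusion weightings in s·mm^-2.
#' @param direction_index Integer vector (>= 0) labelling gradient directions;
#'   0 is conventionally used for b = 0.
#' @return A `data.frame` of class `acquisition_protocol` with columns
#'   `echo_time`, `b_value`, `direction_index` and attribute `te_min`.
#' @export
acquisition_protocol <- function(echo_time, b_value, direction_index = NULL) {
  n <- length(echo_time)
  if (length(b_value) != n) {
    stop("echo_time and b_value must have equal length", call. = FALSE)
  }
  if (is.null(direction_index)) direction_index <- integer(n)
  if (length(direction_index) != n) {
    stop("direction_index must match the number of measurements", call. = FALSE)
  }
  if (n < 1) stop("protocol must contain at least one measurement", call. = FALSE)
  if (any(!is.finite(echo_time)) || any(echo_time <= 0)) {
    stop("echo times must be positive and finite (seconds)", call. = FALSE)
  }
  if (any(!is.finite(b_value)) || any(b_value < 0)) {
    stop("b-values must be non-negative and finite", call. = FALSE)
  }
  if (any(direction_index < 0)) {
    stop("direction_index must be >= 0", call. = FALSE)
  }
  te_min <- min(echo_time)
  if (!any(echo_time == te_min & b_value == 0)) {
    stop("protocol must contain a b = 0 measurement at the shortest echo time",
         call. = FALSE)
  }
  out <- data.frame(
    echo_time = as.numeric(echo_time),
    b_value = as.numeric(b_value),
    direction_index = as.integer(direction_index)
  )
  attr(out, "te_min") <- te_min
  class(out) <- c("acquisition_protocol", "data.frame")
  out
}

#' Shortest echo time of a protocol
#'
#' @param protocol An [acquisition_protocol()].
#' @return The minimum echo time in seconds.
#' @export
te_min <- function(protocol) {
  tm <- attr(protocol, "te_min")
  if (is.null(tm)) tm <- min(protocol$echo_time)
  tm
}

#' Number of measurements in a protocol
#' @param protocol An [acquisition_protocol()].
#' @return Integer row count.
#' @export
n_measurements <- function(protocol) nrow(protocol)

#' Index of the reference measurement
#'
#' The reference measurement is the first b = 0 volume at the shortest echo
#' time; it is the volume on which the region of interest is drawn and the
#' row of the kernel dictionary that is identically one.
#'
#' @param protocol An [acquisition_protocol()].
#' @return Integer index into the protocol rows.
#' @export
reference_index <- function(protocol) {
  idx <- which(protocol$echo_time == te_min(protocol) & protocol$b_value == 0)
  if (length(idx) == 0) {
    stop("protocol has no b = 0 measurement at the shortest echo time",
         call. = FALSE)
  }
  idx[1]
}

#' The combined T2*-diffusion acquisition protocol
#'
#' Builds the full multi-echo diffusion protocol used throughout the package:
#' every echo time TE in (78, 114, 150, 186) ms is combined with one b = 0
#' volume plus diffusion shells b = (5, 10, 25, 50, 100, 200, 400, 600, 1200,
#' 1600) s·mm^-2 with 3 directions each, b = 18 with 8 directions, b = 36
#' with 7 directions and b = 800 with 15 directions — 61 volumes per echo
#' time, 244 in total.
#'
#' @return An [acquisition_protocol()] with 244 measurements.
#' @export
default_protocol <- function() {
  tes <- c(78, 114, 150, 186) / 1000
  shells <- rbind(
    data.frame(b_value = 0, n_dir = 1),
    expand.grid(b_value = c(5, 10, 25, 50, 100, 200, 400, 600, 1200, 1600),
                n_dir = 3)[, 1:2],
    data.frame(b_value = 18, n_dir = 8),
    data.frame(b_value = 36, n_dir = 7),
    data.frame(b_value = 800, n_dir = 15)
  )
  per_te <- do.call(rbind, lapply(seq_len(nrow(shells)), function(i) {
    b <- shells$b_value[i]
    nd <- shells$n_dir[i]
    data.frame(b_value = rep(b, nd),
               direction_index = if (b == 0) 0L else seq_len(nd))
  }))
  rows <- do.call(rbind, lapply(tes, function(te) {
    cbind(echo_time = te, per_te)
  }))
  acquisition_protocol(rows$echo_time, rows$b_value, rows$direction_index)
}

#' Write a protocol table to disk
#'
#' Serialized as plain CSV with columns `echo_time_ms`, `b_value`,
#' `direction_index` (echo time in milliseconds, the scanner-card
#' convention).
#'
#' @param protocol An [acquisition_protocol()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  out <- data.frame(
    echo_time_ms = protocol$echo_time * 1000,
    b_value = protocol$b_value,
    direction_index = protocol$direction_index
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a protocol table from disk
#'
#' @param path CSV file written by [write_protocol()] (columns
#'   `echo_time_ms`, `b_value`, optional `direction_index`).
#' @return An [acquisition_protocol()].
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path, call. = FALSE)
  tab <- read.csv(path)
  need <- c("echo_time_ms", "b_value")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("protocol file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dir_idx <- if ("direction_index" %in% names(tab)) tab$direction_index else NULL
  acquisition_protocol(tab$echo_time_ms / 1000, tab$b_value, dir_idx)
}
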