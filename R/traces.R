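#' Continuous probe traces
#'
#' Lightweight carrier for continuous multichannel voltage data: a
#' samples x channels numeric matrix (µV) plus sampling rate. Channels are in
#' the order of the accompanying [probe_geometry()].
#'
#' @param data samples x channels numeric matrix, µV (or integer counts of
#'   `scale_uv` µV each — long raw recordings are held as scaled integers to
#'   halve their memory footprint).
#' @param fs_hz sampling rate (Hz).
#' @param t0_s time of the first sample (s).
#' @param scale_uv µV per unit of `data` (1 for plain µV matrices).
#' @return an object of class `probe_traces`.
#' @export
probe_traces <- function(data, fs_hz, t0_s = 0, scale_uv = 1) {
  stopifnot(is.matrix(data), is.numeric(fs_hz), fs_hz > 0)
  structure(list(data = data, fs_hz = fs_hz, t0_s = t0_s,
                 scale_uv = scale_uv),
            class = "probe_traces")
}

#' One channel of a recording, in µV
#' @noRd
col_uv <- function(traces, ch) {
  v <- as.numeric(traces$data[, ch])
  if (!identical(traces$scale_uv %||% 1, 1)) v <- v * traces$scale_uv
  v
}

#' A block of samples, channels x samples, in µV
#' @noRd
rows_uv <- function(traces, rows) {
  m <- t(traces$data[rows, , drop = FALSE])
  if (!identical(traces$scale_uv %||% 1, 1)) m <- m * traces$scale_uv
  m
}

#' @export
print.probe_traces <- function(x, ...) {
  cat(sprintf("<probe_traces> %d channels, %d samples @ %g Hz (%.2f s)\n",
              ncol(x$data), nrow(x$data), x$fs_hz, nrow(x$data) / x$fs_hz))
  invisible(x)
}

n_samples <- function(traces) nrow(traces$data)
n_channels <- function(traces) ncol(traces$data)

#' Epoched traces
#'
#' Stimulus-locked voltage snippets: a trials x channels x samples array with
#' the analysis-window convention used throughout the package:
#' window \[-40, 150\] ms around stimulus onset, baseline \[-40, 10\] ms,
#' response \[10, 150\] ms.
#'
#' @param data trials x channels x samples array (µV).
#' @param fs_hz sampling rate (Hz).
#' @param window_ms length-2 window relative to stimulus onset (ms).
#' @param baseline_ms,response_ms sub-windows of `window_ms` (ms).
#' @param condition,eye labels attached to the epoch set.
#' @return object of class `epoched_traces`.
#' @export
epoched_traces <- function(data, fs_hz, window_ms = c(-40, 150),
                           baseline_ms = c(-40, 10), response_ms = c(10, 150),
                           condition = NA_character_, eye = NA_character_) {
  stopifnot(length(dim(data)) == 3)
  if (!(window_ms[1] <= baseline_ms[1] && baseline_ms[2] <= window_ms[2] &&
        window_ms[1] <= response_ms[1] && response_ms[2] <= window_ms[2])) {
    stop("baseline and response windows must nest inside the analysis window",
         call. = FALSE)
  }
  n_expect <- round(diff(window_ms) / 1000 * fs_hz)
  if (dim(data)[3] != n_expect) {
    stop(sprintf("sample count %d does not match window %g ms at %g Hz (%d)",
                 dim(data)[3], diff(window_ms), fs_hz, n_expect), call. = FALSE)
  }
  structure(list(data = data, fs_hz = fs_hz, window_ms = window_ms,
                 baseline_ms = baseline_ms, response_ms = response_ms,
                 condition = condition, eye = eye),
            class = "epoched_traces")
}

#' @export
print.epoched_traces <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoched_traces> %d trials x %d channels x %d samples @ %g Hz [%g, %g] ms%s\n",
    d[1], d[2], d[3], x$fs_hz, x$window_ms[1], x$window_ms[2],
    if (is.na(x$condition)) "" else paste0(" (", x$condition, ")")))
  invisible(x)
}

#' Sample times of an epoch window
#' @param epochs an [epoched_traces()] object.
#' @return time of each sample relative to stimulus onset, ms.
#' @export
epoch_times_ms <- function(epochs) {
  n <- dim(epochs$data)[3]
  epochs$window_ms[1] + (seq_len(n) - 1) / epochs$fs_hz * 1000
}

#' Indices of samples within a sub-window
#' @noRd
window_index <- function(epochs, window_ms) {
  t <- epoch_times_ms(epochs)
  which(t >= window_ms[1] & t < window_ms[2])
}
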