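#' AP-band conditioning
#'
#' `condition_ap()` applies the spike-band front end: a 300 Hz high-pass
#' Butterworth filter of order 3 (zero-phase, forward-backward) followed by a
#' per-sample common average reference across channels to remove shared
#' noise. The CAR statistic is the median by default (robust to large
#' spikes); set `car = "mean"` for the classical common average.
#'
#' @param traces a [probe_traces()] object (any rate >= 2x the corner).
#' @param corner_hz high-pass corner frequency.
#' @param order Butterworth order.
#' @param car `"median"`, `"mean"` or `"none"`.
#' @return a [probe_traces()] of the same shape.
#' @export
condition_ap <- function(traces, corner_hz = 300, order = 3,
                         car = c("median", "mean", "none")) {
  car <- match.arg(car)
  fs <- traces$fs_hz
  if (fs < 2 * corner_hz) {
    stop("sampling rate ", fs, " Hz too low for a ", corner_hz,
         " Hz high-pass", call. = FALSE)
  }
  if (ncol(traces$data) < 2) stop("need >= 2 channels", call. = FALSE)
  bf <- signal::butter(order, corner_hz / (fs / 2), type = "high")
  # one preallocated output; the input is never duplicated (matters for
  # hour-scale 384-channel arrays)
  out <- matrix(0, nrow(traces$data), ncol(traces$data))
  for (ch in seq_len(ncol(out))) {
    out[, ch] <- signal::filtfilt(bf, col_uv(traces, ch))
  }
  if (car != "none") {
    ref <- if (car == "median") sample_median(out) else rowMeans(out)
    for (ch in seq_len(ncol(out))) out[, ch] <- out[, ch] - ref
  }
  probe_traces(out, fs, traces$t0_s)
}

#' Band-limit and resample the AP band
#'
#' 300-3000 Hz band-pass (zero-phase Butterworth) then anti-aliased
#' resampling to 10 kHz. Integer decimation is used when the rate ratio is
#' integral (30 kHz -> 10 kHz is a plain factor-3 decimation: the band-pass
#' at 3 kHz already provides the anti-alias margin); otherwise a rational
#' polyphase resampler.
#'
#' @param traces a [probe_traces()] object.
#' @param band_hz pass band (Hz).
#' @param fs_out_hz output rate.
#' @param order Butterworth order.
#' @return band-limited [probe_traces()] at `fs_out_hz`.
#' @export
condition_ap_band <- function(traces, band_hz = c(300, 3000),
                              fs_out_hz = 10000, order = 3) {
  fs <- traces$fs_hz
  stopifnot(band_hz[2] < fs / 2, band_hz[2] <= fs_out_hz / 2)
  bf <- signal::butter(order, band_hz / (fs / 2), type = "pass")
  dec <- fs / fs_out_hz
  n_out <- if (fs == fs_out_hz) nrow(traces$data) else
    floor(nrow(traces$data) * fs_out_hz / fs)
  out <- matrix(0, n_out, ncol(traces$data))
  for (ch in seq_len(ncol(out))) {
    y <- signal::filtfilt(bf, col_uv(traces, ch))
    if (fs == fs_out_hz) {
      out[, ch] <- y
    } else if (abs(dec - round(dec)) < 1e-9) {
      out[, ch] <- y[seq(1, by = round(dec), length.out = n_out)]
    } else {
      r <- rational_ratio(fs_out_hz, fs)
      yr <- signal::resample(y, r[1], r[2])
      out[, ch] <- yr[seq_len(n_out)]
    }
  }
  probe_traces(out, fs_out_hz, traces$t0_s)
}

#' Fused AP conditioning chain
#'
#' Composes [condition_ap()] and [condition_ap_band()] — high-pass, common
#' average reference, band-pass, resample — reusing a single working matrix
#' so that long 384-channel recordings need only one full-size buffer
#' beside the input. Numerically identical to calling the two steps in
#' sequence.
#'
#' @inheritParams condition_ap
#' @inheritParams condition_ap_band
#' @return band-limited [probe_traces()] at `fs_out_hz`.
#' @export
condition_ap_chain <- function(traces, corner_hz = 300, order = 3,
                               car = c("median", "mean", "none"),
                               band_hz = c(300, 3000), fs_out_hz = 10000) {
  car <- match.arg(car)
  fs <- traces$fs_hz
  if (fs < 2 * corner_hz) {
    stop("sampling rate ", fs, " Hz too low for a ", corner_hz,
         " Hz high-pass", call. = FALSE)
  }
  stopifnot(band_hz[2] < fs / 2, band_hz[2] <= fs_out_hz / 2)
  bhp <- signal::butter(order, corner_hz / (fs / 2), type = "high")
  bbp <- signal::butter(order, band_hz / (fs / 2), type = "pass")
  out <- matrix(0, nrow(traces$data), ncol(traces$data))
  for (ch in seq_len(ncol(out))) {
    out[, ch] <- signal::filtfilt(bhp, col_uv(traces, ch))
  }
  if (car != "none") {
    ref <- if (car == "median") sample_median(out) else rowMeans(out)
    for (ch in seq_len(ncol(out))) out[, ch] <- out[, ch] - ref
  }
  if (fs == fs_out_hz) {
    for (ch in seq_len(ncol(out))) {
      out[, ch] <- signal::filtfilt(bbp, out[, ch])
    }
    return(probe_traces(out, fs_out_hz, traces$t0_s))
  }
  dec <- fs / fs_out_hz
  n_out <- floor(nrow(out) * fs_out_hz / fs)
  res <- matrix(0, n_out, ncol(out))
  for (ch in seq_len(ncol(out))) {
    y <- signal::filtfilt(bbp, out[, ch])
    if (abs(dec - round(dec)) < 1e-9) {
      res[, ch] <- y[seq(1, by = round(dec), length.out = n_out)]
    } else {
      r <- rational_ratio(fs_out_hz, fs)
      res[, ch] <- signal::resample(y, r[1], r[2])[seq_len(n_out)]
    }
  }
  probe_traces(res, fs_out_hz, traces$t0_s)
}

#' LFP-band conditioning
#'
#' 60 Hz notch (to remove electrical line noise), 1-100 Hz band-pass, and
#' resampling to 1 kHz, all zero-phase.
#'
#' @param traces a [probe_traces()] object (2.5 kHz native).
#' @param notch_hz line frequency to remove.
#' @param band_hz pass band.
#' @param fs_out_hz output rate.
#' @return conditioned [probe_traces()] at `fs_out_hz`.
#' @export
condition_lfp <- function(traces, notch_hz = 60, band_hz = c(1, 100),
                          fs_out_hz = 1000) {
  fs <- traces$fs_hz
  stopifnot(band_hz[2] < fs_out_hz / 2)
  bstop <- signal::butter(2, c(notch_hz - 2, notch_hz + 2) / (fs / 2),
                          type = "stop")
  # band-pass at the output rate: a 1 Hz corner is numerically much better
  # conditioned at 1 kHz than at the native rate, and the polyphase
  # resampler provides the anti-alias filtering
  bpass <- signal::butter(3, band_hz / (fs_out_hz / 2), type = "pass")
  r <- rational_ratio(fs_out_hz, fs)
  n_out <- floor(nrow(traces$data) * fs_out_hz / fs)
  out <- matrix(0, n_out, ncol(traces$data))
  for (ch in seq_len(ncol(out))) {
    y <- signal::filtfilt(bstop, col_uv(traces, ch))
    if (!(r[1] == 1 && r[2] == 1)) {
      y <- signal::resample(y, r[1], r[2])
    }
    out[, ch] <- signal::filtfilt(bpass, y[seq_len(n_out)])
  }
  probe_traces(out, fs_out_hz, traces$t0_s)
}

#' @noRd
rational_ratio <- function(p, q) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(p, q)
  c(p / d, q / d)
}

#' Epoch continuous traces around stimulus events
#'
#' Cuts one trial slab per event over `window_ms` around each onset. Events
#' whose window falls partly outside the recording are dropped (with a
#' message giving the count); zero surviving events yields an empty epoch
#' set, not an error. Overlapping windows are all kept.
#'
#' @param traces a [probe_traces()] object.
#' @param events tibble with `onset_s` and optionally `condition`, `eye`.
#' @param window_ms,baseline_ms,response_ms analysis windows (ms re onset).
#' @return an [epoched_traces()] object (trials x channels x samples).
#' @export
epoch_traces <- function(traces, events, window_ms = c(-40, 150),
                         baseline_ms = c(-40, 10), response_ms = c(10, 150)) {
  fs <- traces$fs_hz
  n <- nrow(traces$data)
  nw <- round(diff(window_ms) / 1000 * fs)
  start <- round(events$onset_s * fs) + round(window_ms[1] / 1000 * fs) + 1L
  ok <- start >= 1L & (start + nw - 1L) <= n
  if (any(!ok)) {
    message(sum(!ok), " event(s) dropped: window extends outside recording")
  }
  start <- start[ok]
  dat <- array(0, dim = c(length(start), ncol(traces$data), nw))
  for (i in seq_along(start)) {
    dat[i, , ] <- rows_uv(traces, start[i]:(start[i] + nw - 1L))
  }
  cond <- if (!is.null(events[["condition"]]) && length(start)) {
    u <- unique(events[["condition"]][ok])
    if (length(u) == 1) u else NA_character_
  } else NA_character_
  eye <- if (!is.null(events[["eye"]]) && length(start)) {
    u <- unique(events[["eye"]][ok])
    if (length(u) == 1) u else NA_character_
  } else NA_character_
  epoched_traces(dat, fs, window_ms, baseline_ms, response_ms,
                 condition = cond, eye = eye)
}

#' Average same-depth channels
#'
#' Collapses the channel dimension to one series per 20 µm depth row:
#' channels sharing a row are averaged with reference channels excluded, so
#' the output depth step equals the probe row pitch.
#'
#' @param epochs an [epoched_traces()] object whose channel dimension matches
#'   `geometry`.
#' @param geometry the matching [probe_geometry()].
#' @return an [epoched_traces()] whose second dimension is depth; the depth
#'   of each series is in attribute `depth_um`.
#' @export
depth_average <- function(epochs, geometry) {
  stopifnot(dim(epochs$data)[2] == nrow(geometry))
  cd <- channel_depths(geometry)
  axis <- depth_axis(geometry)
  dat <- epochs$data
  out <- array(0, dim = c(dim(dat)[1], length(axis), dim(dat)[3]))
  for (k in seq_along(axis)) {
    sel <- which(cd$depth_um == axis[k] & !cd$is_reference)
    if (length(sel) == 1) {
      out[, k, ] <- dat[, sel, ]
    } else {
      out[, k, ] <- apply(dat[, sel, , drop = FALSE], c(1, 3), mean)
    }
  }
  res <- epoched_traces(out, epochs$fs_hz, epochs$window_ms,
                        epochs$baseline_ms, epochs$response_ms,
                        epochs$condition, epochs$eye)
  attr(res, "depth_um") <- as.numeric(axis)
  res
}

#' Trial-average an epoch set
#'
#' @param epochs an [epoched_traces()] object.
#' @return channels(/depths) x samples matrix.
#' @export
trial_mean <- function(epochs) {
  apply(epochs$data, c(2, 3), mean)
}
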