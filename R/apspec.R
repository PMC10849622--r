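#' Laminar AP-band power spectrum (Pf)
#'
#' Multitaper power spectral density of each channel over the response
#' window, averaged over trials, then over same-depth channels (reference
#' excluded), restricted to the AP band, and gaussian-smoothed along depth.
#'
#' @param epochs band-limited [epoched_traces()] (channel dimension matches
#'   `geometry`).
#' @param geometry the matching [probe_geometry()].
#' @param response_ms analysis window (ms re onset).
#' @param band_hz returned frequency band (Hz).
#' @param nw,k multitaper parameters (NW = 3, 5 tapers by default, about
#'   21 Hz resolution on a 140 ms window).
#' @param smooth_sigma_um depth smoothing width (µm).
#' @return a [depth_spectral_profile()] with metric `"pf"` (µV^2/Hz).
#' @export
power_spectrum <- function(epochs, geometry, response_ms = NULL,
                           band_hz = c(300, 3000), nw = 3, k = 5,
                           smooth_sigma_um = 20) {
  response_ms <- response_ms %||% epochs$response_ms
  idx <- window_index(epochs, response_ms)
  n <- length(idx)
  if (n < 2 * k) stop("response window shorter than taper support",
                      call. = FALSE)
  fs <- epochs$fs_hz
  freqs <- (0:(n - 1)) * fs / n
  bins <- which(freqs >= band_hz[1] & freqs <= min(band_hz[2], fs / 2))
  tp <- dpss_tapers(n, nw, k)
  nch <- dim(epochs$data)[2]
  acc <- matrix(0, length(bins), nch)
  n_tr <- dim(epochs$data)[1]
  for (tr in seq_len(n_tr)) {
    x <- t(epochs$data[tr, , idx])
    X <- tapered_fft(x, tp, bins)
    acc <- acc + apply(Mod(X)^2, c(1, 3), mean)
  }
  psd <- acc / n_tr * 2 / fs
  dp <- depth_collapse(psd, geometry)
  vals <- gaussian_smooth_rows(t(dp$values), smooth_sigma_um, dp$step_um)
  depth_spectral_profile(dp$depth_um, freqs[bins], vals, metric = "pf",
                         condition = epochs$condition, eye = epochs$eye)
}

#' Average a frequency/time x channel matrix over same-depth channels
#' @noRd
depth_collapse <- function(m, geometry) {
  cd <- channel_depths(geometry)
  axis <- depth_axis(geometry)
  out <- matrix(NA_real_, nrow(m), length(axis))
  for (kk in seq_along(axis)) {
    sel <- which(cd$depth_um == axis[kk] & !cd$is_reference)
    out[, kk] <- if (length(sel) == 1) m[, sel] else
      rowMeans(m[, sel, drop = FALSE])
  }
  list(depth_um = as.numeric(axis), values = out,
       step_um = attr(axis, "step_um"))
}

#' Instantaneous AP power (P_t)
#'
#' Mean of squares in a sliding window (10 ms by default) across the full
#' analysis window, per channel, trial-averaged, then averaged over
#' same-depth channels.
#'
#' @param epochs band-limited [epoched_traces()].
#' @param geometry the matching [probe_geometry()].
#' @param window_ms sliding-window length (ms).
#' @param step_ms output time step (ms).
#' @return a [depth_time_profile()] with metric `"pt"` (µV^2).
#' @export
instantaneous_power <- function(epochs, geometry, window_ms = 10,
                                step_ms = 1) {
  fs <- epochs$fs_hz
  w <- max(1L, round(window_ms / 1000 * fs))
  if (w %% 2 == 0) w <- w + 1L                 # centred window
  d <- dim(epochs$data)
  t_all <- epoch_times_ms(epochs)
  keep_t <- seq(1, d[3], by = max(1L, round(step_ms / 1000 * fs)))
  half <- (w - 1L) %/% 2L
  acc <- matrix(0, length(keep_t), d[2])
  for (tr in seq_len(d[1])) {
    sq <- t(epochs$data[tr, , ]^2)             # samples x channels
    cs <- apply(sq, 2, cumsum)
    hi <- pmin(d[3], keep_t + half)
    lo <- pmax(1L, keep_t - half)
    ms <- (cs[hi, , drop = FALSE] -
             rbind(0, cs)[lo, , drop = FALSE]) / (hi - lo + 1L)
    acc <- acc + ms
  }
  acc <- acc / d[1]
  dp <- depth_collapse(acc, geometry)
  depth_time_profile(dp$depth_um, t_all[keep_t], t(dp$values), metric = "pt",
                     condition = epochs$condition, eye = epochs$eye)
}

#' Baseline-relative instantaneous power change (dP/P)
#'
#' `(P_t - mean(P_baseline)) / mean(P_baseline)` per depth. Depths whose
#' baseline power is zero are flagged and returned as missing.
#'
#' @param pt a [depth_time_profile()] from [instantaneous_power()].
#' @param baseline_ms baseline window (ms re onset).
#' @return a [depth_time_profile()] with metric `"dpp"` (dimensionless).
#' @export
delta_p_over_p <- function(pt, baseline_ms = c(-40, 10)) {
  stopifnot(inherits(pt, "depth_time_profile"))
  pm <- profile_matrix(pt, "time_ms")
  bl <- pm$key >= baseline_ms[1] & pm$key < baseline_ms[2]
  if (!any(bl)) stop("no samples in baseline window", call. = FALSE)
  base <- rowMeans(pm$values[, bl, drop = FALSE])
  vals <- (pm$values - base) / base
  bad <- !is.finite(base) | base <= 0
  if (any(bad)) {
    warning(sum(bad), " depth(s) with zero baseline power set to missing")
    vals[bad, ] <- NA_real_
  }
  depth_time_profile(pm$depth_um, pm$key, vals, metric = "dpp",
                     condition = pt$condition[1], eye = pt$eye[1])
}

#' Response onset latency from a dP/P time course
#'
#' First time, within the response window, at which the trace exceeds
#' `criterion` times its own post-stimulus maximum. Rows that never rise
#' (all missing, or no positive response) return `NA`.
#'
#' @param values numeric time course (one depth row of dP/P).
#' @param times_ms matching times (ms re onset).
#' @param criterion fraction of the post-stimulus maximum (default 0.5).
#' @param response_ms search window (ms).
#' @param min_peak minimum post-stimulus maximum for the latency to be
#'   meaningful (dP/P units); weaker rows return `NA` rather than a noise
#'   crossing time.
#' @return latency in ms, or `NA`.
#' @export
onset_latency <- function(values, times_ms, criterion = 0.5,
                          response_ms = c(10, 150), min_peak = 0) {
  sel <- times_ms >= response_ms[1] & times_ms < response_ms[2]
  v <- values[sel]; t <- times_ms[sel]
  if (all(is.na(v))) return(NA_real_)
  pk <- max(v, na.rm = TRUE)
  if (!is.finite(pk) || pk <= 0 || pk < min_peak) return(NA_real_)
  i <- which(v >= criterion * pk)[1]
  if (is.na(i)) NA_real_ else t[i]
}

#' Onset-latency depth profile
#'
#' @param dpp a [depth_time_profile()] with metric `"dpp"`.
#' @param criterion,response_ms,min_peak see [onset_latency()]. The default
#'   `min_peak = 0.5` keeps only depths whose power at least rises 50 %
#'   over baseline, so weakly driven depths do not contribute noise
#'   latencies.
#' @return a [depth_profile()] with metric `"onset_latency_ms"`.
#' @export
latency_profile <- function(dpp, criterion = 0.5, response_ms = c(10, 150),
                            min_peak = 0.5) {
  pm <- profile_matrix(dpp, "time_ms")
  lat <- apply(pm$values, 1, onset_latency, times_ms = pm$key,
               criterion = criterion, response_ms = response_ms,
               min_peak = min_peak)
  depth_profile(pm$depth_um, lat, metric = "onset_latency_ms",
                condition = dpp$condition[1], eye = dpp$eye[1])
}

#' Gaussian-weighted local coherence spectrum (Cf)
#'
#' For each channel, the weighted average of its multitaper
#' magnitude-squared coherence with every other channel within `radius_um`,
#' weights `exp(-d^2 / (2 sigma^2))` of the pair distance (self-pairs
#' excluded). Coherences are computed per trial over the response window,
#' averaged over trials, then over same-depth channels, and optionally
#' depth-smoothed. Being a normalised phase-consistency measure, Cf is
#' independent of per-channel amplitude scaling.
#'
#' @param epochs band-limited [epoched_traces()].
#' @param geometry the matching [probe_geometry()].
#' @param radius_um pairing radius (µm).
#' @param weight_sigma_um gaussian distance-weight width (µm).
#' @param response_ms analysis window.
#' @param band_hz frequency band.
#' @param nw,k multitaper parameters.
#' @param smooth_sigma_um depth smoothing (µm); 0 disables.
#' @return a [depth_spectral_profile()] with metric `"cf"`, values in
#'   \[0, 1\].
#' @export
local_coherence <- function(epochs, geometry, radius_um = 55,
                            weight_sigma_um = 25, response_ms = NULL,
                            band_hz = c(300, 3000), nw = 3, k = 5,
                            smooth_sigma_um = 20) {
  response_ms <- response_ms %||% epochs$response_ms
  idx <- window_index(epochs, response_ms)
  n <- length(idx)
  fs <- epochs$fs_hz
  freqs <- (0:(n - 1)) * fs / n
  bins <- which(freqs >= band_hz[1] & freqs <= min(band_hz[2], fs / 2))
  tp <- dpss_tapers(n, nw, k)
  nch <- dim(epochs$data)[2]
  ## pair list within the radius
  xy <- cbind(geometry$x_um, geometry$y_um)
  pairs <- list(); wts <- list()
  for (i in seq_len(nch)) {
    d <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)
    j <- which(d <= radius_um & seq_len(nch) != i)
    pairs[[i]] <- j
    wts[[i]] <- exp(-d[j]^2 / (2 * weight_sigma_um^2))
  }
  acc <- matrix(0, length(bins), nch)
  n_tr <- dim(epochs$data)[1]
  for (tr in seq_len(n_tr)) {
    X <- tapered_fft(t(epochs$data[tr, , idx]), tp, bins)
    S <- apply(Mod(X)^2, c(1, 3), sum)         # auto-spectra x channels
    for (i in seq_len(nch)) {
      js <- pairs[[i]]
      if (!length(js)) next
      ci <- matrix(0, length(bins), length(js))
      Xi <- Conj(X[, , i])
      for (a in seq_along(js)) {
        sxy <- rowSums(X[, , js[a]] * Xi)
        ci[, a] <- Mod(sxy)^2 / (S[, js[a]] * S[, i])
      }
      acc[, i] <- acc[, i] + as.vector(ci %*% wts[[i]]) / sum(wts[[i]])
    }
  }
  acc <- acc / n_tr
  dp <- depth_collapse(acc, geometry)
  vals <- t(dp$values)
  if (smooth_sigma_um > 0) {
    vals <- gaussian_smooth_rows(vals, smooth_sigma_um, dp$step_um)
  }
  depth_spectral_profile(dp$depth_um, freqs[bins], vals, metric = "cf",
                         condition = epochs$condition, eye = epochs$eye)
}
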