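#' Per-channel spike heights of a mean waveform
#'
#' Height is peak minus trough of the mean waveform on each channel.
#'
#' @param wf a mean-waveform object: list with `channel_id`, `w`
#'   (channels x samples matrix, µV) and `fs_hz`.
#' @return numeric vector of heights (µV), one per channel of `wf`.
#' @export
waveform_heights <- function(wf) {
  apply(wf$w, 1, function(v) max(v) - min(v))
}

#' Mean waveforms from conditioned AP traces
#'
#' Averages up to `max_spikes` randomly chosen spike segments per unit
#' (seeded for reproducibility), then crops to channels within
#' `keep_radius_um` axially of the peak channel.
#'
#' @param traces conditioned AP-band [probe_traces()].
#' @param units a sorted-unit tibble with a `spike_times` list-column (s).
#' @param geometry the matching [probe_geometry()].
#' @param window_ms segment length from spike onset (ms).
#' @param max_spikes maximum averaged segments per unit.
#' @param keep_radius_um axial crop radius around the peak channel.
#' @param seed seed for the random spike subset.
#' @return `units` with a `mean_waveform` list-column.
#' @export
extract_waveforms <- function(traces, units, geometry, window_ms = 0.9,
                              max_spikes = 1000, keep_radius_um = 150,
                              seed = 1L) {
  set.seed(as.integer(seed %% 2147483647))
  fs <- traces$fs_hz
  L <- max(2L, round(window_ms / 1000 * fs))
  n <- nrow(traces$data)
  cd <- channel_depths(geometry)
  units$mean_waveform <- lapply(seq_len(nrow(units)), function(i) {
    st <- units$spike_times[[i]]
    if (length(st) > max_spikes) st <- sort(sample(st, max_spikes))
    idx <- round(st * fs) + 1L
    idx <- idx[idx >= 1 & idx + L - 1 <= n]
    if (!length(idx)) {
      return(list(channel_id = geometry$channel_id,
                  w = matrix(0, nrow(geometry), L), fs_hz = fs))
    }
    gather <- as.vector(outer(idx, 0:(L - 1L), "+"))
    arr <- array(traces$data[gather, ], c(length(idx), L, ncol(traces$data)))
    w <- t(colMeans(arr, dims = 1))           # channels x samples
    pk <- which.max(apply(w, 1, function(v) max(v) - min(v)))
    near <- which(abs(cd$depth_um - cd$depth_um[pk]) <= keep_radius_um)
    list(channel_id = geometry$channel_id[near], w = w[near, , drop = FALSE],
         fs_hz = fs)
  })
  units
}

#' Center-of-mass unit position
#'
#' Channel positions weighted by spike height, over channels within
#' `radius_um` (euclidean) of the largest-height channel.
#'
#' @param wf a mean-waveform object (see [waveform_heights()]).
#' @param geometry a [probe_geometry()].
#' @param radius_um inclusion radius around the peak channel (µm).
#' @return named numeric `c(x_um, y_um)`; `y_um` is on the shared depth axis.
#' @export
unit_position <- function(wf, geometry, radius_um = 65) {
  h <- waveform_heights(wf)
  cd <- channel_depths(geometry)
  m <- match(wf$channel_id, cd$channel_id)
  x <- cd$x_um[m]; y <- cd$depth_um[m]
  pk <- which.max(h)
  d <- sqrt((x - x[pk])^2 + (y - y[pk])^2)
  sel <- d <= radius_um
  c(x_um = sum(x[sel] * h[sel]) / sum(h[sel]),
    y_um = sum(y[sel] * h[sel]) / sum(h[sel]))
}

#' Axial spatial spread of a spike
#'
#' From the peak-height channel, the distance up (and down) the probe to the
#' nearest channel whose height falls below `frac` of the maximum. If no
#' channel falls below threshold before the end of the available span, the
#' spread is the distance to that end and the value is flagged as capped.
#'
#' @param wf a mean-waveform object.
#' @param geometry a [probe_geometry()].
#' @param frac threshold fraction of the maximum height.
#' @return named list: `upward_um`, `downward_um`, `upward_capped`,
#'   `downward_capped`.
#' @export
spike_spread <- function(wf, geometry, frac = 0.15) {
  h <- waveform_heights(wf)
  cd <- channel_depths(geometry)
  y <- cd$depth_um[match(wf$channel_id, cd$channel_id)]
  pk <- which.max(h)
  thr <- frac * h[pk]
  one_dir <- function(up) {
    dy <- if (up) y - y[pk] else y[pk] - y
    cand <- which(dy > 0 & h < thr)
    if (length(cand)) {
      list(um = min(dy[cand]), capped = FALSE)
    } else {
      avail <- dy[dy > 0]
      list(um = if (length(avail)) max(avail) else 0, capped = TRUE)
    }
  }
  upv <- one_dir(TRUE); dnv <- one_dir(FALSE)
  list(upward_um = upv$um, downward_um = dnv$um,
       upward_capped = upv$capped, downward_capped = dnv$capped)
}

#' Spike duration and peak-trough ratio
#'
#' On the largest-height channel: duration is the time of the peak minus the
#' time of the trough (negative for peak-leading, i.e. inverted/axonal
#' spikes); the ratio is the signed peak amplitude over the signed trough
#' amplitude (below -1 flags inverted spikes).
#'
#' @param wf a mean-waveform object.
#' @return named numeric `c(duration_ms, peak_trough_ratio)`.
#' @export
spike_shape <- function(wf) {
  h <- waveform_heights(wf)
  v <- wf$w[which.max(h), ]
  i_pk <- which.max(v); i_tr <- which.min(v)
  dur <- (i_pk - i_tr) / wf$fs_hz * 1000
  ratio <- if (v[i_tr] >= 0) NA_real_ else v[i_pk] / v[i_tr]
  c(duration_ms = dur, peak_trough_ratio = ratio)
}

#' Derive all per-unit waveform features
#'
#' Adds position, height, spreads, duration and peak-trough ratio columns to
#' a sorted-unit table carrying mean waveforms.
#'
#' @param units sorted-unit tibble with `mean_waveform` list-column.
#' @param geometry a [probe_geometry()].
#' @param position_radius_um,spread_frac parameters of [unit_position()] and
#'   [spike_spread()].
#' @return the tibble with feature columns added.
#' @export
unit_features <- function(units, geometry, position_radius_um = 65,
                          spread_frac = 0.15) {
  feats <- lapply(units$mean_waveform, function(wf) {
    pos <- unit_position(wf, geometry, position_radius_um)
    spr <- spike_spread(wf, geometry, spread_frac)
    shp <- spike_shape(wf)
    h <- max(waveform_heights(wf))
    tibble::tibble(x_um = pos[["x_um"]], y_um = pos[["y_um"]], height_uv = h,
                   upward_spread_um = spr$upward_um,
                   downward_spread_um = spr$downward_um,
                   spread_capped = spr$upward_capped || spr$downward_capped,
                   duration_ms = shp[["duration_ms"]],
                   peak_trough_ratio = shp[["peak_trough_ratio"]])
  })
  out <- dplyr::bind_cols(units[setdiff(names(units), names(feats[[1]]))],
                          dplyr::bind_rows(feats))
  class(out) <- unique(c("sorted_units", class(out)))
  out
}

#' Remove double-counted spikes
#'
#' Within each cluster, of any spike pair closer than `isi_ms` the later
#' spike is dropped. Across clusters whose positions lie within `radius_um`,
#' coincident spikes (closer than `isi_ms`) are dropped from the
#' lower-amplitude cluster, keeping the better-resolved unit. Requires the
#' feature columns from [unit_features()] (`y_um`, `x_um`, `height_uv`).
#' Idempotent.
#'
#' @param units featured sorted-unit tibble.
#' @param isi_ms coincidence threshold (ms).
#' @param radius_um cross-cluster neighbourhood radius (µm).
#' @return the tibble with cleaned `spike_times` and updated `mean_rate_hz`.
#' @export
remove_duplicates <- function(units, isi_ms = 0.35, radius_um = 60) {
  stopifnot(all(c("x_um", "y_um", "height_uv") %in% names(units)))
  isi <- isi_ms / 1000
  dedup_within <- function(st) {
    if (length(st) < 2) return(st)
    st <- sort(st)
    keep <- logical(length(st))
    last <- -Inf
    for (k in seq_along(st)) {
      if (st[k] - last > isi) { keep[k] <- TRUE; last <- st[k] }
    }
    st[keep]
  }
  sts <- lapply(units$spike_times, dedup_within)
  n <- nrow(units)
  if (n > 1) {
    dmat <- as.matrix(stats::dist(cbind(units$x_um, units$y_um)))
    ord <- order(units$height_uv, decreasing = TRUE)
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        i <- ord[a]; j <- ord[b]                 # i: higher amplitude
        if (dmat[i, j] > radius_um) next
        hi <- sts[[i]]; lo <- sts[[j]]
        if (!length(hi) || !length(lo)) next
        pos <- findInterval(lo, hi)
        near_lo <- ifelse(pos >= 1, lo - hi[pmax(pos, 1)], Inf)
        near_hi <- ifelse(pos < length(hi), hi[pmin(pos + 1, length(hi))] - lo,
                          Inf)
        sts[[j]] <- lo[pmin(near_lo, near_hi) > isi]
      }
    }
  }
  span <- attr(units, "duration_s")
  units$spike_times <- sts
  if (!is.null(span)) units$mean_rate_hz <- lengths(sts) / span
  units
}

#' Drop low-rate (noise) clusters
#'
#' Units with mean firing rate at or below `min_rate_hz` are regarded as
#' noise and removed (the threshold is inclusive).
#'
#' @param units sorted-unit tibble with `mean_rate_hz`.
#' @param min_rate_hz rate threshold (spikes/s).
#' @return filtered tibble; the removed count is reported via `message()`.
#' @export
filter_low_rate <- function(units, min_rate_hz = 0.5) {
  drop <- units$mean_rate_hz <= min_rate_hz
  if (any(drop)) message(sum(drop), " low-rate cluster(s) removed")
  units[!drop, , drop = FALSE]
}

#' Unit density depth profile
#'
#' Weighted unit count in a 40 µm segment of a 100 µm-radius cylinder slid
#' along the probe in 20 µm steps, divided by the segment volume and
#' gaussian-smoothed along depth. A single unit counts as 1 neuron, a
#' multi-unit as `multi_weight` neurons. Depths with no units are genuinely
#' density zero.
#'
#' @param units featured sorted-unit tibble (`y_um`, `quality`).
#' @param geometry a [probe_geometry()].
#' @param radius_um cylinder radius (µm).
#' @param window_um segment length (µm).
#' @param step_um step between segment centres (µm).
#' @param sigma_um gaussian smoothing width (µm).
#' @param multi_weight neuron-equivalent weight of a multi-unit (1 to 2).
#' @return a [depth_profile()] in units/mm^3.
#' @export
unit_density_profile <- function(units, geometry, radius_um = 100,
                                 window_um = 40, step_um = 20, sigma_um = 28,
                                 multi_weight = 1.2) {
  axis <- seq(0, max(depth_axis(geometry)), by = step_um)
  w <- ifelse(units$quality == "multi", multi_weight, 1)
  counts <- vapply(axis, function(d) {
    sum(w[units$y_um >= d - window_um / 2 & units$y_um < d + window_um / 2])
  }, numeric(1))
  vol_mm3 <- pi * (radius_um / 1000)^2 * (window_um / 1000)
  dens <- gaussian_smooth(counts / vol_mm3, sigma_um, step = step_um)
  depth_profile(axis, dens, metric = "unit_density",
                smoothing_sigma_um = sigma_um)
}

#' Depth distribution of a waveform feature
#'
#' Mean of a per-unit feature over units whose position falls in a sliding
#' 40 µm window (20 µm step), gaussian-smoothed along depth. Windows with no
#' units are explicitly missing (`NA`), and the smoothing skips them.
#'
#' @param units featured sorted-unit tibble.
#' @param field one of `upward_spread_um`, `downward_spread_um`,
#'   `duration_ms`, `peak_trough_ratio` (any numeric column works).
#' @param geometry a [probe_geometry()].
#' @param window_um,step_um,sigma_um window geometry as in
#'   [unit_density_profile()].
#' @return a [depth_profile()].
#' @export
depth_distribution <- function(units, field, geometry, window_um = 40,
                               step_um = 20, sigma_um = 28) {
  stopifnot(field %in% names(units))
  axis <- seq(0, max(depth_axis(geometry)), by = step_um)
  vals <- units[[field]]
  m <- vapply(axis, function(d) {
    sel <- units$y_um >= d - window_um / 2 & units$y_um < d + window_um / 2
    if (!any(sel)) NA_real_ else mean(vals[sel], na.rm = TRUE)
  }, numeric(1))
  depth_profile(axis, gaussian_smooth(m, sigma_um, step = step_um),
                metric = field, smoothing_sigma_um = sigma_um)
}
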