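#' Depth-indexed metric profiles
#'
#' The common currency of all laminar metrics. Three tibble flavours share the
#' depth convention (origin at the deepest active contact, increasing toward
#' the pia):
#'
#' * `depth_profile`: one value per depth (`depth_um`, `value`).
#' * `depth_time_profile`: depth x time (`depth_um`, `time_ms`, `value`).
#' * `depth_spectral_profile`: depth x frequency (`depth_um`, `freq_hz`,
#'   `value`).
#'
#' `value` may be `NA` at depths with no data (e.g. no sorted units); only
#' unit density treats the absence of units as a true zero. Metric name,
#' smoothing width and condition/eye labels travel as columns so profiles can
#' be bound and faceted with ordinary dplyr/ggplot2 tooling.
#'
#' @param depth_um depths (µm).
#' @param value metric values (same length as `depth_um` after recycling of
#'   time/frequency).
#' @param metric metric name, e.g. `"unit_density"`, `"csd"`, `"pf"`.
#' @param condition,eye optional stimulus labels.
#' @param smoothing_sigma_um gaussian depth-smoothing width applied (µm).
#' @return a tibble with subclass `depth_profile`.
#' @export
depth_profile <- function(depth_um, value, metric,
                          condition = NA_character_, eye = NA_character_,
                          smoothing_sigma_um = 0) {
  stopifnot(length(depth_um) == length(value))
  out <- tibble::tibble(
    depth_um = as.numeric(depth_um), value = as.numeric(value),
    metric = metric, condition = condition, eye = eye
  )
  attr(out, "smoothing_sigma_um") <- smoothing_sigma_um
  class(out) <- c("depth_profile", class(out))
  out
}

#' @rdname depth_profile
#' @param time_ms times relative to stimulus onset (ms); `value` must be a
#'   depth x time matrix or a vector in depth-major order.
#' @export
depth_time_profile <- function(depth_um, time_ms, value, metric,
                               condition = NA_character_,
                               eye = NA_character_) {
  if (is.matrix(value)) {
    stopifnot(nrow(value) == length(depth_um), ncol(value) == length(time_ms))
    value <- as.vector(value)
  }
  d_col <- rep(as.numeric(depth_um), times = length(time_ms))
  t_col <- rep(as.numeric(time_ms), each = length(depth_um))
  out <- tibble::tibble(
    depth_um = d_col, time_ms = t_col, value = as.numeric(value),
    metric = metric, condition = condition, eye = eye
  )
  class(out) <- c("depth_time_profile", class(out))
  out
}

#' @rdname depth_profile
#' @param freq_hz frequencies (Hz); `value` as in `depth_time_profile`.
#' @export
depth_spectral_profile <- function(depth_um, freq_hz, value, metric,
                                   condition = NA_character_,
                                   eye = NA_character_) {
  if (is.matrix(value)) {
    stopifnot(nrow(value) == length(depth_um), ncol(value) == length(freq_hz))
    value <- as.vector(value)
  }
  d_col <- rep(as.numeric(depth_um), times = length(freq_hz))
  f_col <- rep(as.numeric(freq_hz), each = length(depth_um))
  out <- tibble::tibble(
    depth_um = d_col, freq_hz = f_col, value = as.numeric(value),
    metric = metric, condition = condition, eye = eye
  )
  class(out) <- c("depth_spectral_profile", class(out))
  out
}

#' Convert a long profile back to a depth x (time|frequency) matrix
#' @noRd
profile_matrix <- function(profile, col) {
  d <- sort(unique(profile$depth_um))
  k <- sort(unique(profile[[col]]))
  m <- matrix(NA_real_, length(d), length(k))
  m[cbind(match(profile$depth_um, d), match(profile[[col]], k))] <- profile$value
  list(depth_um = d, key = k, values = m)
}

#' Collapse a spectral profile to its band mean
#'
#' Mean of `value` over a frequency band, per depth (and condition/eye),
#' yielding a plain depth profile — the form consumed by the boundary edge
#' detectors.
#'
#' @param profile a `depth_spectral_profile`.
#' @param band_hz length-2 frequency band (Hz).
#' @return a [depth_profile()].
#' @export
band_mean <- function(profile, band_hz = c(300, 3000)) {
  stopifnot(inherits(profile, "depth_spectral_profile"))
  sub <- profile[profile$freq_hz >= band_hz[1] & profile$freq_hz <= band_hz[2], ]
  agg <- dplyr::summarise(
    dplyr::group_by(sub, .data$depth_um, .data$metric, .data$condition, .data$eye),
    value = mean(.data$value, na.rm = TRUE), .groups = "drop"
  )
  agg <- agg[order(agg$depth_um), ]
  depth_profile(agg$depth_um, agg$value,
                metric = paste0(agg$metric[1], "_band_mean"),
                condition = agg$condition[1], eye = agg$eye[1])
}

#' Time-window mean of a depth x time profile
#'
#' @param profile a `depth_time_profile`.
#' @param window_ms length-2 time window (ms).
#' @return a [depth_profile()].
#' @export
time_mean <- function(profile, window_ms = c(10, 150)) {
  stopifnot(inherits(profile, "depth_time_profile"))
  sub <- profile[profile$time_ms >= window_ms[1] & profile$time_ms < window_ms[2], ]
  agg <- dplyr::summarise(
    dplyr::group_by(sub, .data$depth_um, .data$metric, .data$condition, .data$eye),
    value = mean(.data$value, na.rm = TRUE), .groups = "drop"
  )
  agg <- agg[order(agg$depth_um), ]
  depth_profile(agg$depth_um, agg$value,
                metric = paste0(agg$metric[1], "_time_mean"),
                condition = agg$condition[1], eye = agg$eye[1])
}
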