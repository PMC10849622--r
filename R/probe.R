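#' Probe geometry
#'
#' A `probe_geometry` is a tibble with one row per recording channel and
#' columns `channel_id`, `x_um` (lateral position on the shank), `y_um`
#' (axial position along the shank) and `is_reference`. The row pitch (axial
#' distance between successive channel rows, in micrometres) is carried as an
#' attribute. All depth-resolved analyses share a single depth convention:
#' depth 0 at the deepest active (non-reference) contact, increasing toward
#' the pia.
#'
#' @param channel_id integer channel identifiers.
#' @param x_um,y_um channel coordinates on the shank, micrometres.
#' @param is_reference logical; reference channels are excluded from all
#'   depth averaging.
#' @param row_pitch_um axial distance between channel rows (µm).
#' @return a tibble of class `probe_geometry`.
#' @export
probe_geometry <- function(channel_id, x_um, y_um, is_reference = FALSE,
                           row_pitch_um = 20) {
  geom <- tibble::tibble(
    channel_id = as.integer(channel_id),
    x_um = as.numeric(x_um),
    y_um = as.numeric(y_um),
    is_reference = rep_len(as.logical(is_reference), length(channel_id))
  )
  if (anyNA(geom$x_um) || anyNA(geom$y_um) || any(!is.finite(geom$x_um)) ||
      any(!is.finite(geom$y_um))) {
    stop("probe coordinates must be finite", call. = FALSE)
  }
  if (anyDuplicated(geom$channel_id)) {
    stop("duplicated channel_id in probe geometry", call. = FALSE)
  }
  ys <- sort(unique(geom$y_um))
  if (length(ys) > 1) {
    steps <- diff(ys)
    if (max(abs(steps - row_pitch_um)) > 1e-6) {
      stop("channel rows are not on a uniform grid of pitch ", row_pitch_um,
           " µm", call. = FALSE)
    }
  }
  attr(geom, "row_pitch_um") <- row_pitch_um
  class(geom) <- c("probe_geometry", class(geom))
  geom
}

#' Neuropixels-class two-column linear probe
#'
#' Builds the geometry of a dense linear probe: `n_channels` contacts in two
#' columns, two contacts per row, rows `row_pitch_um` apart. With the default
#' 384 channels and 20 µm row pitch the contacts cover 192 rows, i.e.
#' 3.84 mm of cortex-spanning rows.
#'
#' @param n_channels total number of channels (even).
#' @param row_pitch_um axial row pitch (µm).
#' @param x_offsets_um lateral positions of the two columns (µm).
#' @param reference_channels channel ids flagged as reference.
#' @return a [probe_geometry()].
#' @export
linear_probe <- function(n_channels = 384, row_pitch_um = 20,
                         x_offsets_um = c(11, 43),
                         reference_channels = integer()) {
  stopifnot(n_channels >= 2, n_channels %% 2 == 0)
  row <- rep(seq_len(n_channels / 2) - 1L, each = 2)
  probe_geometry(
    channel_id = seq_len(n_channels) - 1L,
    x_um = rep(x_offsets_um, n_channels / 2),
    y_um = row * row_pitch_um,
    is_reference = (seq_len(n_channels) - 1L) %in% reference_channels,
    row_pitch_um = row_pitch_um
  )
}

active_channels <- function(geometry) {
  geometry[!geometry$is_reference, , drop = FALSE]
}

#' Depth axis of a probe
#'
#' The ordered depths (µm) of the active channel rows, with origin at the
#' deepest active contact and increasing toward the pia.
#'
#' @param geometry a [probe_geometry()].
#' @return a numeric vector of strictly increasing depths with attribute
#'   `step_um`.
#' @export
depth_axis <- function(geometry) {
  act <- active_channels(geometry)
  d <- sort(unique(act$y_um)) - min(act$y_um)
  structure(d, step_um = attr(geometry, "row_pitch_um"))
}

#' Depth of a channel
#'
#' Axial position of a channel re-referenced to the deepest active contact.
#'
#' @param geometry a [probe_geometry()].
#' @param channel_id one or more channel ids.
#' @return depth(s) in µm on the shared depth axis.
#' @export
depth_of_channel <- function(geometry, channel_id) {
  idx <- match(channel_id, geometry$channel_id)
  if (anyNA(idx)) {
    stop("unknown channel id(s): ",
         paste(channel_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  origin <- min(active_channels(geometry)$y_um)
  geometry$y_um[idx] - origin
}

#' Per-channel depth table
#'
#' @param geometry a [probe_geometry()].
#' @return tibble with `channel_id`, `x_um`, `depth_um`, `is_reference`.
#' @export
channel_depths <- function(geometry) {
  tibble::tibble(
    channel_id = geometry$channel_id,
    x_um = geometry$x_um,
    depth_um = depth_of_channel(geometry, geometry$channel_id),
    is_reference = geometry$is_reference
  )
}
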