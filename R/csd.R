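#' Thin-disc inverse CSD configuration
#'
#' Current sources at each electrode depth are modeled as infinitely thin
#' uniform discs of radius `disc_radius_um` in a homogeneous ohmic medium of
#' conductivity `conductivity_s_per_m`. Note the two distinct sigmas of this
#' module: `conductivity_s_per_m` (tissue conductivity, S/m) and
#' `smoothing_sigma_um` (gaussian depth-smoothing width, µm). The CSD shape
#' is invariant to the conductivity, which only sets absolute units.
#'
#' @param disc_radius_um disc radius (µm).
#' @param conductivity_s_per_m extracellular conductivity (S/m); 0.3 is the
#'   standard cortical value.
#' @param source_pitch_um depth step between source discs (µm).
#' @param smoothing_sigma_um gaussian smoothing applied to the CSD after
#'   inversion (0 = none).
#' @return list of class `icsd_config`.
#' @export
icsd_config <- function(disc_radius_um = 500, conductivity_s_per_m = 0.3,
                        source_pitch_um = 20, smoothing_sigma_um = 0) {
  stopifnot(disc_radius_um > 0, conductivity_s_per_m > 0, source_pitch_um > 0)
  structure(list(disc_radius_um = disc_radius_um,
                 conductivity_s_per_m = conductivity_s_per_m,
                 source_pitch_um = source_pitch_um,
                 smoothing_sigma_um = smoothing_sigma_um),
            class = "icsd_config")
}

#' Forward matrix of the thin-disc model
#'
#' `F[j, i]` is the on-axis potential at electrode depth `z_j` produced by a
#' unit-amplitude planar disc source at `z_i`:
#' `F_ji = h / (2 sigma) * (sqrt((z_j - z_i)^2 + R^2) - |z_j - z_i|)`,
#' with `h` the source pitch and `R` the disc radius.
#'
#' @param depths_um uniform depth grid (µm).
#' @param config an [icsd_config()].
#' @return n x n numeric matrix mapping CSD (µA/mm^3) to potential (µV).
#' @export
forward_matrix <- function(depths_um, config = icsd_config()) {
  if (length(depths_um) > 1) {
    steps <- diff(sort(depths_um))
    if (max(abs(steps - steps[1])) > 1e-6) {
      stop("depth grid must be uniform", call. = FALSE)
    }
  }
  z <- depths_um * 1e-6                     # m
  R <- config$disc_radius_um * 1e-6
  h <- config$source_pitch_um * 1e-6
  dz <- abs(outer(z, z, "-"))
  Fm <- h / (2 * config$conductivity_s_per_m) * (sqrt(dz^2 + R^2) - dz)
  # CSD in µA/mm^3 is 1e3 A/m^3; V -> µV is another 1e6
  Fm * 1e9
}

#' Forward potentials of a CSD depth profile
#'
#' Linear forward half of the thin-disc inverse method: potentials are the
#' superposition of each disc source's on-axis field.
#'
#' @param csd depth x time matrix (or vector) of CSD amplitudes.
#' @param depths_um uniform depth grid matching the rows of `csd`.
#' @param config an [icsd_config()].
#' @return depth x time matrix of potentials.
#' @export
forward_potentials <- function(csd, depths_um, config = icsd_config()) {
  if (!is.matrix(csd)) csd <- matrix(csd, ncol = 1)
  stopifnot(nrow(csd) == length(depths_um))
  forward_matrix(depths_um, config) %*% csd
}

#' Inverse CSD of a depth-resolved LFP
#'
#' Inverts the thin-disc forward matrix per time sample, then (optionally)
#' gaussian-smooths along depth. Input may be a depth x time matrix plus an
#' explicit depth grid, or a depth-averaged [epoched_traces()] (which is
#' trial-averaged first).
#'
#' @param lfp depth x time matrix of potentials (µV), or a depth-averaged
#'   [epoched_traces()] carrying its `depth_um` attribute.
#' @param depths_um depth grid (µm); taken from `lfp` when it is epoched.
#' @param config an [icsd_config()]; `smoothing_sigma_um` is applied after
#'   inversion.
#' @param times_ms optional time labels for the output profile.
#' @return a [depth_time_profile()] with metric `"csd"`.
#' @export
inverse_csd <- function(lfp, depths_um = NULL, config = icsd_config(),
                        times_ms = NULL) {
  if (inherits(lfp, "epoched_traces")) {
    depths_um <- attr(lfp, "depth_um")
    if (is.null(times_ms)) times_ms <- epoch_times_ms(lfp)
    lfp <- trial_mean(lfp)
  }
  stopifnot(is.matrix(lfp), nrow(lfp) == length(depths_um),
            length(depths_um) >= 3)
  Fm <- forward_matrix(depths_um, config)
  csd <- solve(Fm, lfp)
  if (config$smoothing_sigma_um > 0) {
    csd <- gaussian_smooth_rows(csd, config$smoothing_sigma_um,
                                step = abs(diff(depths_um[1:2])))
  }
  if (is.null(times_ms)) times_ms <- seq_len(ncol(csd))
  depth_time_profile(depths_um, times_ms, csd, metric = "csd")
}

#' Gaussian-smooth a profile along depth
#'
#' 1-D gaussian filtering along the depth dimension only (reflective
#' boundary), the spatial-averaging experiment applied to 20 µm-pitch CSD
#' profiles with sigma of 20, 30 or 40 µm.
#'
#' @param profile a [depth_profile()] or [depth_time_profile()].
#' @param sigma_um gaussian width (µm); 0 returns the input unchanged.
#' @return profile of the same class.
#' @export
smooth_profile <- function(profile, sigma_um) {
  if (sigma_um <= 0) return(profile)
  if (inherits(profile, "depth_time_profile")) {
    pm <- profile_matrix(profile, "time_ms")
    sm <- gaussian_smooth_rows(pm$values, sigma_um,
                               step = abs(diff(pm$depth_um[1:2])))
    out <- depth_time_profile(pm$depth_um, pm$key, sm,
                              metric = profile$metric[1],
                              condition = profile$condition[1],
                              eye = profile$eye[1])
  } else if (inherits(profile, "depth_spectral_profile")) {
    pm <- profile_matrix(profile, "freq_hz")
    sm <- gaussian_smooth_rows(pm$values, sigma_um,
                               step = abs(diff(pm$depth_um[1:2])))
    out <- depth_spectral_profile(pm$depth_um, pm$key, sm,
                                  metric = profile$metric[1],
                                  condition = profile$condition[1],
                                  eye = profile$eye[1])
  } else {
    stopifnot(inherits(profile, "depth_profile"))
    d <- profile$depth_um
    out <- profile
    out$value <- gaussian_smooth(profile$value, sigma_um,
                                 step = abs(diff(sort(unique(d))[1:2])))
    attr(out, "smoothing_sigma_um") <- sigma_um
  }
  out
}

#' CSD at reduced electrode pitch
#'
#' Sub-samples the depth rows of the LFP by keeping every `(skip + 1)`-th
#' row and inverts with the pitch-adjusted forward matrix, mimicking the CSD
#' a coarser probe would have produced (skip 1, 2, 3, 4 on a 20 µm-pitch
#' probe correspond to 40, 60, 80, 100 µm contact spacing).
#'
#' @param lfp depth x time matrix (µV) or depth-averaged [epoched_traces()].
#' @param depths_um depth grid of the rows of `lfp`.
#' @param skip number of contacts skipped between kept rows (0 = none).
#' @param config an [icsd_config()]; its `source_pitch_um` is scaled by
#'   `skip + 1`.
#' @param times_ms optional time labels.
#' @return a [depth_time_profile()] on the coarse depth grid.
#' @export
downsample_csd <- function(lfp, depths_um = NULL, skip = 2,
                           config = icsd_config(), times_ms = NULL) {
  if (inherits(lfp, "epoched_traces")) {
    depths_um <- attr(lfp, "depth_um")
    if (is.null(times_ms)) times_ms <- epoch_times_ms(lfp)
    lfp <- trial_mean(lfp)
  }
  stopifnot(skip >= 0, skip == round(skip))
  keep <- seq(1, nrow(lfp), by = skip + 1)
  cfg <- config
  cfg$source_pitch_um <- config$source_pitch_um * (skip + 1)
  inverse_csd(lfp[keep, , drop = FALSE], depths_um[keep], cfg,
              times_ms = times_ms)
}

#' Stimulus-induced CSD change
#'
#' Subtracts, per depth, the temporal mean of the CSD over the baseline
#' window: `dCSD_t = CSD_t - mean(CSD_baseline)`.
#'
#' @param csd a [depth_time_profile()] with metric `"csd"`.
#' @param baseline_ms baseline window (ms re stimulus onset).
#' @return a [depth_time_profile()] with metric `"delta_csd"`.
#' @export
delta_csd <- function(csd, baseline_ms = c(-40, 10)) {
  stopifnot(inherits(csd, "depth_time_profile"))
  pm <- profile_matrix(csd, "time_ms")
  bl <- pm$key >= baseline_ms[1] & pm$key < baseline_ms[2]
  if (!any(bl)) stop("no samples in baseline window", call. = FALSE)
  base <- rowMeans(pm$values[, bl, drop = FALSE])
  depth_time_profile(pm$depth_um, pm$key, pm$values - base,
                     metric = "delta_csd", condition = csd$condition[1],
                     eye = csd$eye[1])
}
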