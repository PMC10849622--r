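#' Biphasic extracellular spike template
#'
#' Somatic spikes are modeled as a 0.3 ms trough followed by a 0.2 ms peak
#' with |peak/trough| = 0.4, sampled at `fs_hz` and normalised to unit trough
#' depth. Axonal (white-matter) spikes use the amplitude-inverted template:
#' peak-leading, giving the characteristic negative spike duration and
#' peak-trough ratio below -1.
#'
#' @param fs_hz sampling rate.
#' @param inverted logical; `TRUE` for the axonal form.
#' @return numeric template (µV per unit trough amplitude).
#' @export
spike_template <- function(fs_hz, inverted = FALSE) {
  t_ms <- seq(0, 0.8, by = 1000 / fs_hz)
  s <- -exp(-(t_ms - 0.18)^2 / (2 * 0.075^2)) +
    0.4 * exp(-(t_ms - 0.43)^2 / (2 * 0.055^2))
  s <- s / abs(min(s))
  if (inverted) -s else s
}

#' Simulate a laminar probe recording with known ground truth
#'
#' Generates the four primary inputs of the analysis pipeline — AP-band
#' traces, LFP-band traces, a sorted-unit table and a stimulus event table —
#' from a known layer stack, so every metric and boundary detector can be
#' validated against ground truth.
#'
#' The generative model: neurons are placed along the probe by an
#' inhomogeneous Poisson point process with per-layer density (the
#' white-matter zone below the cortex contains only axonal sources with
#' inverted waveforms); each neuron fires Poisson spikes at a baseline rate
#' plus a condition-dependent evoked rate that steps on at its layer's onset
#' latency; every spike adds a biphasic template to nearby channels with
#' amplitude decaying as `exp(-distance / soma_spread_um)`, truncated below a
#' noise floor; i.i.d. gaussian noise is added per sample. The LFP is built
#' with the same thin-disc forward model used by the CSD inversion, from a
#' prescribed depth-CSD movie with sinks in the LGN-recipient layers at
#' their latencies, so the inverse-CSD analysis is a true round trip.
#'
#' @param spec a [default_layer_spec()] stack.
#' @param probe a [probe_geometry()], default 384-channel 20 µm-pitch probe.
#' @param n_trials stimulus presentations per condition.
#' @param fs_ap_hz,fs_lfp_hz sampling rates. The native AP rate is 30 kHz;
#'   since the AP band is 300-3000 Hz, 10 kHz is adequate and much cheaper
#'   for simulation studies.
#' @param pia_depth_um pial depth above the deepest contact.
#' @param noise_uv_rms AP-band noise (µV RMS).
#' @param neurons_per_density_um sortable neuron count scale (neurons per
#'   µm at relative density 1).
#' @param background_per_density_um additional background population per µm
#'   at relative density 1. AP-band voltage is the superposition of the
#'   whole population's spikes, which is far denser than the sortable
#'   subset; these sources are painted into the traces (and drive the
#'   power/coherence profiles) but never appear in the sorted-unit table.
#' @param isi_s inter-stimulus interval (s); presentations alternate
#'   conditions every `isi_s`.
#' @param min_unit_height_uv sorting-yield proxy: only neurons whose largest
#'   channel spike height exceeds this become sorted units.
#' @param multi_fraction fraction of sorted units labeled multi-unit.
#' @param seed integer seed; the same seed gives bit-identical output.
#' @return a list of class `laminar_sim` with elements `ap`, `lfp`
#'   ([probe_traces()]), `units` (sorted-unit tibble), `events` (tibble with
#'   `onset_s`, `condition`, `eye`), `probe`, and `truth` (boundaries,
#'   neuron table, sink table, seed).
#' @export
simulate_recording <- function(spec = default_layer_spec(),
                               probe = linear_probe(),
                               n_trials = 10,
                               fs_ap_hz = 30000, fs_lfp_hz = 2500,
                               pia_depth_um = 2200,
                               noise_uv_rms = 10,
                               neurons_per_density_um = 0.5,
                               background_per_density_um = 2,
                               isi_s = 1.5,
                               min_unit_height_uv = 40,
                               multi_fraction = 0.2,
                               seed = 1L) {
  stopifnot(nrow(spec) > 1, n_trials >= 1, nrow(probe) > 0)
  conditions <- attr(spec, "conditions")
  set.seed(as.integer(seed %% 2147483647))

  truth_bounds <- spec_boundaries(spec, pia_depth_um)
  th <- layer_thicknesses(truth_bounds)
  wm_bottom <- 0
  wm_top <- th$bottom_um[th$layer == "L6B"]

  ## ---- events -------------------------------------------------------------
  n_events <- n_trials * length(conditions)
  onsets <- 0.5 + (seq_len(n_events) - 1) * isi_s
  events <- tibble::tibble(
    onset_s = onsets,
    condition = rep(conditions, length.out = n_events),
    eye = "dominant"
  )
  duration_s <- max(onsets) + isi_s

  ## ---- neuron placement ---------------------------------------------------
  zones <- rbind(
    data.frame(layer = th$layer, top = th$top_um, bottom = th$bottom_um),
    data.frame(layer = "WM", top = wm_top, bottom = wm_bottom)
  )
  neurons <- do.call(rbind, lapply(seq_len(nrow(zones)), function(i) {
    zn <- zones[i, ]
    row <- spec[spec$layer == zn$layer, ]
    n <- rpois(1, row$neuron_density * (zn$top - zn$bottom) *
                 neurons_per_density_um)
    if (n == 0) return(NULL)
    data.frame(
      layer = zn$layer,
      depth_um = runif(n, zn$bottom, zn$top),
      x_um = runif(n, min(probe$x_um) - 10, max(probe$x_um) + 10),
      z_um = runif(n, 8, 50),
      soma_spread_um = row$soma_spread_um * exp(rnorm(n, 0, 0.12)),
      amp_uv = exp(rnorm(n, log(150), 0.35)),
      is_axon = zn$layer == "WM",
      baseline_rate_hz = row$baseline_rate_hz,
      onset_latency_ms = row$onset_latency_ms
    )
  }))
  neurons$neuron_id <- seq_len(nrow(neurons))
  evoked_tab <- do.call(rbind, lapply(spec$evoked_rate_hz, function(v) v[conditions]))
  rownames(evoked_tab) <- spec$layer

  ## ---- spike times per neuron --------------------------------------------
  resp_dur_s <- 0.25
  origin_y <- min(active_channels(probe)$y_um)
  ch_depth <- probe$y_um - origin_y
  ap_n <- round(duration_s * fs_ap_hz)
  template <- spike_template(fs_ap_hz)
  tl <- length(template)

  spikes <- vector("list", nrow(neurons))
  wave_chan <- vector("list", nrow(neurons))
  wave_amp <- vector("list", nrow(neurons))
  for (i in seq_len(nrow(neurons))) {
    nn <- neurons[i, ]
    n_base <- rpois(1, nn$baseline_rate_hz * duration_s)
    t_base <- runif(n_base, 0, duration_s)
    rates <- evoked_tab[nn$layer, events$condition]
    lat <- if (is.na(nn$onset_latency_ms)) 0 else nn$onset_latency_ms / 1000
    n_ev <- rpois(length(rates), rates * resp_dur_s)
    t_ev <- rep(events$onset_s + lat, n_ev) + runif(sum(n_ev), 0, resp_dur_s)
    spikes[[i]] <- sort(c(t_base, t_ev))
    dist <- sqrt((ch_depth - nn$depth_um)^2 + (probe$x_um - nn$x_um)^2 +
                   nn$z_um^2)
    a <- nn$amp_uv * exp(-dist / nn$soma_spread_um)
    keep <- which(a >= 1)                      # noise-floor truncation
    wave_chan[[i]] <- keep
    wave_amp[[i]] <- a[keep]
  }
  neurons$mean_rate_hz <- lengths(spikes) / duration_s
  neurons$peak_height_uv <- vapply(wave_amp, function(a)
    if (length(a)) max(a) * (1 + 0.4) else 0, numeric(1))

  ## ---- AP traces ----------------------------------------------------------
  ap <- matrix(rnorm(ap_n * nrow(probe), 0, noise_uv_rms), ap_n, nrow(probe))
  for (i in seq_len(nrow(neurons))) {
    if (!length(wave_chan[[i]]) || !length(spikes[[i]])) next
    idx <- pmin(pmax(round(spikes[[i]] * fs_ap_hz) + 1L, 1L), ap_n - tl)
    cnt <- tabulate(match(idx, unique(idx)))
    u <- unique(idx)
    pos <- rep(u, each = tl) + rep(seq_len(tl) - 1L, times = length(u))
    val <- rep(cnt, each = tl) * rep(template, times = length(u))
    agg <- rowsum(val, pos)
    p <- as.integer(rownames(agg))
    sgn <- if (neurons$is_axon[i]) -1 else 1
    for (k in seq_along(wave_chan[[i]])) {
      ch <- wave_chan[[i]][k]
      ap[p, ch] <- ap[p, ch] + sgn * wave_amp[[i]][k] * agg[, 1]
    }
  }

  ## dense background population: the AP band superposes the whole
  ## population's spikes, far more neurons than spike sorting resolves;
  ## these sources shape the power/coherence profiles but are never sorted
  n_background <- 0L
  if (background_per_density_um > 0) {
    for (i in seq_len(nrow(zones))) {
      zn <- zones[i, ]
      row <- spec[spec$layer == zn$layer, ]
      nbk <- rpois(1, row$neuron_density * (zn$top - zn$bottom) *
                     background_per_density_um)
      if (nbk == 0) next
      n_background <- n_background + nbk
      depth <- runif(nbk, zn$bottom, zn$top)
      xs <- runif(nbk, min(probe$x_um) - 10, max(probe$x_um) + 10)
      zs <- runif(nbk, 8, 50)
      spreads <- row$soma_spread_um * exp(rnorm(nbk, 0, 0.12))
      amps <- exp(rnorm(nbk, log(150), 0.35))
      lat <- if (is.na(row$onset_latency_ms)) 0 else row$onset_latency_ms / 1000
      rates <- evoked_tab[zn$layer, events$condition]
      sgn <- if (zn$layer == "WM") -1 else 1
      for (j in seq_len(nbk)) {
        n_base <- rpois(1, row$baseline_rate_hz * duration_s)
        n_ev <- rpois(length(rates), rates * resp_dur_s)
        st <- c(runif(n_base, 0, duration_s),
                rep(events$onset_s + lat, n_ev) + runif(sum(n_ev), 0, resp_dur_s))
        if (!length(st)) next
        dist <- sqrt((ch_depth - depth[j])^2 + (probe$x_um - xs[j])^2 +
                       zs[j]^2)
        a <- amps[j] * exp(-dist / spreads[j])
        keep <- which(a >= 1)
        if (!length(keep)) next
        idx <- pmin(pmax(round(st * fs_ap_hz) + 1L, 1L), ap_n - tl)
        u <- unique(idx)
        cnt <- tabulate(match(idx, u))
        pos <- rep(u, each = tl) + rep(seq_len(tl) - 1L, times = length(u))
        val <- rep(cnt, each = tl) * rep(template, times = length(u))
        agg <- rowsum(val, pos)
        p <- as.integer(rownames(agg))
        for (k in seq_along(keep)) {
          ap[p, keep[k]] <- ap[p, keep[k]] + sgn * a[keep[k]] * agg[, 1]
        }
      }
    }
  }

  ## ---- LFP from a prescribed CSD movie ------------------------------------
  axis <- depth_axis(probe)
  nd <- length(axis)
  sink_layers <- spec$layer[spec$receives_lgn %in% TRUE]
  t_resp <- seq(0, resp_dur_s, by = 1 / fs_lfp_hz)
  cfg <- icsd_config(source_pitch_um = attr(axis, "step_um"))
  Fm <- forward_matrix(axis, cfg)
  sinks <- tibble::tibble(layer = sink_layers,
                          center_um = (th$top_um + th$bottom_um)[
                            match(sink_layers, th$layer)] / 2,
                          sigma_um = th$thickness_um[
                            match(sink_layers, th$layer)] / 4,
                          latency_ms = spec$onset_latency_ms[
                            match(sink_layers, spec$layer)])
  lfp_n <- round(duration_s * fs_lfp_hz)
  lfp <- matrix(rnorm(lfp_n * nrow(probe), 0, noise_uv_rms), lfp_n,
                nrow(probe))
  row_of_channel <- match(ch_depth, axis)
  phi_cond <- lapply(conditions, function(cc) {
    C <- matrix(0, nd, length(t_resp))
    for (j in seq_len(nrow(sinks))) {
      sl <- sinks[j, ]
      amp <- evoked_tab[sl$layer, cc] / 20
      prof <- -amp * exp(-(axis - sl$center_um)^2 / (2 * sl$sigma_um^2))
      tt <- (t_resp - sl$latency_ms / 1000) / 0.015
      tc <- ifelse(tt > 0, tt * exp(1 - tt), 0)
      C <- C + outer(prof, tc)
    }
    in_cortex <- axis >= wm_top & axis <= pia_depth_um
    C[in_cortex, ] <- sweep(C[in_cortex, , drop = FALSE], 2,
                            colMeans(C[in_cortex, , drop = FALSE]))
    C[!in_cortex, ] <- 0
    Fm %*% C                                   # depth x time potentials, µV
  })
  names(phi_cond) <- conditions
  for (e in seq_len(nrow(events))) {
    i0 <- round(events$onset_s[e] * fs_lfp_hz) + 1L
    rng <- i0:(i0 + length(t_resp) - 1L)
    if (max(rng) > lfp_n) next
    phi <- phi_cond[[events$condition[e]]]
    lfp[rng, ] <- lfp[rng, ] + t(phi)[, row_of_channel]
  }

  ## ---- sorted-unit table --------------------------------------------------
  det <- which(neurons$peak_height_uv >= min_unit_height_uv &
                 neurons$mean_rate_hz > 0)
  wf_win_um <- 150
  units <- tibble::tibble(
    unit_id = seq_along(det),
    neuron_id = neurons$neuron_id[det],
    quality = ifelse(runif(length(det)) < multi_fraction, "multi", "single"),
    spike_times = lapply(det, function(i) spikes[[i]]),
    mean_rate_hz = neurons$mean_rate_hz[det]
  )
  units$mean_waveform <- lapply(det, function(i) {
    nn <- neurons[i, ]
    near <- which(abs(ch_depth - nn$depth_um) <= wf_win_um)
    dist <- sqrt((ch_depth[near] - nn$depth_um)^2 +
                   (probe$x_um[near] - nn$x_um)^2 + nn$z_um^2)
    a <- nn$amp_uv * exp(-dist / nn$soma_spread_um)
    sgn <- if (nn$is_axon) -1 else 1
    w <- outer(a, sgn * template)
    list(channel_id = probe$channel_id[near], w = w, fs_hz = fs_ap_hz)
  })
  attr(units, "duration_s") <- duration_s
  class(units) <- c("sorted_units", class(units))

  # store long raw traces as 0.1 µV integer counts (half the memory of a
  # double matrix; far finer than the 10 µV noise floor); quantise in
  # column blocks to avoid a second full-size temporary
  quantise <- function(m) {
    out <- matrix(0L, nrow(m), ncol(m))
    for (b in split(seq_len(ncol(m)), ceiling(seq_len(ncol(m)) / 32))) {
      out[, b] <- as.integer(round(m[, b] * 10))
    }
    out
  }
  ap <- quantise(ap)
  lfp <- quantise(lfp)

  structure(list(
    ap = probe_traces(ap, fs_ap_hz, scale_uv = 0.1),
    lfp = probe_traces(lfp, fs_lfp_hz, scale_uv = 0.1),
    units = units,
    events = events,
    probe = probe,
    truth = list(boundaries = truth_bounds, neurons = tibble::as_tibble(neurons),
                 n_background = n_background, sinks = sinks, layer_spec = spec,
                 pia_depth_um = pia_depth_um, seed = seed)
  ), class = "laminar_sim")
}

#' @export
print.laminar_sim <- function(x, ...) {
  cat(sprintf(
    "<laminar_sim> %d channels, %.1f s, %d events, %d sorted units (seed %s)\n",
    ncol(x$ap$data), nrow(x$ap$data) / x$ap$fs_hz, nrow(x$events),
    nrow(x$units), format(x$truth$seed)))
  invisible(x)
}
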