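# Shared fixtures. The reference simulation (full 384-channel probe, 60 s,
# four stimulus conditions at the reduced 10 kHz AP rate) is expensive, so it
# is computed once per session and cached; smaller fixtures are built inline.

.fixture_env <- new.env(parent = emptyenv())

reference_sim <- function(seed = 1L) {
  key <- paste0("sim_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_recording(
      default_layer_spec(), linear_probe(), n_trials = 10,
      fs_ap_hz = 8000, fs_lfp_hz = 1250, pia_depth_um = 2200, seed = seed
    )
  }
  .fixture_env[[key]]
}

reference_run <- function(seed = 1L) {
  key <- paste0("run_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- suppressMessages(
      run_pipeline(reference_sim(seed), verbose = FALSE)
    )
  }
  .fixture_env[[key]]
}

small_sim <- function(seed = 7L, conditions = c("black", "s_off"),
                      n_trials = 3) {
  key <- paste0("small_", seed, "_", paste(conditions, collapse = ""),
                "_", n_trials)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_recording(
      default_layer_spec(conditions = conditions),
      linear_probe(n_channels = 192), n_trials = n_trials,
      fs_ap_hz = 10000, fs_lfp_hz = 2500, pia_depth_um = 1900, seed = seed
    )
  }
  .fixture_env[[key]]
}

# toy mean-waveform object on a given probe: gaussian-amplitude biphasic
# spike centred at a known depth
toy_waveform <- function(geometry, depth_um, spread_um = 30, amp_uv = 100,
                         fs_hz = 30000, inverted = FALSE) {
  tmpl <- spike_template(fs_hz, inverted)
  cd <- channel_depths(geometry)
  a <- amp_uv * exp(-abs(cd$depth_um - depth_um) / spread_um)
  list(channel_id = geometry$channel_id, w = outer(a, tmpl), fs_hz = fs_hz)
}

# minimal featured unit table for spikefeat tests
toy_units <- function(y_um, quality = "single", rate = 5,
                      times = NULL, height = 100, x_um = 11) {
  n <- length(y_um)
  tibble::tibble(
    unit_id = seq_len(n),
    quality = rep_len(quality, n),
    spike_times = times %||% replicate(n, sort(runif(50, 0, 10)),
                                       simplify = FALSE),
    mean_rate_hz = rep_len(rate, n),
    x_um = rep_len(x_um, n),
    y_um = y_um,
    height_uv = rep_len(height, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
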