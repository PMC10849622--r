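#' Pipeline configuration
#'
#' All numeric parameters of the pipeline with their standard defaults:
#' \[-40, 150\] ms analysis window with \[-40, 10\] ms baseline and
#' \[10, 150\] ms response; 300 Hz order-3 high-pass and 300-3000 Hz AP
#' band at 10 kHz; 60 Hz notch and 1-100 Hz LFP band at 1 kHz; 500 µm iCSD
#' disc with 30 µm CSD smoothing (20/30/40 µm are the studied options);
#' 20 µm depth smoothing for spectra; 55 µm pairing radius and 25 µm
#' gaussian weight for local coherence; 100 µm cylinder radius, 40 µm
#' segment, 20 µm step and 28 µm smoothing for unit density; 0.35 ms
#' duplicate-spike window with 60 µm cluster radius; 0.5 Hz noise-rate
#' threshold; 1.2 multi-unit weight; 15 % spread criterion; 65 µm
#' position radius.
#'
#' @param ... overrides of any default.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    window_ms = c(-40, 150), baseline_ms = c(-40, 10),
    response_ms = c(10, 150),
    ap_highpass_hz = 300, ap_filter_order = 3, car = "median",
    ap_band_hz = c(300, 3000), ap_fs_out_hz = 10000,
    lfp_notch_hz = 60, lfp_band_hz = c(1, 100), lfp_fs_out_hz = 1000,
    csd_disc_radius_um = 500, csd_conductivity_s_per_m = 0.3,
    csd_smooth_sigma_um = 30, csd_smooth_options_um = c(20, 30, 40),
    spectrum_smooth_sigma_um = 20, mt_nw = 3, mt_k = 5,
    power_window_ms = 10, power_step_ms = 1,
    coherence_radius_um = 55, coherence_weight_sigma_um = 25,
    density_radius_um = 100, density_window_um = 40, density_step_um = 20,
    density_sigma_um = 28, multi_weight = 1.2,
    duplicate_isi_ms = 0.35, duplicate_radius_um = 60,
    min_rate_hz = 0.5, spread_frac = 0.15, position_radius_um = 65,
    max_waveform_spikes = 1000,
    pia_offset_um = 135, match_tol_um = 150, latency_min_step_ms = 5,
    onset_criterion = 0.5,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Run the full laminar-identification pipeline
#'
#' preprocess -> \{CSD, spike features, AP spectra\} -> boundary assembly.
#' Each stage is wrapped so that a failure (or a missing input, e.g. no
#' LFP) is logged and the stages that depend on it are skipped while the
#' rest still run.
#'
#' @param x a `laminar_sim` (from [simulate_recording()]) or a list with
#'   elements `ap`, `lfp` ([probe_traces()], either may be `NULL`),
#'   `units`, `events`, `probe`.
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, every metric table and
#'   the boundary table are written as tidy TSV files.
#' @param overrides optional named vector of manual boundary depths.
#' @param prior thickness prior for boundary assembly.
#' @param verbose log stage progress and timings to stderr.
#' @return list of class `laminar_run`: `spike` (featured unit table and
#'   depth profiles), `pf`, `cf`, `pt`, `dpp` (per-condition profile
#'   lists), `csd`, `delta_csd`, `boundaries`, `log`.
#' @export
run_pipeline <- function(x, config = run_config(), out_dir = NULL,
                         overrides = NULL, prior = default_layer_spec(),
                         verbose = TRUE) {
  log <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                 msg))
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      say("stage %s FAILED: %s", name, conditionMessage(e))
      NULL
    })
    if (!is.null(out)) say("stage %s done (%.1f s)", name,
                           as.numeric(Sys.time() - t0, units = "secs"))
    out
  }
  probe <- x$probe
  events <- x$events
  conditions <- unique(events$condition)
  res <- list(config = config)

  ## ---- AP preprocessing ---------------------------------------------------
  ap_epochs <- NULL
  if (!is.null(x$ap)) {
    ap_epochs <- stage("preprocess_ap", {
      ap <- condition_ap_chain(x$ap, config$ap_highpass_hz,
                               config$ap_filter_order, car = config$car,
                               band_hz = config$ap_band_hz,
                               fs_out_hz = min(config$ap_fs_out_hz,
                                               x$ap$fs_hz))
      lapply(stats::setNames(conditions, conditions), function(cc) {
        epoch_traces(ap, events[events$condition == cc, ], config$window_ms,
                     config$baseline_ms, config$response_ms)
      })
    })
  } else say("no AP traces: AP-band metrics skipped")

  ## ---- spike features -----------------------------------------------------
  res$spike <- stage("spike_features", {
    units <- x$units
    if (is.null(units) || !nrow(units)) stop("no sorted units")
    if (!"mean_waveform" %in% names(units)) {
      stop("units carry no mean waveforms; run extract_waveforms() first")
    }
    units <- unit_features(units, probe, config$position_radius_um,
                           config$spread_frac)
    units <- remove_duplicates(units, config$duplicate_isi_ms,
                               config$duplicate_radius_um)
    units <- filter_low_rate(units, config$min_rate_hz)
    units$spread_um <- (units$upward_spread_um + units$downward_spread_um) / 2
    list(
      units = units,
      density = unit_density_profile(units, probe, config$density_radius_um,
                                     config$density_window_um,
                                     config$density_step_um,
                                     config$density_sigma_um,
                                     config$multi_weight),
      duration = depth_distribution(units, "duration_ms", probe,
                                    config$density_window_um,
                                    config$density_step_um,
                                    config$density_sigma_um),
      ratio = depth_distribution(units, "peak_trough_ratio", probe,
                                 config$density_window_um,
                                 config$density_step_um,
                                 config$density_sigma_um),
      spread = depth_distribution(units, "spread_um", probe,
                                  config$density_window_um,
                                  config$density_step_um,
                                  config$density_sigma_um)
    )
  })

  ## ---- AP-band spectral metrics -------------------------------------------
  if (!is.null(ap_epochs)) {
    res$pf <- stage("power_spectrum", lapply(ap_epochs, function(ep) {
      power_spectrum(ep, probe, config$response_ms, config$ap_band_hz,
                     config$mt_nw, config$mt_k,
                     config$spectrum_smooth_sigma_um)
    }))
    res$cf <- stage("local_coherence", lapply(ap_epochs, function(ep) {
      local_coherence(ep, probe, config$coherence_radius_um,
                      config$coherence_weight_sigma_um, config$response_ms,
                      config$ap_band_hz, config$mt_nw, config$mt_k,
                      config$spectrum_smooth_sigma_um)
    }))
    res$pt <- stage("instantaneous_power", lapply(ap_epochs, function(ep) {
      instantaneous_power(ep, probe, config$power_window_ms,
                          config$power_step_ms)
    }))
    if (!is.null(res$pt)) {
      res$dpp <- stage("delta_p_over_p", lapply(res$pt, delta_p_over_p,
                                                baseline_ms = config$baseline_ms))
    }
  }

  ## ---- CSD ----------------------------------------------------------------
  if (!is.null(x$lfp)) {
    csd_res <- stage("csd", {
      lfp <- condition_lfp(x$lfp, config$lfp_notch_hz, config$lfp_band_hz,
                           config$lfp_fs_out_hz)
      cfg <- icsd_config(config$csd_disc_radius_um,
                         config$csd_conductivity_s_per_m,
                         attr(probe, "row_pitch_um"),
                         config$csd_smooth_sigma_um)
      lapply(stats::setNames(conditions, conditions), function(cc) {
        ep <- epoch_traces(lfp, events[events$condition == cc, ],
                           config$window_ms, config$baseline_ms,
                           config$response_ms)
        csd <- inverse_csd(depth_average(ep, probe), config = cfg)
        list(csd = csd, delta = delta_csd(csd, config$baseline_ms))
      })
    })
    if (!is.null(csd_res)) {
      res$csd <- lapply(csd_res, `[[`, "csd")
      res$delta_csd <- lapply(csd_res, `[[`, "delta")
    }
  } else say("no LFP traces: CSD skipped")

  ## ---- boundary assembly --------------------------------------------------
  res$boundaries <- stage("delineate", {
    if (is.null(res$spike)) stop("spike features unavailable")
    power_profiles <- c(
      if (!is.null(res$pf)) lapply(res$pf, band_mean, config$ap_band_hz),
      if (!is.null(res$cf)) lapply(res$cf, band_mean, config$ap_band_hz)
    )
    delineate_layers(
      spike_profiles = res$spike[c("duration", "ratio", "spread")],
      power_profiles = power_profiles,
      dpp_profiles = res$dpp %||% list(),
      prior = prior, overrides = overrides,
      match_tol_um = config$match_tol_um,
      pia_offset_um = config$pia_offset_um,
      latency_min_step_ms = config$latency_min_step_ms
    )
  })
  res$log <- log

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wp <- function(p, name) {
      if (is.null(p)) return()
      if (inherits(p, "data.frame")) {
        write_profile(p, file.path(out_dir, paste0(name, ".tsv")))
      } else {
        for (cc in names(p)) {
          write_profile(p[[cc]], file.path(out_dir,
                                           paste0(name, "_", cc, ".tsv")))
        }
      }
    }
    wp(res$spike$density, "unit_density")
    wp(res$spike$duration, "spike_duration")
    wp(res$spike$ratio, "peak_trough_ratio")
    wp(res$spike$spread, "spike_spread")
    wp(res$pf, "pf"); wp(res$cf, "cf"); wp(res$pt, "pt"); wp(res$dpp, "dpp")
    wp(res$delta_csd, "delta_csd")
    if (!is.null(res$boundaries)) {
      write_boundaries(res$boundaries, file.path(out_dir, "boundaries.tsv"))
    }
    writeLines(log, file.path(out_dir, "pipeline.log"))
  }
  class(res) <- "laminar_run"
  res
}

#' @export
print.laminar_run <- function(x, ...) {
  cat("<laminar_run>\n")
  done <- intersect(c("spike", "pf", "cf", "pt", "dpp", "csd", "boundaries"),
                    names(x)[!vapply(x, is.null, logical(1))])
  cat("  stages:", paste(done, collapse = ", "), "\n")
  if (!is.null(x$boundaries)) {
    cat("  boundaries:\n")
    print(tidy(x$boundaries), n = Inf)
  }
  invisible(x)
}
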