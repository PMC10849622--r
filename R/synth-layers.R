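#' Synthetic V1 layer specification
#'
#' Per-layer generative parameters for the synthetic laminar recording:
#' thickness, relative neuron density, spatial decay length of spike
#' amplitude (a soma-size proxy), per-condition evoked firing rate, onset
#' latency, and whether the layer receives direct LGN input (such layers get
#' evoked current sinks in the synthetic LFP).
#'
#' The default stack encodes the anatomical and functional premises the
#' metrics are designed to read out: packing density ranked
#' 4Cb > 4A > 6A > 6B ~ 2/3 > 4Ca > 4B > 5 > 1; small somata (short spike
#' spread) in 4Cb and 4A, large in 5; magnocellular-recipient 4Ca responding
#' faster (40 ms) than parvocellular-recipient 4Cb (60 ms); the thin 4A
#' strongly driven only by the S-cone-OFF stimulus; L1 nearly devoid of
#' units. Layer 4Cb is never thicker than 4Ca, and L1 defaults to 135 µm
#' (within the anatomically typical 120-150 µm band).
#'
#' @param total_thickness_um total cortical thickness, 1500-2000 µm.
#' @param l1_thickness_um L1 thickness, kept within 120-150 µm.
#' @param conditions stimulus condition labels. The defaults are the four
#'   full-field color transitions used throughout: achromatic `black` and
#'   `white`, L/M cone-opponent `lm`, and S-cone `s_off`.
#' @return a tibble of class `layer_spec`, one row per layer pia -> WM plus a
#'   terminal `WM` row describing the axonal white-matter zone.
#' @export
default_layer_spec <- function(total_thickness_um = 1750,
                               l1_thickness_um = 135,
                               conditions = c("black", "white", "lm", "s_off")) {
  stopifnot(total_thickness_um >= 1500, total_thickness_um <= 2000,
            l1_thickness_um >= 120, l1_thickness_um <= 150)
  base <- tibble::tibble(
    layer = v1_layers,
    # reference thicknesses for a 1750 µm cortex with a 135 µm L1
    thickness_um = c(135, 370, 185, 80, 130, 200, 160, 170, 170, 150),
    neuron_density = c(0.03, 0.50, 0.50, 0.85, 0.35, 0.45, 1.00, 0.25, 0.70, 0.50),
    soma_spread_um = c(30, 35, 35, 26, 40, 33, 25, 45, 32, 32),
    onset_latency_ms = c(NA, 70, 70, 60, 70, 40, 60, 75, 50, 60),
    receives_lgn = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE,
                     TRUE, FALSE)
  )
  # L1 pinned inside its anatomical band; remaining layers scaled
  base$thickness_um[1] <- l1_thickness_um
  rest <- base$thickness_um[-1]
  base$thickness_um[-1] <- rest * (total_thickness_um - l1_thickness_um) / sum(rest)
  # per-condition evoked rates (Hz), rows match layers
  evoked <- rbind(
    L1      = c(black = 0,  white = 0,  lm = 0,  s_off = 0),
    `L2-3A` = c(8,  7,  8,  5),
    L3B     = c(8,  7,  8,  6),
    L4A     = c(5,  4,  4,  25),
    L4B     = c(6,  5,  4,  3),
    L4Ca    = c(25, 20, 5,  5),
    L4Cb    = c(20, 15, 20, 5),
    L5      = c(5,  4,  4,  3),
    L6A     = c(14, 12, 10, 8),
    L6B     = c(8,  7,  6,  5)
  )
  missing_cond <- setdiff(conditions, colnames(evoked))
  if (length(missing_cond)) {
    for (cc in missing_cond) evoked <- cbind(evoked, rep(5, nrow(evoked)))
    colnames(evoked)[(ncol(evoked) - length(missing_cond) + 1):ncol(evoked)] <-
      missing_cond
  }
  base$evoked_rate_hz <- lapply(seq_len(nrow(base)), function(i) {
    stats::setNames(as.numeric(evoked[i, conditions]), conditions)
  })
  base$baseline_rate_hz <- c(0.5, rep(2, 9))
  # terminal white-matter zone: LGN axons, inverted waveforms
  wm <- tibble::tibble(
    layer = "WM", thickness_um = NA_real_, neuron_density = 1.50,
    soma_spread_um = 14, onset_latency_ms = 30, receives_lgn = FALSE,
    evoked_rate_hz = list(stats::setNames(rep(12, length(conditions)), conditions)),
    baseline_rate_hz = 5
  )
  out <- rbind(base, wm)
  attr(out, "conditions") <- conditions
  class(out) <- c("layer_spec", class(out))
  out
}

#' Ground-truth boundaries implied by a layer spec
#'
#' Stacks the layer thicknesses downward from the pia on the shared depth
#' axis. The L4Ca/L4Cb boundary falls where those two layers meet.
#'
#' @param spec a [default_layer_spec()] tibble.
#' @param pia_depth_um depth of the pial surface above the deepest contact.
#' @return a [layer_boundaries()] object with provenance `manual`.
#' @export
spec_boundaries <- function(spec, pia_depth_um = 2200) {
  cortex <- spec[spec$layer != "WM", ]
  stopifnot(nrow(cortex) == length(v1_layers))
  bottoms <- pia_depth_um - cumsum(cortex$thickness_um)
  depths <- c(pia_depth_um, bottoms)
  names(depths) <- c("pia/L1", "L1/L2", "L2-3A/L3B", "L3B/L4A", "L4A/L4B",
                     "L4B/L4C", "L4Ca/L4Cb", "L4Cb/L5", "L5/L6A", "L6A/L6B",
                     "L6/WM")
  layer_boundaries(depths, provenance = "manual")
}
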