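#' Fill undetected boundaries by anatomical fallback rules
#'
#' Requires the five anchor boundaries (`L1/L2`, `L4B/L4C`, `L4Cb/L5`,
#' `L5/L6A`, `L6/WM`), detected or manual, and fills every missing boundary
#' with the standard anatomical estimates:
#'
#' * L4A is 50 µm thick and L4B is half the thickness of L4C (used when no
#'   L4A electrical signature was found);
#' * the L4Ca/L4Cb border sits halfway down L4C (subject to L4Cb never
#'   being thicker than L4Ca);
#' * the pia sits `pia_offset_um` (120-150, default 135) above L1/L2;
#' * L2-3A/L3B sits two-thirds of the way from L1/L2 to the top of L4A;
#' * L6A/L6B sits halfway from L5/L6A to L6/WM.
#'
#' Filled boundaries are tagged `provenance = "fallback"`.
#'
#' @param partial named numeric vector of known boundary depths (µm), or a
#'   partial `layer_boundaries` tibble.
#' @param provenance provenance of the supplied boundaries (recycled;
#'   ignored when `partial` is a tibble).
#' @param pia_offset_um pia/L1 offset above L1/L2 (µm).
#' @return a complete, validated [layer_boundaries()] object.
#' @export
apply_fallbacks <- function(partial, provenance = "detected",
                            pia_offset_um = 135) {
  stopifnot(pia_offset_um >= 120, pia_offset_um <= 150)
  if (inherits(partial, "data.frame")) {
    depths <- stats::setNames(partial$depth_um, partial$boundary)
    prov <- stats::setNames(partial$provenance, partial$boundary)
  } else {
    depths <- partial
    prov <- stats::setNames(rep_len(provenance, length(partial)),
                            names(partial))
  }
  anchors <- c("L1/L2", "L4B/L4C", "L4Cb/L5", "L5/L6A", "L6/WM")
  missing_anchors <- setdiff(anchors, names(depths))
  if (length(missing_anchors)) {
    stop("missing anchor boundaries: ",
         paste(missing_anchors, collapse = ", "), call. = FALSE)
  }
  put <- function(name, value) {
    if (!name %in% names(depths) || is.na(depths[name])) {
      depths[name] <<- value
      prov[name] <<- "fallback"
    }
  }
  t4c <- depths[["L4B/L4C"]] - depths[["L4Cb/L5"]]
  put("L4A/L4B", depths[["L4B/L4C"]] + t4c / 2)   # L4B half of L4C
  put("L3B/L4A", depths[["L4A/L4B"]] + 50)        # L4A 50 µm thick
  put("L4Ca/L4Cb", depths[["L4Cb/L5"]] + t4c / 2) # halfway down L4C
  # clamp a detected alpha/beta border so L4Cb <= L4Ca
  mid <- depths[["L4Cb/L5"]] + t4c / 2
  if (depths[["L4Ca/L4Cb"]] > mid + 1e-9) {
    depths[["L4Ca/L4Cb"]] <- mid
    prov[["L4Ca/L4Cb"]] <- "fallback"
  }
  put("pia/L1", depths[["L1/L2"]] + pia_offset_um)
  put("L2-3A/L3B", depths[["L1/L2"]] -
        2 / 3 * (depths[["L1/L2"]] - depths[["L3B/L4A"]]))
  put("L6A/L6B", (depths[["L5/L6A"]] + depths[["L6/WM"]]) / 2)
  out <- tibble::tibble(
    boundary = v1_boundaries,
    depth_um = as.numeric(depths[v1_boundaries]),
    provenance = as.character(prov[v1_boundaries])
  )
  class(out) <- c("layer_boundaries", class(out))
  validate_boundaries(out)
  out
}

#' Assemble layer boundaries from metric profiles
#'
#' Codifies the delineation workflow: anchor the cortex with the L6/WM
#' border from spike features and the L1/L2 border from the shallowest
#' strong power/coherence edge; scale an anatomical thickness prior between
#' those anchors to get expected boundary positions; assign the remaining
#' sharp edges (L4B/L4C, L4Cb/L5, L5/L6A, L6A/L6B) to the sign-consistent
#' candidates nearest their expected positions; search for the thin L4A
#' band across all conditions; place the L4Ca/L4Cb border at the largest
#' latency step inside L4C; and fill everything still missing with the
#' anatomical fallback rules. Manual overrides (same schema as the boundary
#' table) take precedence and are tagged `provenance = "manual"`.
#'
#' @param spike_profiles list with [depth_profile()]s `duration`, `ratio`
#'   and optionally `spread`.
#' @param power_profiles list of band-mean [depth_profile()]s (Pf per
#'   condition; Cf profiles may be appended).
#' @param dpp_profiles list of [depth_time_profile()]s (dP/P per
#'   condition); optional, used for L4A and the latency border.
#' @param prior a [default_layer_spec()] (thickness prior only).
#' @param overrides optional named vector of manual boundary depths (µm).
#' @param match_tol_um maximum distance between an edge and its expected
#'   position (µm).
#' @param min_cortex_um minimum plausible cortical thickness (µm), used
#'   when picking the L1/L2 edge.
#' @param pia_offset_um see [apply_fallbacks()].
#' @param latency_min_step_ms see [detect_alpha_beta()].
#' @return a [layer_boundaries()] object; the pooled evidence table is in
#'   `attr(, "evidence")`.
#' @export
delineate_layers <- function(spike_profiles, power_profiles,
                             dpp_profiles = list(),
                             prior = default_layer_spec(),
                             overrides = NULL, match_tol_um = 150,
                             min_cortex_um = 1200, pia_offset_um = 135,
                             latency_min_step_ms = 5) {
  found <- c()
  prov <- c()
  note <- function(name, depth, p = "detected") {
    found[name] <<- depth
    prov[name] <<- p
  }
  if (!is.null(overrides)) {
    for (nm in names(overrides)) note(nm, overrides[[nm]], "manual")
  }

  ## 1. white matter border
  if (!"L6/WM" %in% names(found)) {
    wm <- detect_wm_border(spike_profiles$duration, spike_profiles$ratio,
                           spike_profiles$spread)
    if (nrow(wm)) note("L6/WM", wm$depth_um)
  }
  evidence <- evidence_tbl()

  ## 2. pooled power/coherence edges
  for (p in power_profiles) {
    evidence <- rbind(evidence, detect_edges(p))
  }

  ## 3. L1/L2: shallowest strong falling-with-depth edge above min cortex
  if (!"L1/L2" %in% names(found) && "L6/WM" %in% names(found)) {
    cand <- evidence[evidence$sign < 0 &
                       evidence$depth_um >= found[["L6/WM"]] + min_cortex_um, ]
    if (nrow(cand)) note("L1/L2", max(cand$depth_um))
  }
  need <- setdiff(c("L6/WM", "L1/L2"), names(found))
  if (length(need)) {
    stop("could not anchor the cortex; missing: ",
         paste(need, collapse = ", "),
         " (supply them via `overrides`)", call. = FALSE)
  }

  ## 4. expected positions from the scaled thickness prior
  th <- prior$thickness_um[match(v1_layers, prior$layer)]
  names(th) <- v1_layers
  below_l1 <- th[setdiff(v1_layers, "L1")]
  s <- (found[["L1/L2"]] - found[["L6/WM"]]) / sum(below_l1)
  exp_d <- found[["L1/L2"]] - cumsum(below_l1 * s)
  names(exp_d) <- c("L2-3A/L3B", "L3B/L4A", "L4A/L4B", "L4B/L4C",
                    "L4Ca/L4Cb", "L4Cb/L5", "L5/L6A", "L6A/L6B", "L6/WM")

  ## 5. assign sharp edges by sign and proximity to expectation
  targets <- list(`L4B/L4C` = -1, `L4Cb/L5` = 1, `L5/L6A` = -1,
                  `L6A/L6B` = 1)
  for (nm in names(targets)) {
    if (nm %in% names(found)) next
    cand <- evidence[evidence$sign == targets[[nm]] &
                       abs(evidence$depth_um - exp_d[[nm]]) <= match_tol_um, ]
    if (nrow(cand)) note(nm, cand$depth_um[which.max(cand$score)])
  }

  ## 6. thin L4A band (max over conditions and metrics)
  if (!all(c("L3B/L4A", "L4A/L4B") %in% names(found))) {
    zone <- c(exp_d[["L4A/L4B"]] - 80, exp_d[["L3B/L4A"]] + 80)
    if ("L4B/L4C" %in% names(found)) {
      zone[1] <- max(zone[1], found[["L4B/L4C"]] + 20)
    }
    band_profiles <- c(power_profiles,
                       lapply(dpp_profiles, time_mean))
    band <- detect_l4a_band(band_profiles, zone)
    if (nrow(band) == 2) {
      note("L3B/L4A", band$depth_um[band$boundary == "L3B/L4A"])
      note("L4A/L4B", band$depth_um[band$boundary == "L4A/L4B"])
    }
  }

  ## 7. alpha/beta border from the latency step inside L4C
  if (!"L4Ca/L4Cb" %in% names(found) &&
      all(c("L4B/L4C", "L4Cb/L5") %in% names(found))) {
    l4c <- c(found[["L4Cb/L5"]], found[["L4B/L4C"]])
    best <- NULL
    for (dpp in dpp_profiles) {
      ev <- detect_alpha_beta(latency_profile(dpp), l4c,
                              min_step_ms = latency_min_step_ms)
      if (nrow(ev) && (is.null(best) || ev$score > best$score)) best <- ev
    }
    if (!is.null(best)) note("L4Ca/L4Cb", best$depth_um)
  }

  out <- apply_fallbacks(
    tibble::tibble(boundary = names(found), depth_um = as.numeric(found),
                   provenance = as.character(prov)),
    pia_offset_um = pia_offset_um
  )
  attr(out, "evidence") <- evidence
  out
}

#' Assign sorted units to layers
#'
#' Layers are half-open depth intervals `[bottom, top)`: a unit exactly on
#' a boundary belongs to the layer above. Units above the pia are labeled
#' `above_pia`; units below the L6/WM border are labeled `WM`.
#'
#' @param units featured sorted-unit tibble (`y_um`).
#' @param boundaries a complete [layer_boundaries()] object.
#' @return `units` with a `layer` column.
#' @export
assign_units_to_layers <- function(units, boundaries) {
  d <- boundaries$depth_um[match(v1_boundaries, boundaries$boundary)]
  tops <- d[-length(d)]
  bots <- d[-1]
  units$layer <- vapply(units$y_um, function(y) {
    if (y >= d[1]) return("above_pia")
    if (y < d[length(d)]) return("WM")
    v1_layers[which(y < tops & y >= bots)[1]]
  }, character(1))
  units
}
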