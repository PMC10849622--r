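#' Boundary evidence tables
#'
#' Detectors emit ranked candidate boundaries as tibbles with columns
#' `boundary` (may be `NA` before assignment), `depth_um`, `score`
#' (dimensionless edge strength), `sign` (+1 if the metric increases with
#' depth across the edge, i.e. is larger on the pial side), `source`
#' (metric name) and `condition`.
#'
#' @name boundary_evidence
NULL

evidence_tbl <- function(boundary = character(), depth_um = numeric(),
                         score = numeric(), sign = numeric(),
                         source = character(), condition = character()) {
  tibble::tibble(boundary = boundary, depth_um = depth_um, score = score,
                 sign = sign, source = source, condition = condition)
}

#' Detect the gray matter / white matter border from spike features
#'
#' White matter contains only axonal sources: inverted waveforms (negative
#' spike duration, peak-trough ratio below -1) and small spatial spread.
#' The detector finds the deepest depth above which, over a persistence
#' window, the smoothed depth distributions look somatic throughout:
#' duration > 0, ratio > -1, and mean spread above the white-matter floor.
#' A recording with no white-matter span (nothing non-somatic below) yields
#' no candidate.
#'
#' @param duration,ratio,spread [depth_profile()]s of spike duration (ms),
#'   peak-trough ratio, and mean axial spread (µm) from
#'   [depth_distribution()]. `spread` may be `NULL` to use shape criteria
#'   only.
#' @param persistence_um depth span over which the somatic criteria must
#'   hold (µm).
#' @param spread_floor_um white-matter spread floor (µm).
#' @return a [boundary_evidence] tibble with zero or one row
#'   (`boundary = "L6/WM"`).
#' @export
detect_wm_border <- function(duration, ratio, spread = NULL,
                             persistence_um = 40, spread_floor_um = 50) {
  d <- duration$depth_um
  step <- diff(sort(unique(d))[1:2])
  somatic <- duration$value > 0 & ratio$value > -1
  if (!is.null(spread)) {
    somatic <- somatic & (spread$value > spread_floor_um | is.na(spread$value))
  }
  somatic[is.na(somatic)] <- NA
  np <- max(1L, round(persistence_um / step))
  n <- length(somatic)
  ok_run <- vapply(seq_len(n), function(i) {
    w <- somatic[i:min(n, i + np)]
    all(!is.na(w)) && all(w)
  }, logical(1))
  runs <- which(ok_run)
  if (!length(runs)) return(evidence_tbl())
  # deepest persistent somatic run that has non-somatic evidence below it
  below_ns <- vapply(runs, function(i) {
    any(!somatic[seq_len(i - 1)] & !is.na(somatic[seq_len(i - 1)]))
  }, logical(1))
  runs <- runs[below_ns]
  if (!length(runs)) return(evidence_tbl())    # all-somatic recording
  i0 <- min(runs)
  ns_below <- which(!somatic[seq_len(i0 - 1)] & !is.na(somatic[seq_len(i0 - 1)]))
  d_lo <- d[max(ns_below)]
  evidence_tbl("L6/WM", (d[i0] + d_lo) / 2, score = 1, sign = 1,
               source = "spike_features", condition = NA_character_)
}

#' Detect edges in a band-averaged depth profile
#'
#' Max-normalises the profile, optionally smooths it, and returns the local
#' extrema of its depth derivative whose magnitude exceeds
#' `min_gradient_factor` times the median absolute gradient, ranked by
#' |gradient|. Edge `sign` is the sign of the derivative (+1: the metric
#' grows toward the pia across the edge). Boundary identities are assigned
#' later by the assembler using ordering and template priors.
#'
#' @param profile a [depth_profile()] (e.g. [band_mean()] of Pf or Cf).
#' @param smooth_sigma_um extra smoothing before differentiation (µm).
#' @param min_gradient_factor significance threshold as a multiple of the
#'   median absolute gradient.
#' @return a [boundary_evidence] tibble ranked by score (possibly empty).
#' @export
detect_edges <- function(profile, smooth_sigma_um = 20,
                         min_gradient_factor = 2) {
  ord <- order(profile$depth_um)
  d <- profile$depth_um[ord]
  v <- profile$value[ord]
  mx <- max(abs(v), na.rm = TRUE)
  if (!is.finite(mx) || mx == 0) return(evidence_tbl())
  v <- v / mx
  step <- diff(d[1:2])
  if (smooth_sigma_um > 0) v <- gaussian_smooth(v, smooth_sigma_um, step)
  n <- length(v)
  g <- c(NA, (v[3:n] - v[1:(n - 2)]) / (d[3:n] - d[1:(n - 2)]), NA)
  ag <- abs(g)
  mx_g <- max(ag, na.rm = TRUE)
  if (!is.finite(mx_g) || mx_g == 0) return(evidence_tbl())  # flat profile
  # floor the significance threshold so that zero-gradient plateaus never
  # qualify (the median gradient of a near-piecewise-constant profile is 0)
  thr <- max(min_gradient_factor * median(ag, na.rm = TRUE), 1e-9 * mx_g)
  is_ext <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    if (is.na(ag[i]) || ag[i] < thr) next
    if (ag[i] >= max(ag[i - 1], 0, na.rm = TRUE) &&
        ag[i] >= max(ag[i + 1], 0, na.rm = TRUE)) is_ext[i] <- TRUE
  }
  idx <- which(is_ext)
  if (!length(idx)) return(evidence_tbl())
  # a step falling between two samples yields a two-sample gradient
  # plateau: merge adjacent extrema of the same sign into one edge at
  # their centre
  grp <- cumsum(c(1, diff(idx) > 1 | diff(sign(g[idx])) != 0))
  depth <- tapply(d[idx], grp, mean)
  score <- tapply(ag[idx], grp, max)
  sgn <- tapply(sign(g[idx]), grp, `[`, 1)
  out <- evidence_tbl(rep(NA_character_, length(depth)), as.numeric(depth),
                      as.numeric(score), as.numeric(sgn),
                      profile$metric[1],
                      rep(profile$condition[1], length(depth)))
  out[order(-out$score), ]
}

#' Detect the thin L4A band
#'
#' Searches a set of depth profiles (one per metric and stimulus condition)
#' for a locally elevated band of width 30-110 µm inside the expected zone
#' above L4B; the band need only appear under one condition (the maximum
#' over conditions is taken). The top of the best band is the L3B/L4A
#' border, the bottom the L4A/L4B border.
#'
#' @param profiles list of [depth_profile()]s (band-mean Pf/Cf or time-mean
#'   dP/P per condition).
#' @param zone_um length-2 search zone (depths, µm).
#' @param width_um_range admissible band widths (µm).
#' @param min_excess minimum elevation over the zone background, as a
#'   fraction of the zone's value range.
#' @return a [boundary_evidence] tibble with zero or two rows
#'   (`L3B/L4A` and `L4A/L4B`).
#' @export
detect_l4a_band <- function(profiles, zone_um, width_um_range = c(30, 110),
                            min_excess = 0.3) {
  best <- NULL
  for (p in profiles) {
    ord <- order(p$depth_um)
    d <- p$depth_um[ord]; v <- p$value[ord]
    sel <- d >= zone_um[1] & d <= zone_um[2] & !is.na(v)
    if (sum(sel) < 3) next
    dz <- d[sel]; vz <- v[sel]
    rng <- max(vz) - min(vz)
    if (rng <= 0) next
    bg <- median(vz)
    step <- diff(dz[1:2])
    # scan a ladder of elevation thresholds: a band wider than the
    # admissible range at a low threshold may still resolve to an
    # admissible core at a higher one
    for (excess in seq(min_excess, 0.75, by = 0.1)) {
      elevated <- vz > bg + excess * rng
      if (!any(elevated)) next
      r <- rle(elevated)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (ri in which(r$values)) {
        # a band must be interior to the zone: runs touching a zone edge
        # are shoulders of a neighbouring layer, not bands
        if (starts[ri] == 1 || ends[ri] == length(vz)) next
        lo <- dz[starts[ri]] - step / 2
        hi <- dz[ends[ri]] + step / 2
        if (hi - lo < width_um_range[1] || hi - lo > width_um_range[2]) next
        sc <- mean(vz[starts[ri]:ends[ri]] - bg) / rng
        if (is.null(best) || sc > best$score) {
          best <- list(top = hi, bottom = lo, score = sc,
                       source = p$metric[1], condition = p$condition[1])
        }
      }
    }
  }
  if (is.null(best)) return(evidence_tbl())
  evidence_tbl(c("L3B/L4A", "L4A/L4B"), c(best$top, best$bottom),
               rep(best$score, 2), c(-1, 1), rep(best$source, 2),
               rep(best$condition %||% NA_character_, 2))
}

#' Detect the L4Ca/L4Cb border from response latencies
#'
#' Finds the largest onset-latency step inside L4C (magnocellular-recipient
#' L4Ca responds earlier than parvocellular-recipient L4Cb). The resulting
#' border is constrained so that L4Cb is not thicker than L4Ca: a step that
#' would violate this is clamped to the L4C midpoint. A step smaller than
#' `min_step_ms` yields no candidate (the midpoint fallback applies
#' instead).
#'
#' @param latency a [depth_profile()] of onset latencies (ms), e.g. from
#'   [latency_profile()].
#' @param l4c_um length-2 depth range of L4C (bottom, top), µm.
#' @param min_step_ms significance threshold on the latency step (ms).
#' @return a [boundary_evidence] tibble with zero or one row
#'   (`L4Ca/L4Cb`).
#' @export
detect_alpha_beta <- function(latency, l4c_um, min_step_ms = 5) {
  ord <- order(latency$depth_um)
  d <- latency$depth_um[ord]; v <- latency$value[ord]
  # trim one bin at each end: spikes from the neighbouring layers bleed
  # into the outermost rows of L4C
  sel <- d >= l4c_um[1] + 1e-9 & d <= l4c_um[2] - 1e-9 & !is.na(v)
  if (sum(sel) < 4) return(evidence_tbl())
  dz <- d[sel]; vz <- v[sel]
  n <- length(vz)
  stat <- vapply(2:(n - 1), function(i) {
    a <- vz[1:(i - 1)]; b <- vz[i:n]
    diff <- mean(a) - mean(b)                  # deep latency minus shallow
    sp <- sqrt((sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n - 2))
    se <- max(sp, 0.5) * sqrt(1 / length(a) + 1 / length(b))
    c(diff, abs(diff) / se)
  }, numeric(2))
  i_best <- which.max(stat[2, ]) + 1L
  diff <- stat[1, i_best - 1L]
  if (abs(diff) < min_step_ms) return(evidence_tbl())
  border <- (dz[i_best - 1L] + dz[i_best]) / 2
  mid <- mean(l4c_um)
  if (border > mid) border <- mid              # L4Cb must not exceed L4Ca
  evidence_tbl("L4Ca/L4Cb", border, stat[2, i_best - 1L],
               sign(diff), "onset_latency", latency$condition[1])
}
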