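#' Build a cross-penetration layer template
#'
#' Averages per-layer thicknesses across penetrations and stacks them into
#' a template boundary set, with the L6/WM border at depth 0.
#'
#' @param boundary_list list of complete [layer_boundaries()] objects, one
#'   per penetration.
#' @return list with `boundaries` (the template, provenance `manual`) and
#'   `thicknesses` (tibble: `layer`, `mean_um`, `sd_um`, plus one
#'   `pen<i>_um` column per penetration).
#' @export
build_template <- function(boundary_list) {
  stopifnot(length(boundary_list) >= 1)
  per_pen <- lapply(boundary_list, function(b) layer_thicknesses(b)$thickness_um)
  m <- do.call(cbind, per_pen)
  rownames(m) <- v1_layers
  mean_th <- rowMeans(m)
  depths <- c(sum(mean_th), sum(mean_th) - cumsum(mean_th))
  names(depths) <- v1_boundaries
  thick <- tibble::tibble(layer = v1_layers, mean_um = mean_th,
                          sd_um = apply(m, 1, stats::sd))
  for (i in seq_along(boundary_list)) thick[[paste0("pen", i, "_um")]] <- m[, i]
  list(boundaries = layer_boundaries(depths, provenance = "manual"),
       thicknesses = thick)
}

#' Piecewise-linear depth map between boundary sets
#'
#' Maps depths of one penetration onto the template axis by linearly
#' scaling each layer interval onto the corresponding template interval;
#' outside the cortex the map continues with slope 1.
#'
#' @param from,to complete [layer_boundaries()] objects.
#' @return a function mapping depths (µm) from `from`'s axis to `to`'s.
#' @export
depth_map <- function(from, to) {
  xf <- from$depth_um[match(v1_boundaries, from$boundary)]
  xt <- to$depth_um[match(v1_boundaries, to$boundary)]
  ord <- order(xf)
  xf <- xf[ord]; xt <- xt[ord]
  function(depth_um) {
    y <- stats::approx(xf, xt, xout = depth_um, rule = 2)$y
    below <- depth_um < xf[1]
    above <- depth_um > xf[length(xf)]
    y[below] <- xt[1] - (xf[1] - depth_um[below])
    y[above] <- xt[length(xt)] + (depth_um[above] - xf[length(xf)])
    y
  }
}

#' Align a metric profile to the layer template
#'
#' Warps a penetration's depth profile onto the template depth grid: each
#' layer is linearly scaled onto the template layer, values are
#' re-interpolated by cubic spline at the template grid points, and
#' (optionally) normalised — profiles are normalised per stimulus before
#' averaging across penetrations.
#'
#' @param profile a [depth_profile()].
#' @param boundaries the penetration's complete [layer_boundaries()].
#' @param template the template [layer_boundaries()] (e.g. from
#'   [build_template()]).
#' @param step_um template grid step (µm).
#' @param normalize `"max_abs"` (divide by the maximum absolute value,
#'   default), `"zscore"`, or `"none"`.
#' @return a [depth_profile()] on the template grid; depths outside the
#'   penetration's span are `NA`.
#' @export
align_to_template <- function(profile, boundaries, template, step_um = 20,
                              normalize = c("max_abs", "zscore", "none")) {
  normalize <- match.arg(normalize)
  span_b <- range(boundaries$depth_um)
  span_p <- range(profile$depth_um)
  if (span_p[1] > span_b[1] || span_p[2] < span_b[2]) {
    stop("profile depth span does not cover its boundaries", call. = FALSE)
  }
  fmap <- depth_map(boundaries, template)
  x <- fmap(profile$depth_um)
  v <- profile$value
  if (normalize == "max_abs") {
    mx <- max(abs(v), na.rm = TRUE)
    if (is.finite(mx) && mx > 0) v <- v / mx
  } else if (normalize == "zscore") {
    v <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
  }
  ok <- !is.na(v)
  grid <- seq(min(template$depth_um) - step_um,
              max(template$depth_um) + step_um, by = step_um)
  out <- rep(NA_real_, length(grid))
  inside <- grid >= min(x[ok]) & grid <= max(x[ok])
  if (sum(ok) >= 4) {
    out[inside] <- stats::spline(x[ok], v[ok], xout = grid[inside],
                                 method = "natural")$y
  } else if (sum(ok) >= 2) {
    out[inside] <- stats::approx(x[ok], v[ok], xout = grid[inside])$y
  }
  depth_profile(grid, out, metric = profile$metric[1],
                condition = profile$condition[1], eye = profile$eye[1])
}

#' Average aligned profiles across penetrations
#'
#' @param profiles list of [depth_profile()]s already on a common
#'   (template) grid.
#' @return a [depth_profile()] of the pointwise mean (missing values
#'   skipped).
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  d <- profiles[[1]]$depth_um
  vals <- vapply(profiles, function(p) {
    stopifnot(identical(p$depth_um, d))
    p$value
  }, numeric(length(d)))
  depth_profile(d, rowMeans(as.matrix(vals), na.rm = TRUE),
                metric = profiles[[1]]$metric[1])
}
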