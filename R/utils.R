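#' @useDynLib laminarid, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom stats fft median rnorm rpois runif sd spline approx
NULL

#' Gaussian smoothing along depth
#'
#' 1-D gaussian filter with reflective boundary handling, used for CSD
#' profiles and all depth distributions. `NA` entries are skipped: the kernel
#' is renormalised over the non-missing neighbours, and entries that have no
#' non-missing neighbour stay `NA`.
#'
#' @param x numeric vector sampled on a uniform grid.
#' @param sigma gaussian width in grid units of `step`.
#' @param step grid step (same units as `sigma`).
#' @return smoothed vector, same length.
#' @export
gaussian_smooth <- function(x, sigma, step = 1) {
  if (sigma <= 0 || length(x) < 2) return(x)
  s <- sigma / step
  half <- max(1L, ceiling(4 * s))
  k <- exp(-(-half:half)^2 / (2 * s^2))
  k <- k / sum(k)
  n <- length(x)
  # reflective padding
  pre <- x[pmin(n, pmax(1, (half + 1):2))]
  post <- x[pmin(n, pmax(1, (n - 1):(n - half)))]
  xp <- c(pre, x, post)
  ok <- !is.na(xp)
  xz <- ifelse(ok, xp, 0)
  num <- as.numeric(stats::filter(xz, k, sides = 2))
  den <- as.numeric(stats::filter(as.numeric(ok), k, sides = 2))
  out <- (num / den)[(half + 1):(half + n)]
  out[is.nan(out)] <- NA_real_
  out
}

#' Gaussian-smooth a matrix along its rows (depth dimension)
#' @noRd
gaussian_smooth_rows <- function(m, sigma, step) {
  if (sigma <= 0) return(m)
  apply(m, 2, gaussian_smooth, sigma = sigma, step = step)
}

#' Sliding mean over a centered window
#'
#' @param x numeric vector.
#' @param width odd window width in samples.
#' @return centred moving average, `NA`-padded at the edges shortened by
#'   partial-window renormalisation.
#' @noRd
sliding_mean <- function(x, width) {
  if (width <= 1) return(x)
  k <- rep(1 / width, width)
  y <- as.numeric(stats::filter(x, k, sides = 2))
  # renormalise edges over the available samples
  n <- length(x)
  half <- (width - 1L) %/% 2L
  cs <- cumsum(x)
  for (i in seq_len(min(half, n))) {
    y[i] <- cs[min(n, i + half)] / (min(n, i + half))
    j <- n - i + 1L
    y[j] <- (cs[n] - if (j - half - 1L >= 1L) cs[j - half - 1L] else 0) /
      (n - max(1L, j - half) + 1L)
  }
  y
}

#' Median across channels, per sample
#' @noRd
sample_median <- function(m) {
  row_medians_cpp(m)
}

#' Deterministic child seed
#' @noRd
child_seed <- function(seed, k) {
  (seed * 48271 + k * 1299709) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
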