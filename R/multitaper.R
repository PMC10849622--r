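#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, via the standard symmetric tridiagonal eigenproblem whose
#' eigenvectors are the tapers. Tapers are normalised to unit energy; signs
#' follow the usual convention (positive mean for symmetric tapers, positive
#' initial slope for antisymmetric ones). Results are cached per
#' `(n, nw, k)`.
#'
#' @param n taper length (samples).
#' @param nw time-bandwidth product.
#' @param k number of tapers (`k < 2 * nw` for well-concentrated tapers).
#' @return n x k matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 3, k = 5) {
  stopifnot(n >= 2, k >= 1, nw > 0)
  key <- paste(n, nw, k, sep = "_")
  hit <- .taper_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  i <- 0:(n - 1)
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A[cbind(2:n, 1:(n - 1))] <- off
  A[cbind(1:(n - 1), 2:n)] <- off
  ev <- eigen(A, symmetric = TRUE)
  v <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    if (j %% 2 == 1) {                       # symmetric taper: positive mean
      if (sum(v[, j]) < 0) v[, j] <- -v[, j]
    } else {                                 # antisymmetric: positive start
      if (v[2, j] - v[1, j] < 0) v[, j] <- -v[, j]
    }
  }
  assign(key, v, envir = .taper_cache)
  v
}

.taper_cache <- new.env(parent = emptyenv())

#' Tapered FFTs of a multichannel segment
#'
#' @param x samples x channels matrix.
#' @param tapers n x k DPSS matrix.
#' @param bins frequency-bin indices to keep (1-based into the FFT).
#' @return complex array `length(bins)` x k x channels.
#' @noRd
tapered_fft <- function(x, tapers, bins) {
  n <- nrow(x); nch <- ncol(x); k <- ncol(tapers)
  out <- array(0i, dim = c(length(bins), k, nch))
  for (j in seq_len(k)) {
    out[, j, ] <- stats::mvfft(x * tapers[, j])[bins, , drop = FALSE]
  }
  out
}

#' Multitaper power spectral density
#'
#' Average over tapers of the tapered periodograms, one-sided, in
#' units^2/Hz.
#'
#' @param x numeric vector or samples x channels matrix.
#' @param fs_hz sampling rate.
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @param band_hz frequency band to return.
#' @return list with `freq_hz` and `psd` (frequencies x channels matrix).
#' @export
mt_psd <- function(x, fs_hz, nw = 3, k = 5, band_hz = c(0, fs_hz / 2)) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n < 2 * k) stop("segment shorter than taper support", call. = FALSE)
  freqs <- (0:(n - 1)) * fs_hz / n
  bins <- which(freqs >= band_hz[1] & freqs <= min(band_hz[2], fs_hz / 2))
  tp <- dpss_tapers(n, nw, k)
  X <- tapered_fft(x, tp, bins)
  psd <- apply(Mod(X)^2, c(1, 3), mean) * 2 / fs_hz
  list(freq_hz = freqs[bins], psd = psd)
}

#' Multitaper magnitude-squared coherence of a channel pair
#'
#' `C_xy(f) = |S_xy(f)|^2 / (S_xx(f) S_yy(f))` with auto- and cross-spectra
#' estimated by averaging over DPSS tapers (and over trials when the inputs
#' are matrices with one trial per column). Values lie in \[0, 1\];
#' amplitude scaling of either signal leaves the coherence unchanged. At
#' least 2 tapers are required — a single-taper coherence estimate is
#' identically 1.
#'
#' @param x,y numeric vectors (one segment) or samples x trials matrices.
#' @param fs_hz sampling rate.
#' @param nw,k multitaper parameters.
#' @param band_hz frequency band to return.
#' @return list with `freq_hz` and `coherence`.
#' @export
coherence_pair <- function(x, y, fs_hz, nw = 3, k = 5,
                           band_hz = c(300, 3000)) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  if (!is.matrix(y)) y <- matrix(y, ncol = 1)
  stopifnot(nrow(x) == nrow(y), ncol(x) == ncol(y))
  if (k < 2) stop("coherence needs >= 2 tapers", call. = FALSE)
  n <- nrow(x)
  freqs <- (0:(n - 1)) * fs_hz / n
  bins <- which(freqs >= band_hz[1] & freqs <= min(band_hz[2], fs_hz / 2))
  tp <- dpss_tapers(n, nw, k)
  sxx <- syy <- numeric(length(bins))
  sxy <- complex(length(bins))
  for (tr in seq_len(ncol(x))) {
    X <- tapered_fft(x[, tr, drop = FALSE], tp, bins)[, , 1]
    Y <- tapered_fft(y[, tr, drop = FALSE], tp, bins)[, , 1]
    sxx <- sxx + rowSums(Mod(X)^2)
    syy <- syy + rowSums(Mod(Y)^2)
    sxy <- sxy + rowSums(X * Conj(Y))
  }
  if (any(sxx == 0) || any(syy == 0)) {
    stop("zero-power channel: coherence undefined", call. = FALSE)
  }
  list(freq_hz = freqs[bins], coherence = Mod(sxy)^2 / (sxx * syy))
}
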