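# reference DPSS values computed independently with
# scipy.signal.windows.dpss(64, 3, 3, norm = 2), matching sign conventions
scipy_dpss_64_3 <- rbind(
  c(0.0003564442, 0.0673524676, 0.2297040105, 0.0785507489, 0.0003564442),
  c(0.0025072425, 0.1551844506, 0.0148643136, -0.1683405905, -0.0025072425),
  c(0.0118392207, 0.1947723213, -0.1533556899, 0.1893441482, 0.0118392207)
)

test_that("DPSS tapers match the independent reference and are orthonormal", {
  tp <- dpss_tapers(64, 3, 3)
  expect_equal(t(tp[c(1, 16, 32, 48, 64), ]), scipy_dpss_64_3,
               tolerance = 1e-7, ignore_attr = TRUE)
  expect_lt(max(abs(crossprod(tp) - diag(3))), 1e-12)
  # in-band energy concentration close to 1 for the leading taper
  tp2 <- dpss_tapers(256, 3, 5)
  spec <- Mod(stats::fft(c(tp2[, 1], rep(0, 768))))^2
  w <- 3 / 256
  inband <- sum(spec[abs(((0:1023) / 1024 + 0.5) %% 1 - 0.5) <= w])
  expect_gt(inband / sum(spec), 0.999)
})

test_that("multitaper PSD is flat for white noise and scales with power", {
  set.seed(11)
  fs <- 10000
  x <- matrix(rnorm(1400 * 50, 0, 3), 1400)
  ps <- mt_psd(x, fs, band_hz = c(300, 3000))
  # oracle: white noise of variance v has one-sided PSD 2 v / fs
  expect_equal(mean(ps$psd), 2 * 9 / fs, tolerance = 0.05)
  band_sd <- stats::sd(rowMeans(ps$psd)) / mean(ps$psd)
  expect_lt(band_sd, 0.15)                      # flat across the band
  # doubling the amplitude quadruples the power
  ps2 <- mt_psd(2 * x, fs, band_hz = c(300, 3000))
  expect_equal(ps2$psd, 4 * ps$psd, tolerance = 1e-12)
})

test_that("a pure tone yields a single spectral peak at its frequency", {
  fs <- 10000
  t <- seq_len(1400) / fs
  ps <- mt_psd(sin(2 * pi * 1000 * t), fs, band_hz = c(300, 3000))
  expect_equal(ps$freq_hz[which.max(ps$psd)], 1000, tolerance = 0.03)
  outside <- ps$freq_hz < 900 | ps$freq_hz > 1100
  expect_lt(max(ps$psd[outside]) / max(ps$psd), 1e-3)
})

test_that("instantaneous power reproduces mean-of-squares identities", {
  p <- probe_geometry(1:2, c(0, 30), c(0, 0))
  mk <- function(v) {
    dat <- array(0, c(1, 2, length(v)))
    dat[1, 1, ] <- v; dat[1, 2, ] <- v
    epoched_traces(dat, 10000)
  }
  n <- 1900
  pt_c <- instantaneous_power(mk(rep(3, n)), p)
  expect_equal(unique(round(pt_c$value, 10)), 9)     # constant c -> c^2
  pt_0 <- instantaneous_power(mk(rep(0, n)), p)
  expect_true(all(pt_0$value == 0))
  # variance step at t0: half-rise within +-half the 10 ms window
  set.seed(12)
  t_ms <- -40 + (seq_len(n) - 1) / 10
  v <- rnorm(n, 0, ifelse(t_ms < 30, 1, 4))
  pt_s <- instantaneous_power(mk(v), p)
  m <- pt_s$value[pt_s$depth_um == 0]
  tt <- sort(unique(pt_s$time_ms))
  half <- (1 + 16) / 2
  t_half <- tt[which(m >= half)[1]]
  expect_lt(abs(t_half - 30), 6)
})

test_that("dP/P normalises to baseline and flags dead depths", {
  d <- c(0, 20)
  t <- seq(-40, 149)
  base <- matrix(2, 2, 190)
  expect_true(all(abs(delta_p_over_p(
    depth_time_profile(d, t, base, "pt"))$value) < 1e-12))
  twox <- base; twox[, t >= 10] <- 4
  dpp <- delta_p_over_p(depth_time_profile(d, t, twox, "pt"))
  m <- matrix(dpp$value, 2, 190)
  expect_equal(unique(as.vector(m[, t >= 10])), 1)   # P = 2 Pb -> dP/P = 1
  dead <- base; dead[2, ] <- 0
  expect_warning(
    dpp2 <- delta_p_over_p(depth_time_profile(d, t, dead, "pt")),
    "zero baseline")
  expect_true(all(is.na(dpp2$value[dpp2$depth_um == 20])))
})

test_that("onset latency finds half-rise times", {
  t <- seq(-40, 149)
  stepv <- as.numeric(t >= 30)
  expect_equal(onset_latency(stepv, t), 30)
  expect_true(is.na(onset_latency(rep(0, 190), t)))
  # monotone ramp from 20 ms: half-max crossing at the midpoint
  ramp <- pmax(0, (t - 20) / 130)
  expect_equal(onset_latency(ramp, t), 85, tolerance = 0.02)
  # sub-threshold rows are suppressed
  expect_true(is.na(onset_latency(0.2 * stepv, t, min_peak = 0.5)))
})

test_that("coherence is exact for scaled copies and unaffected by delay", {
  set.seed(13)
  fs <- 10000
  x <- rnorm(1400)
  for (a in c(0.5, 1, 8)) {
    co <- coherence_pair(x, a * x, fs)
    expect_equal(unique(round(co$coherence, 12)), 1)
  }
  # circular one-sample delay: pure phase shift, magnitude unchanged
  xd <- c(x[1400], x[1:1399])
  co_d <- coherence_pair(x, xd, fs)
  expect_gt(min(co_d$coherence), 0.97)
  # independent streams decorrelate as tapers x segments grow
  xm <- matrix(rnorm(1400 * 12), 1400)
  ym <- matrix(rnorm(1400 * 12), 1400)
  co_i <- coherence_pair(xm, ym, fs)
  expect_lt(mean(co_i$coherence), 0.08)          # ~1/(K x trials) bias floor
  expect_error(coherence_pair(x, x, fs, k = 1), "2 tapers")
  expect_error(coherence_pair(x, 0 * x, fs), "zero-power")
})

test_that("local coherence is 1 for identical channels, low for noise", {
  p <- probe_geometry(1:4, c(11, 43, 11, 43), c(0, 0, 20, 20))
  n <- 1400
  mk <- function(m) {
    dat <- array(0, c(2, 4, 1900))
    for (ch in 1:4) dat[1, ch, 401:1800] <- m[, ch]
    for (ch in 1:4) dat[2, ch, 401:1800] <- m[, ncol(m):1][, ch]
    epoched_traces(dat, 10000)
  }
  set.seed(14)
  shared <- rnorm(n)
  cf1 <- local_coherence(mk(cbind(shared, shared, shared, shared)), p,
                         smooth_sigma_um = 0)
  expect_equal(unique(round(cf1$value, 10)), 1)
  noise <- matrix(rnorm(4 * n), n)
  cf0 <- local_coherence(mk(noise), p, smooth_sigma_um = 0)
  expect_lt(mean(cf0$value), 0.25)               # near the 1/K bias floor
  expect_true(all(cf0$value >= 0 & cf0$value <= 1))
})

test_that("spontaneous Pf keeps its laminar shape across time windows", {
  # with no evoked drive, the power profile reflects density alone, so the
  # baseline-window and response-window profiles share one shape
  spec <- default_layer_spec(conditions = "black")
  spec$evoked_rate_hz <- lapply(spec$evoked_rate_hz, function(v) v * 0)
  spec$baseline_rate_hz <- c(0.5, rep(8, 9), 8)   # spontaneous activity only
  sim <- simulate_recording(spec, linear_probe(192), n_trials = 4,
                            fs_ap_hz = 10000, pia_depth_um = 1900, seed = 19)
  ap <- condition_ap_chain(sim$ap, fs_out_hz = 10000)
  ep <- epoch_traces(ap, sim$events)
  pf_resp <- band_mean(power_spectrum(ep, sim$probe, response_ms = c(10, 150)))
  pf_base <- band_mean(power_spectrum(ep, sim$probe, response_ms = c(-40, 10)))
  span <- range(sim$truth$boundaries$depth_um)
  keep <- pf_resp$depth_um >= span[1] & pf_resp$depth_um <= span[2]
  expect_gt(stats::cor(pf_resp$value[keep], pf_base$value[keep]), 0.9)
  # and the profile correlates positively with the density profile (power
  # also grows with soma spread, so sparse large-cell layers are boosted
  # and the association is positive rather than a strict rank match)
  th <- layer_thicknesses(sim$truth$boundaries)
  layer_pf <- vapply(seq_len(nrow(th)), function(i) {
    mean(pf_resp$value[pf_resp$depth_um >= th$bottom_um[i] &
                         pf_resp$depth_um < th$top_um[i]])
  }, numeric(1))
  dens <- spec$neuron_density[match(th$layer, spec$layer)]
  expect_gt(stats::cor(layer_pf, dens, method = "spearman"), 0)
})

test_that("amplitude scaling leaves Cf unchanged while Pf scales by a^2", {
  probe <- linear_probe(n_channels = 16)
  dat <- array(rnorm(2 * 16 * 1900), c(2, 16, 1900))
  dat[, , 500:1000] <- dat[, , 500:1000] * 3     # structure in the response
  dat[, 6, ] <- dat[, 5, ]       # the two contacts of one row see one signal
  ep <- epoched_traces(dat, 10000)
  a <- 7
  dat2 <- dat; dat2[, 5, ] <- a * dat2[, 5, ]    # scale one of them
  ep2 <- epoched_traces(dat2, 10000)
  pf1 <- power_spectrum(ep, probe, smooth_sigma_um = 0)
  pf2 <- power_spectrum(ep2, probe, smooth_sigma_um = 0)
  d5 <- depth_of_channel(probe, 5)               # the row holding channels 4, 5
  r <- pf2$value[pf2$depth_um == d5] / pf1$value[pf1$depth_um == d5]
  other <- pf2$depth_um != d5
  expect_equal(unique(round(r, 8)), (a^2 + 1) / 2)  # one of two row channels
  expect_equal(pf2$value[other], pf1$value[other])
  cf1 <- local_coherence(ep, probe, smooth_sigma_um = 0)
  cf2 <- local_coherence(ep2, probe, smooth_sigma_um = 0)
  expect_equal(cf2$value, cf1$value, tolerance = 1e-10)
})
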