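test_that("duplicate spikes are removed within and across clusters", {
  base <- toy_units(y_um = c(500, 530, 900), height = c(120, 80, 100))
  base$spike_times <- list(
    c(1.0000, 1.0002, 1.01),     # 0.2 ms apart: later one dropped
    c(1.0001, 2.0, 2.0005),      # first coincides with big unit 30 µm away
    c(1.0001, 5.0)               # 400 µm away: never cross-deduplicated
  )
  out <- remove_duplicates(base)
  expect_equal(out$spike_times[[1]], c(1.0000, 1.01))
  expect_equal(out$spike_times[[2]], c(2.0, 2.0005))   # 0.5 ms pair survives
  expect_equal(out$spike_times[[3]], c(1.0001, 5.0))
  # idempotent
  expect_identical(remove_duplicates(out)$spike_times, out$spike_times)
})

test_that("low-rate clusters are dropped with an inclusive threshold", {
  u <- toy_units(y_um = c(100, 200, 300), rate = c(0.4, 0.5, 0.6))
  expect_message(out <- filter_low_rate(u), "2 low-rate")
  expect_equal(out$mean_rate_hz, 0.6)
})

test_that("unit position is the height-weighted centre of mass", {
  p <- linear_probe(n_channels = 20)
  cd <- channel_depths(p)
  # single live channel: position is that channel
  w1 <- list(channel_id = p$channel_id,
             w = outer(as.numeric(cd$depth_um == 100 & cd$x_um == 11),
                       spike_template(30000)) * 100,
             fs_hz = 30000)
  pos1 <- unit_position(w1, p)
  expect_equal(pos1[["y_um"]], 100)
  expect_equal(pos1[["x_um"]], 11)
  # equal heights on two adjacent rows: midpoint
  amp2 <- as.numeric(cd$depth_um %in% c(100, 120) & cd$x_um == 11)
  w2 <- list(channel_id = p$channel_id,
             w = outer(amp2, spike_template(30000)) * 100, fs_hz = 30000)
  expect_equal(unit_position(w2, p)[["y_um"]], 110)
  # gaussian-amplitude unit at a known depth recovered within 5 µm
  p2 <- linear_probe(n_channels = 100)
  wf <- toy_waveform(p2, depth_um = 487, spread_um = 30)
  expect_lt(abs(unit_position(wf, p2)[["y_um"]] - 487), 5)
})

test_that("spike spread finds the nearest sub-threshold channel per direction", {
  p <- probe_geometry(1:5, 0, c(0, 20, 40, 60, 80))
  mk <- function(amps) list(channel_id = 1:5,
                            w = outer(amps, spike_template(30000)),
                            fs_hz = 30000)
  # peak at row 0 (depth 0): [100, 100, 10] upward -> first sub-15% row at 40
  s <- spike_spread(mk(c(100, 100, 10, 5, 5)), p)
  expect_equal(s$upward_um, 40)
  expect_false(s$upward_capped)
  # single-channel unit: next row is already below threshold
  s1 <- spike_spread(mk(c(100, 1, 1, 1, 1)), p)
  expect_equal(s1$upward_um, 20)
  expect_equal(s1$downward_um, 0)    # probe end below, flagged
  expect_true(s1$downward_capped)
  # no sub-threshold channel before the probe end: capped at the end
  s2 <- spike_spread(mk(c(100, 90, 80, 70, 60)), p)
  expect_equal(s2$upward_um, 80)
  expect_true(s2$upward_capped)
})

test_that("wider somata produce wider measured spreads", {
  p <- linear_probe(n_channels = 100)
  spreads <- c(15, 25, 40, 60)
  measured <- vapply(spreads, function(s) {
    sp <- spike_spread(toy_waveform(p, 500, spread_um = s), p)
    (sp$upward_um + sp$downward_um) / 2
  }, numeric(1))
  expect_true(all(diff(measured) > 0))
})

test_that("spike shape gives signed duration and peak-trough ratio", {
  fs <- 10000
  t <- seq(0, 0.8, by = 1000 / fs)
  v <- -100 * exp(-(t - 0.3)^2 / (2 * 0.05^2)) +
    40 * exp(-(t - 0.5)^2 / (2 * 0.05^2))
  wf <- list(channel_id = 1L, w = matrix(v, 1), fs_hz = fs)
  shp <- spike_shape(wf)
  expect_equal(shp[["duration_ms"]], 0.2)
  expect_equal(shp[["peak_trough_ratio"]], -0.4, tolerance = 1e-2)
  # time reversal flips the duration sign
  wr <- list(channel_id = 1L, w = matrix(rev(v), 1), fs_hz = fs)
  expect_equal(spike_shape(wr)[["duration_ms"]], -0.2)
  # the axonal (inverted) template has ratio < -1 and negative duration
  ax <- list(channel_id = 1L, w = matrix(spike_template(fs, inverted = TRUE), 1),
             fs_hz = fs)
  expect_lt(spike_shape(ax)[["peak_trough_ratio"]], -1)
  expect_lt(spike_shape(ax)[["duration_ms"]], 0)
})

test_that("per-unit features are invariant under amplitude scaling", {
  p <- linear_probe(n_channels = 60)
  wf <- toy_waveform(p, 300, spread_um = 35)
  wf10 <- wf; wf10$w <- wf$w * 10
  expect_equal(unit_position(wf10, p), unit_position(wf, p))
  expect_equal(spike_spread(wf10, p), spike_spread(wf, p))
  expect_equal(spike_shape(wf10), spike_shape(wf))
  expect_equal(max(waveform_heights(wf10)), 10 * max(waveform_heights(wf)))
})

test_that("unit density counts weighted units per cylinder volume", {
  p <- linear_probe(n_channels = 40)
  vol <- pi * 0.1^2 * 0.04                       # 100 µm radius, 40 µm segment
  u1 <- toy_units(y_um = 200, quality = "single")
  d1 <- unit_density_profile(u1, p, sigma_um = 0)
  expect_equal(d1$value[d1$depth_um == 200], 1 / vol)
  um <- toy_units(y_um = 200, quality = "multi")
  dm <- unit_density_profile(um, p, sigma_um = 0)
  expect_equal(dm$value[dm$depth_um == 200], 1.2 / vol)  # multi counts 1.2
  d0 <- unit_density_profile(u1[0, ], p)
  expect_true(all(d0$value == 0))                # no units: true zero
})

test_that("unsmoothed density integrates back to the weighted unit count", {
  p <- linear_probe(n_channels = 100)
  set.seed(8)
  u <- toy_units(y_um = runif(40, 100, 900),
                 quality = sample(c("single", "multi"), 40, replace = TRUE))
  d <- unit_density_profile(u, p, sigma_um = 0, window_um = 40, step_um = 20)
  vol <- pi * 0.1^2 * 0.04
  # 40 µm windows at 20 µm step cover each unit twice
  total <- sum(d$value) * vol / 2
  expect_equal(total, sum(ifelse(u$quality == "multi", 1.2, 1)),
               tolerance = 1e-10)
})

test_that("depth distributions average per window and mark empty windows", {
  p <- linear_probe(n_channels = 40)
  u <- toy_units(y_um = c(200, 210, 350))
  u$duration_ms <- c(0.2, 0.4, -0.3)
  d <- depth_distribution(u, "duration_ms", p, sigma_um = 0)
  expect_equal(d$value[d$depth_um == 200], 0.3)  # mean of 0.2, 0.4
  expect_equal(d$value[d$depth_um == 360], -0.3)
  expect_true(is.na(d$value[d$depth_um == 280])) # no units: missing
})

test_that("extracted waveforms recover the injected template", {
  sim <- small_sim(seed = 5, conditions = "black", n_trials = 6)
  ap <- condition_ap_band(condition_ap(sim$ap))
  sub <- sim$units[order(-vapply(sim$units$mean_waveform,
                                 function(w) max(waveform_heights(w)),
                                 numeric(1)))[1:5], ]
  ext <- extract_waveforms(ap, sub, sim$probe, seed = 2)
  for (i in 1:5) {
    h_true <- waveform_heights(sub$mean_waveform[[i]])
    pk_true <- sub$mean_waveform[[i]]$channel_id[which.max(h_true)]
    h_ext <- waveform_heights(ext$mean_waveform[[i]])
    pk_ext <- ext$mean_waveform[[i]]$channel_id[which.max(h_ext)]
    expect_lt(abs(depth_of_channel(sim$probe, pk_ext) -
                    depth_of_channel(sim$probe, pk_true)), 45)
  }
})
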