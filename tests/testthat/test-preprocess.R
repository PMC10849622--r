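test_that("common-mode signals and DC offsets are removed from the AP band", {
  fs <- 30000
  t <- seq_len(3000) / fs
  common <- 50 * sin(2 * pi * 1000 * t)
  x <- matrix(common, length(t), 8) + 3        # same tone + DC everywhere
  out <- condition_ap(probe_traces(x, fs))
  expect_lt(max(abs(out$data)), 1e-6)
  # DC alone dies in the high-pass even without CAR (away from the edge
  # transients of the zero-phase filter)
  dc <- condition_ap(probe_traces(matrix(5, 3000, 4), fs), car = "none")
  expect_lt(max(abs(dc$data[500:2500, ])), 1e-3)
  expect_error(condition_ap(probe_traces(matrix(0, 10, 4), 400)), "too low")
})

test_that("white-noise gain through the high-pass matches its transfer function", {
  # oracle: zero-phase filtering applies |H|^2, so output variance is
  # var_in * mean(|H(f)|^4) over the frequency grid
  fs <- 30000
  bf <- signal::butter(3, 300 / (fs / 2), type = "high")
  H <- signal::freqz(bf$b, bf$a, n = 4096, Fs = fs)
  gain <- mean(Mod(H$h)^4)
  set.seed(5)
  x <- matrix(rnorm(2e5, 0, 10), ncol = 2)
  out <- condition_ap(probe_traces(x, fs), car = "none")
  expect_equal(stats::var(as.vector(out$data)) / 100, gain, tolerance = 0.03)
})

test_that("AP band-pass keeps 1 kHz, rejects 5 kHz, and resamples to 10 kHz", {
  fs <- 30000
  t <- seq_len(fs) / fs                         # 1 s
  rms <- function(v) sqrt(mean(v^2))
  tone <- function(f) probe_traces(matrix(sin(2 * pi * f * t), ncol = 1), fs)
  out1 <- condition_ap_band(tone(1000))
  expect_equal(out1$fs_hz, 10000)
  expect_equal(nrow(out1$data), 10000)          # seconds x 10 kHz
  db1 <- 20 * log10(rms(out1$data) / rms(sin(2 * pi * 1000 * t)))
  expect_gt(db1, -1)
  out5 <- condition_ap_band(tone(5000))
  db5 <- 20 * log10(rms(out5$data) / rms(sin(2 * pi * 5000 * t)))
  expect_lt(db5, -20)
})

test_that("LFP conditioning notches 60 Hz, keeps 10 Hz, kills DC", {
  fs <- 2500
  t <- seq_len(16 * fs) / fs        # long record: the 1 Hz corner settles slowly
  rms <- function(v) sqrt(mean(v^2))
  mid <- function(v) v[seq(length(v) * 0.35, length(v) * 0.65)]
  out60 <- condition_lfp(probe_traces(matrix(sin(2 * pi * 60 * t), ncol = 1), fs))
  expect_equal(out60$fs_hz, 1000)
  expect_lt(20 * log10(rms(mid(out60$data)) / sqrt(0.5)), -20)
  out10 <- condition_lfp(probe_traces(matrix(sin(2 * pi * 10 * t), ncol = 1), fs))
  expect_gt(20 * log10(rms(mid(out10$data)) / sqrt(0.5)), -1)
  outc <- condition_lfp(probe_traces(matrix(7, length(t), 1), fs))
  expect_lt(max(abs(mid(outc$data))), 0.01)
})

test_that("filters are linear operators", {
  fs <- 30000
  set.seed(9)
  x <- matrix(rnorm(3e4), ncol = 2)
  f <- function(m) condition_ap(probe_traces(m, fs), car = "none")$data
  expect_equal(f(3.7 * x), 3.7 * f(x), tolerance = 1e-10)
})

test_that("the fused AP chain equals high-pass + CAR then band-pass", {
  fs <- 30000
  set.seed(17)
  tr <- probe_traces(matrix(rnorm(3e4 * 4, 0, 20), ncol = 4), fs)
  two_step <- condition_ap_band(condition_ap(tr))
  fused <- condition_ap_chain(tr)
  expect_equal(fused$data, two_step$data, tolerance = 1e-12)
  expect_equal(fused$fs_hz, 10000)
})

test_that("epoching extracts the documented sample windows", {
  fs <- 1000
  x <- matrix(seq_len(3000), ncol = 1)          # value = 1-based sample index
  events <- tibble::tibble(onset_s = 1, condition = "a", eye = "dominant")
  ep <- epoch_traces(probe_traces(x, fs), events)
  # onset sample (0-based) 1000; window [-40, 150) ms -> samples [960, 1150)
  expect_equal(dim(ep$data), c(1, 1, 190))
  expect_equal(as.vector(ep$data[1, 1, ]), as.numeric(961:1150))
  expect_equal(ep$condition, "a")

  # zero events: empty epoch set, no error
  ep0 <- epoch_traces(probe_traces(x, fs), tibble::tibble(onset_s = numeric()))
  expect_equal(dim(ep0$data)[1], 0)

  # events overlapping each other are both kept
  ep2 <- epoch_traces(probe_traces(x, fs),
                      tibble::tibble(onset_s = c(1, 1.05)))
  expect_equal(dim(ep2$data)[1], 2)

  # events overlapping a recording edge are dropped with a message
  expect_message(
    ep3 <- epoch_traces(probe_traces(x, fs), tibble::tibble(onset_s = c(0.01, 1))),
    "dropped")
  expect_equal(dim(ep3$data)[1], 1)
})

test_that("epoching conserves within-window samples", {
  fs <- 1000
  set.seed(2)
  x <- matrix(rnorm(5000), ncol = 1)
  onsets <- c(0.5, 1.5, 2.5)
  ep <- epoch_traces(probe_traces(x, fs), tibble::tibble(onset_s = onsets))
  for (i in seq_along(onsets)) {
    i0 <- onsets[i] * fs - 40 + 1
    expect_equal(as.vector(ep$data[i, 1, ]), x[i0:(i0 + 189), 1])
  }
})

test_that("depth averaging pools same-row channels and skips the reference", {
  p <- linear_probe(n_channels = 6, reference_channels = 3)
  # rows: (0,1)@0, (2,3)@20 with 3 = reference, (4,5)@40
  dat <- array(0, c(1, 6, 190))
  dat[1, 1, ] <- 2; dat[1, 2, ] <- 4            # row 0: mean 3
  dat[1, 3, ] <- 6; dat[1, 4, ] <- 999          # row 1: ref ignored -> 6
  dat[1, 5, ] <- 1; dat[1, 6, ] <- 5            # row 2: mean 3
  ep <- depth_average(epoched_traces(dat, 1000), p)
  expect_equal(attr(ep, "depth_um"), c(0, 20, 40))
  expect_equal(unique(as.vector(ep$data[1, 1, ])), 3)
  expect_equal(unique(as.vector(ep$data[1, 2, ])), 6)
  expect_equal(unique(as.vector(ep$data[1, 3, ])), 3)

  # single-column probe: identity
  p1 <- probe_geometry(1:4, 0, c(0, 20, 40, 60))
  d1 <- array(rnorm(4 * 190), c(1, 4, 190))
  ep1 <- depth_average(epoched_traces(d1, 1000), p1)
  expect_equal(ep1$data, d1)
})
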