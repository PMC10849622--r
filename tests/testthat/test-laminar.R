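mk_profile <- function(d, v, metric = "pf_band_mean", condition = NA) {
  depth_profile(d, v, metric, condition = condition)
}

test_that("white-matter border detection follows the somatic criteria", {
  d <- seq(0, 1980, by = 20)
  somatic <- d >= 400
  dur <- mk_profile(d, ifelse(somatic, 0.25, -0.25), "duration_ms")
  rat <- mk_profile(d, ifelse(somatic, -0.4, -2.5), "peak_trough_ratio")
  spr <- mk_profile(d, ifelse(somatic, 90, 35), "spread_um")
  ev <- detect_wm_border(dur, rat, spr)
  expect_equal(ev$boundary, "L6/WM")
  expect_equal(ev$depth_um, 390)                 # between last axonal and first somatic row

  # all-somatic recording: no candidate
  dur2 <- mk_profile(d, rep(0.25, length(d)), "duration_ms")
  rat2 <- mk_profile(d, rep(-0.4, length(d)), "peak_trough_ratio")
  expect_equal(nrow(detect_wm_border(dur2, rat2)), 0)

  # two transitions: the deepest persistent one wins
  flick <- somatic; flick[d >= 1200 & d < 1240] <- FALSE
  dur3 <- mk_profile(d, ifelse(flick, 0.25, -0.25), "duration_ms")
  rat3 <- mk_profile(d, ifelse(flick, -0.4, -2.5), "peak_trough_ratio")
  ev3 <- detect_wm_border(dur3, rat3)
  expect_equal(ev3$depth_um, 390)
})

test_that("edge detection finds steps and ignores flat profiles", {
  d <- seq(0, 1980, by = 20)
  stepv <- ifelse(d < 900, 1, 3)
  ev <- detect_edges(mk_profile(d, stepv), smooth_sigma_um = 0)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$depth_um, 890)   # the step falls between samples 880 and 900
  expect_equal(ev$sign, 1)
  expect_equal(nrow(detect_edges(mk_profile(d, rep(2, length(d))))), 0)
})

test_that("the L4A band is found only when interior, narrow and elevated", {
  d <- seq(900, 1500, by = 20)
  band <- d >= 1200 & d < 1280                   # 80 µm band
  p_band <- mk_profile(d, ifelse(band, 5, 1), condition = "s_off")
  p_flat <- mk_profile(d, rep(1, length(d)), condition = "black")
  ev <- detect_l4a_band(list(p_flat, p_band), zone_um = c(1000, 1400))
  expect_equal(sort(ev$boundary), c("L3B/L4A", "L4A/L4B"))
  top <- ev$depth_um[ev$boundary == "L3B/L4A"]
  bot <- ev$depth_um[ev$boundary == "L4A/L4B"]
  expect_lt(abs(top - 1280), 20)
  expect_lt(abs(bot - 1200), 20)
  expect_equal(unique(ev$condition), "s_off")    # max over conditions
  # no band injected: nothing found
  expect_equal(nrow(detect_l4a_band(list(p_flat), c(1000, 1400))), 0)
  # a 300 µm-wide plateau is not a band
  wide <- mk_profile(d, ifelse(d >= 1100 & d < 1400, 5, 1))
  expect_equal(nrow(detect_l4a_band(list(wide), c(1000, 1400))), 0)
})

test_that("the latency step places the L4Ca/L4Cb border", {
  d <- seq(900, 1300, by = 20)
  lat <- mk_profile(d, ifelse(d < 1100, 60, 40), "onset_latency_ms")
  ev <- detect_alpha_beta(lat, l4c_um = c(900, 1300))
  expect_equal(ev$boundary, "L4Ca/L4Cb")
  expect_equal(ev$depth_um, 1090, tolerance = 0.02)
  # uniform latency: no border
  flat <- mk_profile(d, rep(50, length(d)), "onset_latency_ms")
  expect_equal(nrow(detect_alpha_beta(flat, c(900, 1300))), 0)
  # a step that would make L4Cb thicker than L4Ca is clamped to the midpoint
  hi <- mk_profile(d, ifelse(d < 1240, 60, 40), "onset_latency_ms")
  ev2 <- detect_alpha_beta(hi, c(900, 1300))
  expect_equal(ev2$depth_um, 1100)
})

test_that("fallback rules fill boundaries with the anatomical constants", {
  anchors <- c("L1/L2" = 1850, "L4B/L4C" = 1100, "L4Cb/L5" = 700,
               "L5/L6A" = 500, "L6/WM" = 150)
  b <- apply_fallbacks(anchors)
  d <- stats::setNames(b$depth_um, b$boundary)
  expect_equal(d[["L4A/L4B"]], 1300)             # L4B = half of the 400 µm L4C
  expect_equal(d[["L3B/L4A"]], 1350)             # L4A 50 µm thick
  expect_equal(d[["L4Ca/L4Cb"]], 900)            # halfway down L4C
  expect_equal(d[["pia/L1"]], 1850 + 135)        # default pia offset
  # two-thirds of the distance from L1/L2 down to the top of L4A
  expect_equal(d[["L2-3A/L3B"]], 1850 - 2 / 3 * (1850 - 1350))
  expect_equal(d[["L6A/L6B"]], 325)              # halfway L5/L6A -> L6/WM
  expect_equal(unname(b$provenance[b$boundary == "L1/L2"]), "detected")
  expect_true(all(b$provenance[!b$boundary %in% names(anchors)] == "fallback"))
  validate_boundaries(b)                          # ordering + sublayer rule
  th <- layer_thicknesses(b)
  expect_lte(th$thickness_um[th$layer == "L4Cb"],
             th$thickness_um[th$layer == "L4Ca"])

  expect_error(apply_fallbacks(anchors[-2]), "L4B/L4C")
  # a detected alpha/beta border violating the sublayer rule is clamped
  b2 <- apply_fallbacks(c(anchors, "L4Ca/L4Cb" = 1050))
  expect_equal(b2$depth_um[b2$boundary == "L4Ca/L4Cb"], 900)
})

test_that("fallback output always satisfies the ordering invariants", {
  set.seed(15)
  for (i in 1:25) {
    wm <- runif(1, 0, 400)
    l1 <- wm + runif(1, 1300, 1900)
    l4c_bot <- wm + runif(1, 0.25, 0.4) * (l1 - wm)
    l4c_top <- l4c_bot + runif(1, 250, 450)
    l56 <- wm + runif(1, 0.45, 0.75) * (l4c_bot - wm)
    b <- apply_fallbacks(c("L1/L2" = l1, "L4B/L4C" = l4c_top,
                           "L4Cb/L5" = l4c_bot, "L5/L6A" = l56,
                           "L6/WM" = wm))
    expect_silent(validate_boundaries(b))
  }
})

test_that("units land in the right layers under the interval convention", {
  b <- spec_boundaries(default_layer_spec())
  u <- toy_units(y_um = c(2065, 940, 100, 2250, 1200))
  out <- assign_units_to_layers(u, b)
  # exactly on L1/L2 boundary -> layer above (L1); on L4Cb/L5 -> L4Cb
  expect_equal(out$layer, c("L1", "L4Cb", "WM", "above_pia", "L4Ca"))

  sim <- small_sim()
  units <- unit_features(sim$units, sim$probe)
  lab <- assign_units_to_layers(units, sim$truth$boundaries)
  nb <- sim$truth$neurons
  true_layer <- nb$layer[match(lab$neuron_id, nb$neuron_id)]
  agree <- mean(lab$layer == true_layer)
  expect_gt(agree, 0.95)                         # positions are estimates
})

test_that("templates average thicknesses and alignment is exact on knots", {
  b1 <- spec_boundaries(default_layer_spec(total_thickness_um = 1600),
                        pia_depth_um = 1900)
  b2 <- spec_boundaries(default_layer_spec(total_thickness_um = 1900),
                        pia_depth_um = 2300)
  tpl <- build_template(list(b1, b2))
  th1 <- layer_thicknesses(b1)$thickness_um
  th2 <- layer_thicknesses(b2)$thickness_um
  expect_equal(tpl$thicknesses$mean_um, (th1 + th2) / 2, ignore_attr = TRUE)
  expect_equal(glance(tpl$boundaries)$cortex_thickness_um, 1750)
  # identical penetrations: template equals each
  tpl1 <- build_template(list(b1, b1))
  expect_equal(layer_thicknesses(tpl1$boundaries)$thickness_um, th1)

  # boundaries map exactly onto template boundaries; inverse map recovers
  fmap <- depth_map(b1, tpl$boundaries)
  finv <- depth_map(tpl$boundaries, b1)
  expect_equal(fmap(b1$depth_um), tpl$boundaries$depth_um)
  expect_equal(finv(fmap(b1$depth_um)), b1$depth_um)
})

test_that("profile alignment warps layers onto the template grid", {
  b <- spec_boundaries(default_layer_spec())
  d <- seq(0, 2400, by = 20)
  prof <- depth_profile(d, sin(d / 300), "pf_band_mean")
  # template identical to the penetration: identity resampling
  self <- align_to_template(prof, b, b, normalize = "none")
  keep <- self$depth_um >= 0 & self$depth_um <= 2400
  expect_equal(self$value[keep],
               sin(self$depth_um[keep] / 300), tolerance = 1e-3)

  # two penetrations sharing an L4C band average to band edges at the
  # template L4C borders
  b2 <- spec_boundaries(default_layer_spec(total_thickness_um = 1900),
                        pia_depth_um = 2300)
  tpl <- build_template(list(b, b2))$boundaries
  mkband <- function(bb) {
    th <- layer_thicknesses(bb)
    inb <- d >= th$bottom_um[th$layer == "L4Cb"] &
      d < th$top_um[th$layer == "L4Ca"]
    depth_profile(d, ifelse(inb, 2, 0), "pf_band_mean")
  }
  avg <- average_profiles(list(
    align_to_template(mkband(b), b, tpl),
    align_to_template(mkband(b2), b2, tpl)))
  tt <- layer_thicknesses(tpl)
  top <- tt$top_um[tt$layer == "L4Ca"]; bot <- tt$bottom_um[tt$layer == "L4Cb"]
  inside <- avg$depth_um > bot + 40 & avg$depth_um < top - 40
  outside <- (avg$depth_um < bot - 60 | avg$depth_um > top + 60) &
    avg$depth_um >= 0 & avg$depth_um <= max(tpl$depth_um)
  expect_gt(min(avg$value[inside]), 0.8)
  expect_lt(max(abs(avg$value[outside]), na.rm = TRUE), 0.2)

  # profile not covering its boundaries is rejected
  short <- depth_profile(seq(500, 1000, 20), rnorm(26), "x")
  expect_error(align_to_template(short, b, tpl), "span")
})
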