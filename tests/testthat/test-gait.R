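noise_free <- gaitSimConfig(curve_noise_sd = 0, cycle_noise_sd = 0)

test_that("noise-free trials reproduce every configured parameter", {
  tr <- simulateGaitTrial(noise_free, "baseline", seed = 1)
  for (side in c("left", "right")) {
    sp <- spatiotemporalParams(tr, side)
    expect_equal(sp$stride_time, 1.1, tolerance = 1e-6)
    expect_equal(sp$stride_length, 1.30, tolerance = 1e-6)
    expect_equal(sp$cadence, 120 / 1.1, tolerance = 1e-6)
    expect_equal(sp$gait_speed, 1.30 / 1.1, tolerance = 1e-6)
    expect_equal(sp$stance_pct, 62, tolerance = 1e-6)
    expect_equal(sp$swing_pct, 38, tolerance = 1e-6)
    expect_equal(sp$double_support_pct, 24, tolerance = 1e-6)
    expect_equal(sp$step_width, 0.10, tolerance = 1e-6)
    expect_equal(sp$gait_speed, sp$stride_length / sp$stride_time,
                 tolerance = 1e-9)
  }
})

test_that("a different stance fraction propagates to stance/swing/DS", {
  cfg <- gaitSimConfig(stance_fraction = 0.60, curve_noise_sd = 0,
                       cycle_noise_sd = 0)
  sp <- spatiotemporalParams(simulateGaitTrial(cfg, "baseline", 1), "left")
  expect_equal(sp$stance_pct, 60, tolerance = 1e-6)
  expect_equal(sp$swing_pct, 40, tolerance = 1e-6)
  # each double-support interval is stance - 50 = 10% -> total 20%
  expect_equal(sp$double_support_pct, 20, tolerance = 1e-6)
})

test_that("condition effects shift stride length and foot progression", {
  base <- spatiotemporalParams(simulateGaitTrial(noise_free, "baseline", 1),
                               "left")
  gng <- spatiotemporalParams(simulateGaitTrial(noise_free, "go_nogo_1", 1),
                              "left")
  expect_equal(base$stride_length - gng$stride_length, 0.10,
               tolerance = 1e-6)
  prof <- trialGaitProfile(simulateGaitTrial(noise_free, "go_nogo_1", 1),
                           referenceCurves(), "left")
  expect_equal(prof$gvs_foot_progression, 5, tolerance = 1e-9)
  null_prof <- trialGaitProfile(simulateGaitTrial(noise_free, "baseline", 1),
                                referenceCurves(), "left")
  expect_equal(unname(unlist(null_prof)), rep(0, 10))
})

test_that("gait trials are deterministic per seed and symmetric up to \
noise", {
  a <- simulateGaitTrial(gaitSimConfig(), "n_back_2", seed = 3)
  b <- simulateGaitTrial(gaitSimConfig(), "n_back_2", seed = 3)
  expect_identical(a@markers, b@markers)
  expect_identical(a@curves, b@curves)
  l <- spatiotemporalParams(a, "left"); r <- spatiotemporalParams(a, "right")
  expect_equal(l$stride_length, r$stride_length, tolerance = 0.05)
})

test_that("time normalization is exact for linear, constant and resampled \
curves", {
  t <- seq(0, 3, by = 0.005)
  ramp <- timeNormalize(t, 2 * t + 1, cycle = c(0.5, 2.5))
  expect_equal(ramp, seq(2 * 0.5 + 1, 2 * 2.5 + 1, length.out = 101))
  expect_equal(timeNormalize(t, rep(7, length(t)), c(0, 3)), rep(7, 101))
  # idempotence: resampling a 101-point curve over its own cycle
  curve <- referenceCurves()[, "knee_flexion"]
  again <- timeNormalize(seq(0, 1, length.out = 101), curve, c(0, 1))
  expect_equal(again, unname(curve), tolerance = 1e-9)
  expect_error(timeNormalize(t, t, c(1, 1)), "degenerate")
  expect_error(timeNormalize(t, t, c(2, 5)), "span")
})

test_that("GVS is an RMS with the expected closed forms", {
  ref <- referenceCurves()[, "foot_progression"]
  expect_equal(gvs(ref, ref), 0)
  expect_equal(gvs(ref + 5, ref), 5)
  expect_equal(gvs(ref - 5, ref), 5)
  alt <- ref + rep(c(3, -3), length.out = 101)
  expect_equal(gvs(alt, ref), 3)
  expect_error(gvs(ref[1:50], ref), "101")
  # translation detection for arbitrary constants
  for (c0 in c(-2.5, 0.1, 7)) expect_equal(gvs(ref + c0, ref), abs(c0))
})

test_that("GPS aggregates nine GVS values as an RMS (or a sum)", {
  expect_equal(gps(rep(4, 9)), 4)
  expect_equal(gps(c(3, rep(0, 8))), 1)
  expect_equal(gps(rep(0, 9)), 0)
  expect_equal(gps(rep(2, 9), method = "sum"), 18)
  expect_error(gps(rep(1, 5)), "9")
  expect_error(gps(c(-1, rep(1, 8))), "non-negative")
  # bounds against brute force on random GVS vectors
  set.seed(20)
  for (i in 1:20) {
    g <- runif(9, 0, 10)
    val <- gps(g)
    expect_equal(val, sqrt(mean(g^2)), tolerance = 1e-12)
    expect_lte(val, max(g) + 1e-12)
    expect_gte(val, mean(g) / sqrt(9) - 1e-12)
  }
})

test_that("side comparison detects an injected stride asymmetry", {
  sym <- lapply(1:6, function(s) {
    spatiotemporalParams(simulateGaitTrial(noise_free, "baseline", s),
                         "left") -
      spatiotemporalParams(simulateGaitTrial(noise_free, "baseline", s),
                           "right")
  })
  expect_true(all(abs(unlist(sym)) < 1e-6))

  asym_cfg <- gaitSimConfig(stride_asymmetry = 0.1, curve_noise_sd = 0,
                            cycle_noise_sd = 0)
  lefts <- do.call(rbind, lapply(1:6, function(s) {
    spatiotemporalParams(simulateGaitTrial(asym_cfg, "baseline", s), "left")
  }))
  rights <- do.call(rbind, lapply(1:6, function(s) {
    spatiotemporalParams(simulateGaitTrial(asym_cfg, "baseline", s), "right")
  }))
  expect_equal(mean(lefts$stride_length - rights$stride_length), 0.1,
               tolerance = 1e-6)
  cmp <- compareSides(lefts, rights)
  expect_equal(mean(cmp$differences$stride_length), 0.1, tolerance = 1e-6)
  expect_error(compareSides(lefts[1, ], rights[1, ]), "one trial")
  expect_error(compareSides(lefts, rights[1:3, ]), "unequal")
})

test_that("the coordinate-based event detector finds the planted events", {
  tr <- simulateGaitTrial(noise_free, "baseline", 1)
  det <- detectGaitEvents(tr, "left")
  truth <- tr@events$left$heel_strike
  matched <- vapply(truth[2:(length(truth) - 1)], function(h) {
    min(abs(det$heel_strike - h))
  }, 0)
  expect_lt(max(matched), 0.05)
})
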