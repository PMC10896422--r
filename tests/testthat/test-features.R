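sine_mat <- function(freq, fs, dur, amp = 1, label = "Fz") {
  t <- seq(1 / fs, dur, by = 1 / fs)
  matrix(amp * sin(2 * pi * freq * t), 1, dimnames = list(label, NULL))
}

test_that("a unit 10 Hz sine concentrates 0.5 uV^2 in the alpha band", {
  sp <- psdWelch(sine_mat(10, 512, 10), 512)
  expect_equal(unname(bandPower(sp, "alpha")), 0.5, tolerance = 0.05)
  expect_gte(unname(relativePower(sp, "alpha")), 99)
  for (b in c("delta", "theta", "beta", "gamma")) {
    expect_lt(unname(bandPower(sp, b)), 0.05 * bandPower(sp, "alpha"))
  }
})

test_that("white-noise spectra are flat and partition as bandwidth ratios", {
  ratio <- vapply(1:20, function(s) {
    set.seed(s)
    sp <- psdWelch(matrix(rnorm(256 * 20), 1, dimnames = list("Fz", NULL)),
                   256)
    mean(sp$density[.band <- sp$freq >= 5 & sp$freq < 10]) /
      mean(sp$density[sp$freq >= 30 & sp$freq < 35])
  }, 0)
  expect_gt(mean(ratio), 0.8)
  expect_lt(mean(ratio), 1.25)

  # relative delta ~ 3/44 of the broadband
  rel <- vapply(1:20, function(s) {
    set.seed(100 + s)
    sp <- psdWelch(matrix(rnorm(256 * 20), 1, dimnames = list("Fz", NULL)),
                   256)
    unname(relativePower(sp, "delta"))
  }, 0)
  expect_equal(mean(rel), 100 * 3 / 44, tolerance = 0.15)
})

test_that("zero signal gives an identically zero spectrum and errors on \
relative power", {
  sp <- psdWelch(matrix(0, 1, 1024, dimnames = list("Fz", NULL)), 256)
  expect_true(all(sp$density == 0))
  expect_equal(unname(bandPower(sp, "alpha")), 0)
  expect_error(relativePower(sp, "alpha"), "zero total power")
})

test_that("band sums respect the band algebra exactly", {
  rec <- toy_recording(8, 256 * 10, 256, seed = 4)
  sp <- psdWelch(eegSamples(rec), 256)
  expect_equal(bandPower(sp, "low_beta") + bandPower(sp, "high_beta"),
               bandPower(sp, "beta"))
  rel_sum <- Reduce(`+`, lapply(c("delta", "theta", "alpha", "beta",
                                  "gamma"),
                                function(b) relativePower(sp, b)))
  expect_equal(unname(rel_sum), rep(100, 8), tolerance = 1e-6)
  expect_error(bandPower(sp, c(120, 140)), "outside")
})

test_that("single-segment boxcar Welch equals the DFT periodogram", {
  set.seed(11)
  x <- rnorm(1000)
  sp <- psdWelch(x, fs = 250, segment_s = 4, window = "boxcar")
  po <- oracle_periodogram(x, 250)
  expect_equal(sp$freq, po$freq)
  expect_equal(as.numeric(sp$density), po$density, tolerance = 1e-8)
  # Parseval: integral of the density recovers the variance
  df <- sp$freq[2] - sp$freq[1]
  expect_equal(sum(sp$density) * df, mean(x^2), tolerance = 0.01)
})

test_that("scaling a recording scales absolute but not relative power", {
  rec <- toy_recording(8, 256 * 8, 256, seed = 6)
  sp1 <- psdWelch(eegSamples(rec), 256)
  sp3 <- psdWelch(3 * eegSamples(rec), 256)
  for (b in eegBands()$band) {
    expect_equal(bandPower(sp3, b), 9 * bandPower(sp1, b),
                 tolerance = 1e-9)
    expect_equal(relativePower(sp3, b), relativePower(sp1, b),
                 tolerance = 1e-9)
  }
})

test_that("the condition feature vector has the complete 112-column layout", {
  rec <- toy_recording(8, 512 * 20, 512, seed = 2)
  ep <- epochRecording(rec, seq(0, 18, by = 2), 2)
  feats <- extractConditionFeatures(ep)
  expect_length(feats, 112)
  grid <- expand.grid(channel = eegChannels(), band = eegBands()$band,
                      type = c("absolute", "relative"))
  expected <- paste(grid$channel, grid$band, grid$type, sep = "_")
  expect_setequal(names(feats), expected)
  expect_equal(anyDuplicated(names(feats)), 0)
})

test_that("the epoch mean reduces correctly for degenerate epoch sets", {
  rec <- toy_recording(8, 512 * 4, 512, seed = 8)
  one <- epochRecording(rec, 0, 2)
  expect_equal(nEpochs(one), 1)
  f_one <- extractConditionFeatures(one)
  # identical epochs: the mean equals the single-epoch features
  X <- eegSamples(rec)[, 1:1024]
  rep3 <- EEGRecording(cbind(X, X, X), 512)
  f_rep <- extractConditionFeatures(epochRecording(rep3, c(0, 2, 4), 2))
  expect_equal(f_rep, f_one, tolerance = 1e-12)
})

test_that("feature tables round-trip through the tidy CSV format", {
  rec <- toy_recording(8, 512 * 10, 512, seed = 3)
  rows <- list(
    A = extractConditionFeatures(epochRecording(rec, c(0, 2), 2)),
    B = extractConditionFeatures(epochRecording(rec, c(4, 6), 2))
  )
  info <- data.frame(subject = c("S01", "S01"), setting = "sitting",
                     condition = c("baseline", "go_nogo_1"),
                     level = c(1, 2))
  ft <- buildFeatureTable(rows, info)
  expect_s4_class(ft, "FeatureTable")
  expect_equal(dim(ft), c(112, 2))
  rd <- as.data.frame(SummarizedExperiment::rowData(ft))
  expect_equal(nrow(unique(rd)), 112)
  f <- tempfile(fileext = ".csv")
  writeFeatureCSV(ft, f)
  ft2 <- readFeatureCSV(f)
  expect_equal(SummarizedExperiment::assay(ft2, "power")[rownames(ft), ],
               SummarizedExperiment::assay(ft, "power"),
               tolerance = 1e-12)
})
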