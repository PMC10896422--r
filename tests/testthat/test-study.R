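# small study used across the integration tests
small_study <- function(seed = 1, settings = "sitting", n_subjects = 4,
                        effects = defaultLevelEffects()) {
  simulateStudy(
    eegSimConfig(sampling_rate = 128, level_effects = effects,
                 artifact_rate = 0),
    gaitSimConfig(n_cycles = 6),
    n_subjects = n_subjects, master_seed = seed, settings = settings,
    protocol = studyProtocol(8, 8, 16, gait_trials = 2))
}

test_that("a study is byte-identical for the same master seed", {
  a <- small_study(3)
  b <- small_study(3)
  expect_identical(eegSamples(a@recordings$S01$sitting$go_nogo_2),
                   eegSamples(b@recordings$S01$sitting$go_nogo_2))
  expect_identical(a@schedules, b@schedules)
  expect_identical(a@responses, b@responses)
  c <- small_study(4)
  expect_false(identical(eegSamples(a@recordings$S01$sitting$baseline),
                         eegSamples(c@recordings$S01$sitting$baseline)))
})

test_that("the study has the full subject x setting x condition layout", {
  st <- small_study(1, settings = c("sitting", "walking"), n_subjects = 3)
  recs <- unlist(st@recordings, recursive = FALSE)
  recs <- unlist(recs, recursive = FALSE)
  expect_length(recs, 3 * 2 * 5)
  # every recording spans its schedule's duration
  for (cn in setdiff(studyConditions(), "baseline")) {
    sch <- st@schedules[[cn]]
    dur <- duration(st@recordings$S01$sitting[[cn]])
    expect_gte(dur + 1e-9, max(sch$onset_s))
    # equal up to the one-sample rounding of the recording length
    expect_lt(abs(dur - st@protocol$durations[[cn]]), 1 / 128)
  }
  # walking gait trials exist per condition
  expect_equal(names(st@gait$S01), studyConditions())
  expect_length(st@gait$S01$baseline, 2)
})

test_that("the ground-truth registry mirrors the injected effects", {
  gt <- groundTruth(small_study(1))
  expect_equal(nrow(gt), 2)
  expect_true(any(gt$task == "go_nogo" & gt$channel == "Fz" &
                    gt$band == "delta" & gt$power_type == "relative" &
                    gt$direction == 1))
  expect_true(any(gt$task == "n_back" & gt$channel == "Fz" &
                    gt$band == "high_beta" & gt$power_type == "absolute" &
                    gt$direction == -1))
  expect_equal(nrow(groundTruth(small_study(1, effects =
                                              nullLevelEffects()))), 0)
  # non-unit level-1 factors are rejected: level 1 is the shared baseline
  bad <- defaultLevelEffects(); bad$l1[1] <- 1.2
  expect_error(eegSimConfig(level_effects = bad), "level-1")
})

test_that("screening output covers all 112 features for every context", {
  st <- small_study(2)
  an <- runStudyAnalysis(st)
  expect_equal(nrow(an$screen), 112 * 2)   # two tasks, one setting
  expect_equal(sort(unique(an$screen$task)), c("go_nogo", "n_back"))
  expect_equal(as.integer(table(an$screen$task)), c(112L, 112L))
  expect_true(all(!is.na(an$screen$rho) | !an$screen$passes_screen))
  expect_true(all(abs(an$screen$rho) <= 1, na.rm = TRUE))
  w <- an$screen$kendalls_w
  expect_true(all(w >= 0 & w <= 1, na.rm = TRUE))
  # task scores look sane
  expect_true(all(an$task_scores$percent_correct >= 0 &
                    an$task_scores$percent_correct <= 100))
})

test_that("the analysis is deterministic and round-trips through disk", {
  st <- small_study(5, settings = c("sitting", "walking"), n_subjects = 3)
  dir <- file.path(tempdir(), "study-export")
  unlink(dir, recursive = TRUE)
  exportStudy(st, dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))

  out1 <- file.path(tempdir(), "report1")
  out2 <- file.path(tempdir(), "report2")
  writeAnalysisReport(runStudyAnalysis(dir), out1)
  writeAnalysisReport(runStudyAnalysis(dir), out2)
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }

  # a deleted condition file is reported by name
  victim <- file.path(dir, "eeg", "S02_sitting_n_back_1.csv")
  unlink(victim)
  expect_error(runStudyAnalysis(dir), "S02_sitting_n_back_1")
})

test_that("gait comparisons span the six contrasts and detect the stride \
effect", {
  st <- small_study(6, settings = c("sitting", "walking"), n_subjects = 5)
  an <- runStudyAnalysis(st)
  gc <- an$gait_comparisons
  expect_setequal(unique(gc$comparison),
                  c("walking_vs_n_back_1", "walking_vs_n_back_2",
                    "walking_vs_go_nogo_1", "walking_vs_go_nogo_2",
                    "n_back_1_vs_n_back_2", "go_nogo_1_vs_go_nogo_2"))
  expect_true(all(c("stride_length", "gait_speed", "cadence",
                    "stance_pct", "swing_pct", "double_support_pct",
                    "step_width", "gps", "gvs_foot_progression") %in%
                    unique(gc$parameter)))
  expect_true(all(gc$p_value >= 0 & gc$p_value <= 1))
  # symmetric generator: left-only analysis is licensed
  expect_true(an$side_comparison$left_only_ok)
})

test_that("EEG recordings round-trip through the wide CSV format", {
  rec <- toy_recording(8, 1024, 256, seed = 10)
  f <- tempfile(fileext = ".csv")
  writeEEGCSV(rec, f)
  back <- readEEGCSV(f)
  expect_equal(samplingRate(back), 256)
  expect_equal(channelLabels(back), channelLabels(rec))
  expect_equal(eegSamples(back), eegSamples(rec), tolerance = 1e-12)
})
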