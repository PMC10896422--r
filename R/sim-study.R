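# deterministic sub-seed derivation (kept below 2^31)
.derive_seed <- function(master, i1 = 0, i2 = 0, i3 = 0) {
  as.integer((as.numeric(master) %% 1000003) * 1009 +
               i1 * 7919 + i2 * 101 + i3 * 13) %% 2147483562L + 1L
}

#' Study protocol sizes
#'
#' Trial counts and durations of the experimental protocol. The defaults
#' are the full protocol (150 Go/NoGo and 75 N-Back stimuli; the no-task
#' baseline matches the 300 s level-1 Go/NoGo run). Reduced protocols
#' (fewer trials, shorter baseline) are used for simulation studies where
#' the full runs would be needlessly slow.
#'
#' @param go_nogo_trials,n_back_trials stimuli per run.
#' @param baseline_duration baseline recording length, s (default: the
#'   level-1 Go/NoGo run length).
#' @param gait_trials walking trials recorded per condition.
#' @param response_accuracy per-trial probability of a correct response
#'   in the simulated logs.
#' @return list of class `study_protocol`.
#' @examples
#' studyProtocol()                       # full protocol
#' studyProtocol(20, 20, 40)             # reduced, for simulations
#' @export
studyProtocol <- function(go_nogo_trials = 150, n_back_trials = 75,
                          baseline_duration = NULL, gait_trials = 3,
                          response_accuracy = 0.9) {
  if (is.null(baseline_duration)) baseline_duration <- go_nogo_trials * 2.0
  structure(list(go_nogo_trials = go_nogo_trials,
                 n_back_trials = n_back_trials,
                 baseline_duration = baseline_duration,
                 gait_trials = gait_trials,
                 response_accuracy = response_accuracy),
            class = "study_protocol")
}

# condition -> (task context, difficulty level 1..3)
.condition_map <- data.frame(
  condition = c("baseline", "go_nogo_1", "go_nogo_2", "n_back_1",
                "n_back_2"),
  task = c(NA, "go_nogo", "go_nogo", "n_back", "n_back"),
  level = c(1L, 2L, 3L, 2L, 3L)
)

#' Epoch duration for a condition
#'
#' Epoch length equals the trial length: 2 s and 1.3 s for the two
#' Go/NoGo levels, 1.5 s for both N-Back levels. The un-stimulated
#' baseline is cut into 2 s epochs.
#'
#' @param condition condition label.
#' @return epoch duration in seconds.
#' @export
epochDurationFor <- function(condition) {
  switch(condition,
         baseline = 2.0, go_nogo_1 = 2.0, go_nogo_2 = 1.3,
         n_back_1 = 1.5, n_back_2 = 1.5,
         stop("unknown condition: ", condition))
}

#' Simulate a complete dual-task study
#'
#' Builds the full synthetic data set the analysis pipeline consumes:
#' for each of `n_subjects` subjects, each setting and each of the five
#' conditions, an EEG recording spanning the condition's schedule (with
#' per-subject log-normal band-amplitude jitter, the configured level
#' effects, walking-setting broadband noise, and burst artifacts); shared
#' stimulus schedules; simulated response logs; and, for the walking
#' setting, gait trials per condition with per-subject stride and
#' foot-progression offsets. All randomness derives deterministically
#' from `master_seed`.
#'
#' @param eeg_config an [eegSimConfig()].
#' @param gait_config a [gaitSimConfig()].
#' @param n_subjects number of subjects (>= 3; study default 13).
#' @param master_seed integer master seed.
#' @param settings subset of `c("sitting", "walking")`.
#' @param protocol a [studyProtocol()].
#' @return a [SyntheticStudy-class].
#' @examples
#' st <- simulateStudy(eegSimConfig(sampling_rate = 128), gaitSimConfig(),
#'                     n_subjects = 3, master_seed = 1,
#'                     settings = "sitting",
#'                     protocol = studyProtocol(10, 10, 20))
#' st
#' @export
simulateStudy <- function(eeg_config = eegSimConfig(),
                          gait_config = gaitSimConfig(),
                          n_subjects = 13, master_seed = 1,
                          settings = c("sitting", "walking"),
                          protocol = studyProtocol()) {
  stopifnot(n_subjects >= 3)
  settings <- match.arg(settings, several.ok = TRUE)
  conds <- studyConditions()
  subjects <- sprintf("S%02d", seq_len(n_subjects))

  specs <- list(
    go_nogo_1 = taskSpec("go_nogo", 1, n_trials = protocol$go_nogo_trials),
    go_nogo_2 = taskSpec("go_nogo", 2, n_trials = protocol$go_nogo_trials),
    n_back_1 = taskSpec("n_back", 1, n_trials = protocol$n_back_trials),
    n_back_2 = taskSpec("n_back", 2, n_trials = protocol$n_back_trials)
  )
  schedules <- c(list(baseline = NULL),
                 lapply(seq_along(specs), function(i) {
                   buildSchedule(specs[[i]],
                                 .derive_seed(master_seed, 0, 0, i))
                 }))
  names(schedules) <- conds
  durations <- vapply(conds, function(cn) {
    if (cn == "baseline") protocol$baseline_duration else
      scheduleDuration(schedules[[cn]], specs[[cn]])
  }, 0)

  recordings <- list(); responses <- list(); gait <- list()
  n_gb <- nrow(.gen_bands)
  for (si in seq_len(n_subjects)) {
    sid <- subjects[si]
    set.seed(.derive_seed(master_seed, si))
    band_gains <- setNames(exp(rnorm(n_gb, 0, eeg_config$subject_sd)),
                           .gen_bands$band)
    stride_offset <- rnorm(1, 0, gait_config$subject_stride_sd)
    fp_offset <- rnorm(1, 0, gait_config$subject_fp_sd)
    recordings[[sid]] <- list(); responses[[sid]] <- list()
    gait[[sid]] <- list()
    for (st_i in seq_along(settings)) {
      stg <- settings[st_i]
      recordings[[sid]][[stg]] <- list()
      for (ci in seq_along(conds)) {
        cn <- conds[ci]
        cm <- .condition_map[.condition_map$condition == cn, ]
        seed <- .derive_seed(master_seed, si, st_i, ci)
        rec <- simulateEEGRecording(
          eeg_config, level = cm$level, duration = durations[[cn]],
          seed = seed, task = if (is.na(cm$task)) NULL else cm$task,
          setting = stg, band_gains = band_gains)
        if (eeg_config$artifact_rate > 0) {
          rec <- injectArtifacts(rec, eeg_config, seed + 1L)$recording
        }
        recordings[[sid]][[stg]][[cn]] <- rec
        if (stg == "walking") {
          gait[[sid]][[cn]] <- lapply(seq_len(protocol$gait_trials),
            function(k) simulateGaitTrial(
              gait_config, cn, seed = .derive_seed(master_seed, si, ci, k),
              stride_offset = stride_offset, fp_offset = fp_offset))
        }
      }
    }
    for (cn in setdiff(conds, "baseline")) {
      ci <- match(cn, conds)
      responses[[sid]][[cn]] <- simulateResponses(
        schedules[[cn]], specs[[cn]], accuracy = protocol$response_accuracy,
        seed = .derive_seed(master_seed, si, 9, ci))
    }
  }

  le <- eeg_config$level_effects
  gt <- if (nrow(le) > 0) {
    data.frame(task = le$task, channel = le$channel, band = le$band,
               power_type = le$power_type,
               direction = sign(le$l3 - le$l1))
  } else {
    data.frame(task = character(0), channel = character(0),
               band = character(0), power_type = character(0),
               direction = numeric(0))
  }
  gt <- gt[gt$direction != 0, , drop = FALSE]

  new("SyntheticStudy", recordings = recordings, schedules = schedules,
      responses = responses, gait = gait, groundTruth = gt,
      eegConfig = unclass(eeg_config), gaitConfig = unclass(gait_config),
      protocol = c(unclass(protocol),
                   list(settings = settings, durations = as.list(durations),
                        sampling_rate = eeg_config$sampling_rate)),
      masterSeed = as.integer(master_seed))
}
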