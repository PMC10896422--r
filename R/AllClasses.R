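#' Standard channel montage and condition labels
#'
#' The eight-channel dry-electrode montage (10/20 positions) and the five
#' experimental conditions used throughout the package: a no-task baseline
#' plus two difficulty levels each of the Go/NoGo (inhibition) and N-Back
#' (working memory) tasks.
#'
#' @return `eegChannels()` returns the eight channel labels;
#'   `studyConditions()` the five condition labels; `studySettings()` the
#'   two acquisition settings.
#' @examples
#' eegChannels()
#' studyConditions()
#' @export
eegChannels <- function() c("Fp1", "Fp2", "Fz", "Cz", "C3", "C4", "O1", "O2")

#' @rdname eegChannels
#' @export
studyConditions <- function() {
  c("baseline", "go_nogo_1", "go_nogo_2", "n_back_1", "n_back_2")
}

#' @rdname eegChannels
#' @export
studySettings <- function() c("sitting", "walking")

#' Multichannel EEG recording
#'
#' An in-memory EEG recording: a channels-by-samples matrix in microvolts
#' with its sampling rate. Channel labels are the matrix rownames.
#'
#' @slot samples numeric matrix, channels x time points, microvolts.
#' @slot samplingRate sampling rate in Hz.
#'
#' @seealso [EEGRecording()] for the constructor,
#'   [bandpassFilter()], [asrClean()], [epochRecording()].
#' @export
setClass("EEGRecording",
  representation(samples = "matrix", samplingRate = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@samples) < 2) {
      msg <- c(msg, "a recording needs at least 2 channels")
    }
    if (is.null(rownames(object@samples))) {
      msg <- c(msg, "channel labels (rownames of 'samples') are required")
    } else if (anyDuplicated(rownames(object@samples))) {
      msg <- c(msg, "channel labels must be unique")
    }
    if (!all(is.finite(object@samples))) {
      msg <- c(msg, "samples contain non-finite values")
    }
    if (length(object@samplingRate) != 1 || object@samplingRate <= 0) {
      msg <- c(msg, "samplingRate must be a single positive number")
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct an EEGRecording
#'
#' @param samples channels x samples numeric matrix (microvolts); rownames
#'   are the channel labels. If rownames are absent, `channels` is used.
#' @param samplingRate sampling rate in Hz.
#' @param channels optional channel labels (length `nrow(samples)`).
#' @return An [EEGRecording-class] object.
#' @examples
#' x <- matrix(rnorm(8 * 512), nrow = 8, dimnames = list(eegChannels(), NULL))
#' rec <- EEGRecording(x, samplingRate = 512)
#' nSamples(rec)
#' @export
EEGRecording <- function(samples, samplingRate, channels = NULL) {
  if (!is.null(channels)) rownames(samples) <- channels
  new("EEGRecording", samples = samples, samplingRate = samplingRate)
}

#' Trial-locked EEG epochs
#'
#' Equal-length slices of a recording aligned at stimulus onsets, stored as
#' an epochs x channels x samples array.
#'
#' @slot epochs numeric array `n_epochs x channels x samples_per_epoch`.
#' @slot samplingRate sampling rate in Hz.
#' @slot epochDuration epoch length in seconds.
#' @slot onsets onset times (s) of the retained epochs.
#' @slot dropped onset times (s) whose window ran past the recording end.
#' @slot condition condition label.
#' @export
setClass("EpochSet",
  representation(
    epochs = "array", samplingRate = "numeric", epochDuration = "numeric",
    onsets = "numeric", dropped = "numeric", condition = "character"
  ),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@epochs)) != 3) {
      msg <- c(msg, "'epochs' must be a 3-d array (epochs x channels x samples)")
    } else if (dim(object@epochs)[1] != length(object@onsets)) {
      msg <- c(msg, "number of epochs must match number of onsets")
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' Graded cognitive task specification
#'
#' Parameters of one difficulty level of a Go/NoGo or N-Back task. Use
#' [taskSpec()] to obtain the study defaults: Go/NoGo presents 150 stimuli
#' at a 2.0 s (level 1) or 1.3 s (level 2) inter-trial distance; N-Back
#' presents 75 stimuli of 1.5 s each with load factor N = 1 or 2.
#'
#' @slot taskName `"go_nogo"` or `"n_back"`.
#' @slot level difficulty level, 1 or 2.
#' @slot nTrials number of stimuli presented.
#' @slot interTrialInterval seconds between Go/NoGo stimulus onsets.
#' @slot trialDuration N-Back trial length in seconds.
#' @slot loadFactor N-Back load factor N (0 for Go/NoGo).
#' @slot targetFraction fraction of no-go (Go/NoGo) or match (N-Back) trials.
#' @slot nScored scoring denominator (150 for Go/NoGo, 44 for N-Back).
#' @export
setClass("TaskSpec",
  representation(
    taskName = "character", level = "integer", nTrials = "integer",
    interTrialInterval = "numeric", trialDuration = "numeric",
    loadFactor = "integer", targetFraction = "numeric", nScored = "integer"
  ),
  validity = function(object) {
    msg <- NULL
    if (!object@taskName %in% c("go_nogo", "n_back")) {
      msg <- c(msg, "taskName must be 'go_nogo' or 'n_back'")
    }
    if (!object@level %in% 1:2) msg <- c(msg, "level must be 1 or 2")
    if (object@nTrials <= 0) msg <- c(msg, "nTrials must be positive")
    if (object@taskName == "go_nogo" && object@interTrialInterval <= 0) {
      msg <- c(msg, "interTrialInterval must be positive")
    }
    if (object@taskName == "n_back" && object@trialDuration <= 0) {
      msg <- c(msg, "trialDuration must be positive")
    }
    if (object@loadFactor >= object@nTrials) {
      msg <- c(msg, "loadFactor must be smaller than nTrials")
    }
    if (object@targetFraction < 0 || object@targetFraction > 1) {
      msg <- c(msg, "targetFraction must be in [0, 1]")
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' One simulated or recorded gait trial
#'
#' Marker trajectories (metres), gait events, and 101-point time-normalized
#' lower-limb kinematic curves (degrees) for both sides.
#'
#' @slot markers named list of frames x 3 matrices (x = progression,
#'   y = mediolateral, z = vertical), e.g. `heel_L`, `heel_R`, `mtH_L`,
#'   `mtH_R`.
#' @slot frameRate camera frame rate, Hz.
#' @slot events list with elements `left` and `right`, each a list of
#'   `heel_strike` and `toe_off` times in seconds.
#' @slot curves list with elements `left` and `right`, each a 101 x 9
#'   matrix (percent gait cycle x kinematic variable, degrees).
#' @slot condition condition label.
#' @export
setClass("GaitTrial",
  representation(
    markers = "list", frameRate = "numeric", events = "list",
    curves = "list", condition = "character"
  ),
  validity = function(object) {
    msg <- NULL
    for (side in c("left", "right")) {
      ev <- object@events[[side]]
      if (is.null(ev)) { msg <- c(msg, paste("missing events for", side)); next }
      if (is.unsorted(ev$heel_strike, strictly = TRUE)) {
        msg <- c(msg, paste(side, "heel strikes must be strictly increasing"))
      }
      cv <- object@curves[[side]]
      if (!is.null(cv) && nrow(cv) != 101) {
        msg <- c(msg, paste(side, "curves must have 101 samples"))
      }
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' Band-power feature table
#'
#' A [SummarizedExperiment-class][SummarizedExperiment::SummarizedExperiment]
#' holding the 112 EEG band-power features (8 channels x 7 bands x
#' absolute/relative power) as rows, with one column per
#' (subject, setting, condition) cell. `rowData` carries `channel`, `band`
#' and `power_type`; `colData` carries `subject`, `setting`, `condition`.
#'
#' @seealso [buildFeatureTable()], [featureValues()], [screenFeatures()].
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

#' A full synthetic dual-task study
#'
#' Container produced by [simulateStudy()]: per subject x setting x
#' condition EEG recordings with their stimulus schedules and response
#' logs, per walking condition gait trials, and the ground-truth registry
#' of injected effects.
#'
#' @slot recordings nested list `[[subject]][[setting]][[condition]]` of
#'   [EEGRecording-class] objects.
#' @slot schedules list `[[condition]]` of stimulus schedules (baseline
#'   entry is `NULL`).
#' @slot responses nested list `[[subject]][[condition]]` of response logs.
#' @slot gait nested list `[[subject]][[condition]]` of
#'   [GaitTrial-class] objects (walking setting only).
#' @slot groundTruth data.frame of injected effects: `task`, `channel`,
#'   `band`, `power_type`, `direction`.
#' @slot eegConfig,gaitConfig the generator configurations used.
#' @slot protocol list: trial counts, durations and sampling rate used.
#' @slot masterSeed integer master seed.
#' @export
setClass("SyntheticStudy",
  representation(
    recordings = "list", schedules = "list", responses = "list",
    gait = "list", groundTruth = "data.frame", eegConfig = "list",
    gaitConfig = "list", protocol = "list", masterSeed = "integer"
  )
)
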