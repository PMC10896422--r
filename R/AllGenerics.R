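#' @rdname EEGRecording-class
#' @param object,x an object.
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname EEGRecording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EEGRecording-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname EEGRecording-class
#' @export
setGeneric("eegSamples", function(x) standardGeneric("eegSamples"))

#' @rdname EpochSet-class
#' @param x an object.
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

setMethod("channelLabels", "EEGRecording", function(x) rownames(x@samples))
setMethod("samplingRate", "EEGRecording", function(x) x@samplingRate)
setMethod("nSamples", "EEGRecording", function(x) ncol(x@samples))
setMethod("eegSamples", "EEGRecording", function(x) x@samples)

setMethod("channelLabels", "EpochSet", function(x) dimnames(x@epochs)[[2]])
setMethod("samplingRate", "EpochSet", function(x) x@samplingRate)
setMethod("nEpochs", "EpochSet", function(x) dim(x@epochs)[1])

#' @describeIn EEGRecording-class duration of the recording in seconds.
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
setMethod("duration", "EEGRecording", function(x) {
  ncol(x@samples) / x@samplingRate
})

setMethod("show", "EEGRecording", function(object) {
  cat("EEGRecording:", nrow(object@samples), "channels x",
      ncol(object@samples), "samples @", object@samplingRate, "Hz (",
      sprintf("%.1f", duration(object)), "s )\n")
  cat("  channels:", paste(channelLabels(object), collapse = ", "), "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat("EpochSet:", d[1], "epochs x", d[2], "channels x", d[3], "samples @",
      object@samplingRate, "Hz\n")
  cat("  condition:", object@condition,
      " epoch duration:", object@epochDuration, "s",
      " dropped onsets:", length(object@dropped), "\n")
})

setMethod("show", "TaskSpec", function(object) {
  cat("TaskSpec:", object@taskName, "level", object@level, "-",
      object@nTrials, "trials,")
  if (object@taskName == "go_nogo") {
    cat(" inter-trial interval", object@interTrialInterval, "s\n")
  } else {
    cat(" trial duration", object@trialDuration, "s, N =",
        object@loadFactor, "\n")
  }
  cat("  target fraction:", object@targetFraction,
      " scored trials:", object@nScored, "\n")
})

setMethod("show", "GaitTrial", function(object) {
  nhs <- length(object@events$left$heel_strike)
  cat("GaitTrial (", object@condition, "): ", nhs, " left heel strikes, ",
      length(object@markers), " markers @ ", object@frameRate, " Hz\n",
      sep = "")
})

setMethod("show", "SyntheticStudy", function(object) {
  cat("SyntheticStudy:", length(object@recordings), "subjects x",
      paste(object@protocol$settings, collapse = "/"), "x",
      length(object@schedules), "conditions (master seed",
      object@masterSeed, ")\n")
  cat("  ground-truth effects:", nrow(object@groundTruth), "\n")
})

#' Ground-truth effect registry of a synthetic study
#'
#' @param study a [SyntheticStudy-class].
#' @return data.frame with columns `task`, `channel`, `band`, `power_type`,
#'   `direction` (+1 increasing with difficulty, -1 decreasing).
#' @export
groundTruth <- function(study) {
  stopifnot(is(study, "SyntheticStudy"))
  study@groundTruth
}

#' Feature values as a samples-by-features matrix
#'
#' Transposed view of a [FeatureTable-class]: one row per
#' (subject, setting, condition) cell, one column per feature.
#'
#' @param ft a [FeatureTable-class].
#' @return numeric matrix with the `colData` cells as rows.
#' @export
featureValues <- function(ft) {
  stopifnot(is(ft, "FeatureTable"))
  t(assay(ft, "power"))
}
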