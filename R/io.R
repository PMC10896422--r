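#' Read and write EEG recordings as wide CSV
#'
#' One column per channel (header = channel labels), one row per sample,
#' values in microvolts. The sampling rate travels in a `# fs=<Hz>`
#' comment on the first line.
#'
#' @param rec an [EEGRecording-class].
#' @param path CSV file path.
#' @param samplingRate override for files without the `# fs=` header.
#' @return `readEEGCSV` returns an [EEGRecording-class].
#' @export
writeEEGCSV <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# fs=", samplingRate(rec)), con)
  write.csv(as.data.frame(t(eegSamples(rec))), con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEEGCSV
#' @export
readEEGCSV <- function(path, samplingRate = NULL) {
  first <- readLines(path, n = 1)
  if (grepl("^# fs=", first)) {
    samplingRate <- as.numeric(sub("^# fs=", "", first))
    x <- read.csv(path, skip = 1, check.names = FALSE)
  } else {
    if (is.null(samplingRate)) stop("samplingRate required (no # fs header)")
    x <- read.csv(path, check.names = FALSE)
  }
  m <- t(as.matrix(x))
  if (!all(is.finite(m))) stop("non-finite samples in ", path)
  EEGRecording(m, samplingRate)
}

#' Read and write 101-point kinematic curve sets as CSV
#'
#' 101 rows (0-100% gait cycle), one column per kinematic variable.
#'
#' @param curves 101 x 9 matrix.
#' @param path CSV file path.
#' @return `readCurvesCSV` returns the matrix.
#' @export
writeCurvesCSV <- function(curves, path) {
  stopifnot(nrow(curves) == 101)
  write.csv(as.data.frame(curves), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCurvesCSV
#' @export
readCurvesCSV <- function(path) {
  as.matrix(read.csv(path, check.names = FALSE))
}

# long CSV (frame, marker, x, y, z) <-> named list of frames x 3 matrices
.write_markers <- function(markers, path) {
  long <- do.call(rbind, lapply(names(markers), function(nm) {
    m <- markers[[nm]]
    data.frame(frame = seq_len(nrow(m)), marker = nm,
               x = m[, "x"], y = m[, "y"], z = m[, "z"])
  }))
  write.csv(long, path, row.names = FALSE)
}

.read_markers <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(long, long$marker), function(d) {
    d <- d[order(d$frame), ]
    cbind(x = d$x, y = d$y, z = d$z)
  })
  out[unique(long$marker)]
}

.write_events <- function(events, path) {
  long <- do.call(rbind, lapply(c("left", "right"), function(side) {
    rbind(data.frame(side = side, event = "heel_strike",
                     time_s = events[[side]]$heel_strike),
          data.frame(side = side, event = "toe_off",
                     time_s = events[[side]]$toe_off))
  }))
  write.csv(long, path, row.names = FALSE)
}

.read_events <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(c("left", "right"), function(side) {
    list(heel_strike = sort(long$time_s[long$side == side &
                                          long$event == "heel_strike"]),
         toe_off = sort(long$time_s[long$side == side &
                                      long$event == "toe_off"]))
  })
  names(out) <- c("left", "right")
  out
}

#' Export a study to disk
#'
#' Writes every recording, schedule, response log and gait trial of a
#' [SyntheticStudy-class] as plain-text files (wide CSV EEG, TSV
#' schedules/logs, long CSV markers, CSV events and curves) under `dir`,
#' plus a `manifest.yaml` listing the layout, the protocol and the
#' ground-truth registry. [readStudy()] reverses this; [runStudyAnalysis()]
#' accepts the directory path directly.
#'
#' @param study a [SyntheticStudy-class].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
exportStudy <- function(study, dir) {
  stopifnot(is(study, "SyntheticStudy"))
  for (d in c("", "eeg", "schedules", "responses", "gait")) {
    dir.create(file.path(dir, d), showWarnings = FALSE, recursive = TRUE)
  }
  subjects <- names(study@recordings)
  settings <- study@protocol$settings
  for (sid in subjects) {
    for (stg in settings) {
      for (cn in studyConditions()) {
        writeEEGCSV(study@recordings[[sid]][[stg]][[cn]],
                    file.path(dir, "eeg",
                              paste0(sid, "_", stg, "_", cn, ".csv")))
      }
    }
    for (cn in names(study@responses[[sid]])) {
      writeResponsesTSV(study@responses[[sid]][[cn]],
                        file.path(dir, "responses",
                                  paste0(sid, "_", cn, ".tsv")))
    }
    for (cn in names(study@gait[[sid]])) {
      for (k in seq_along(study@gait[[sid]][[cn]])) {
        tr <- study@gait[[sid]][[cn]][[k]]
        base <- file.path(dir, "gait", paste0(sid, "_", cn, "_t", k))
        .write_markers(tr@markers, paste0(base, "_markers.csv"))
        .write_events(tr@events, paste0(base, "_events.csv"))
        writeCurvesCSV(tr@curves$left, paste0(base, "_curves_left.csv"))
        writeCurvesCSV(tr@curves$right, paste0(base, "_curves_right.csv"))
      }
    }
  }
  for (cn in setdiff(studyConditions(), "baseline")) {
    writeScheduleTSV(study@schedules[[cn]],
                     file.path(dir, "schedules", paste0(cn, ".tsv")))
  }
  writeCurvesCSV(study@gaitConfig$reference, file.path(dir, "reference.csv"))
  manifest <- list(
    subjects = subjects, settings = settings,
    conditions = studyConditions(), master_seed = study@masterSeed,
    protocol = study@protocol[c("go_nogo_trials", "n_back_trials",
                                "baseline_duration", "gait_trials",
                                "response_accuracy")],
    sampling_rate = study@protocol$sampling_rate,
    frame_rate = study@gaitConfig$frame_rate,
    gait_trials_per_condition = lapply(
      setNames(nm = subjects),
      function(sid) lapply(study@gait[[sid]], length)),
    ground_truth = if (nrow(study@groundTruth)) {
      lapply(seq_len(nrow(study@groundTruth)),
             function(i) as.list(study@groundTruth[i, ]))
    } else list()
  )
  write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read an exported study back from disk
#'
#' @param dir directory written by [exportStudy()].
#' @return a [SyntheticStudy-class].
#' @export
readStudy <- function(dir) {
  mf_path <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf_path)) stop("no manifest.yaml under ", dir)
  mf <- read_yaml(mf_path)
  missing <- character(0)
  recordings <- list(); responses <- list(); gait <- list()
  for (sid in mf$subjects) {
    recordings[[sid]] <- list(); responses[[sid]] <- list()
    gait[[sid]] <- list()
    for (stg in mf$settings) {
      recordings[[sid]][[stg]] <- list()
      for (cn in mf$conditions) {
        p <- file.path(dir, "eeg", paste0(sid, "_", stg, "_", cn, ".csv"))
        if (!file.exists(p)) { missing <- c(missing, p); next }
        recordings[[sid]][[stg]][[cn]] <- readEEGCSV(p)
      }
    }
    for (cn in setdiff(mf$conditions, "baseline")) {
      p <- file.path(dir, "responses", paste0(sid, "_", cn, ".tsv"))
      if (file.exists(p)) responses[[sid]][[cn]] <- readResponsesTSV(p)
    }
    ntr <- mf$gait_trials_per_condition[[sid]]
    for (cn in names(ntr)) {
      gait[[sid]][[cn]] <- lapply(seq_len(ntr[[cn]]), function(k) {
        base <- file.path(dir, "gait", paste0(sid, "_", cn, "_t", k))
        new("GaitTrial",
            markers = .read_markers(paste0(base, "_markers.csv")),
            frameRate = mf$frame_rate,
            events = .read_events(paste0(base, "_events.csv")),
            curves = list(
              left = readCurvesCSV(paste0(base, "_curves_left.csv")),
              right = readCurvesCSV(paste0(base, "_curves_right.csv"))),
            condition = cn)
      })
    }
  }
  if (length(missing)) {
    stop("missing condition files:\n  ", paste(missing, collapse = "\n  "))
  }
  schedules <- c(list(baseline = NULL),
                 lapply(setNames(nm = setdiff(mf$conditions, "baseline")),
                        function(cn) readScheduleTSV(
                          file.path(dir, "schedules",
                                    paste0(cn, ".tsv")))))
  gt <- if (length(mf$ground_truth)) {
    do.call(rbind, lapply(mf$ground_truth, as.data.frame))
  } else {
    data.frame(task = character(0), channel = character(0),
               band = character(0), power_type = character(0),
               direction = numeric(0))
  }
  new("SyntheticStudy", recordings = recordings, schedules = schedules,
      responses = responses, gait = gait, groundTruth = gt,
      eegConfig = list(sampling_rate = mf$sampling_rate),
      gaitConfig = list(reference = readCurvesCSV(
        file.path(dir, "reference.csv")), frame_rate = mf$frame_rate),
      protocol = c(mf$protocol,
                   list(settings = unlist(mf$settings),
                        sampling_rate = mf$sampling_rate)),
      masterSeed = as.integer(mf$master_seed))
}
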