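#' Run the full dual-task analysis on a study
#'
#' The end-to-end pipeline: every EEG recording is bandpass filtered
#' (0.5-45 Hz, zero phase), cleaned with the variance-threshold subspace
#' remover, cut into trial-locked epochs (epoch length = trial length;
#' the baseline is cut into 2 s epochs), and summarized into the 112
#' band-power features. The four analysis contexts (setting x task) are
#' screened for strictly monotone mean trends and Friedman-tested; gait
#' trials yield spatial-temporal parameters and GVS/GPS, the left-right
#' symmetry check, and the six between-condition Wilcoxon-Mann-Whitney
#' comparisons; response logs are scored. The analysis itself is
#' deterministic: rerunning on the same study reproduces identical
#' results.
#'
#' @param study a [SyntheticStudy-class], or a path to a study directory
#'   written by [exportStudy()].
#' @param asr apply the subspace cleaner (default TRUE).
#' @param alpha significance level used throughout.
#' @param gps_method GPS aggregation, see [gps()].
#' @return list of class `study_analysis`: `features`
#'   ([FeatureTable-class]), `screen`, `per_subject_rho`, `gait_metrics`,
#'   `side_comparison`, `gait_comparisons`, `task_scores`, `alpha`.
#' @examples
#' st <- simulateStudy(eegSimConfig(sampling_rate = 128, artifact_rate = 0),
#'                     n_subjects = 3, master_seed = 1,
#'                     settings = "sitting",
#'                     protocol = studyProtocol(10, 10, 20))
#' an <- runStudyAnalysis(st)
#' head(subset(an$screen, passes_screen))
#' @export
runStudyAnalysis <- function(study, asr = TRUE, alpha = 0.05,
                             gps_method = c("rms", "sum")) {
  if (is.character(study)) study <- readStudy(study)
  stopifnot(is(study, "SyntheticStudy"))
  gps_method <- match.arg(gps_method)
  settings <- study@protocol$settings
  conds <- studyConditions()
  subjects <- names(study@recordings)
  cfg <- cleanerConfig()

  rows <- list(); info <- list()
  for (sid in subjects) {
    for (stg in settings) {
      for (cn in conds) {
        rec <- study@recordings[[sid]][[stg]][[cn]]
        if (is.null(rec)) stop("missing recording: ", sid, "/", stg, "/", cn)
        rec <- bandpassFilter(rec, cfg)
        if (asr) rec <- asrClean(rec, cfg)$recording
        ep_dur <- epochDurationFor(cn)
        onsets <- if (cn == "baseline") {
          seq(0, duration(rec) - ep_dur, by = ep_dur)
        } else study@schedules[[cn]]
        ep <- epochRecording(rec, onsets, ep_dur, condition = cn)
        key <- paste(sid, stg, cn, sep = ".")
        rows[[key]] <- extractConditionFeatures(ep)
        info[[key]] <- data.frame(
          subject = sid, setting = stg, condition = cn,
          level = .condition_map$level[.condition_map$condition == cn])
      }
    }
  }
  ft <- buildFeatureTable(rows, do.call(rbind, info))

  screen <- do.call(rbind, lapply(settings, function(stg) {
    rbind(screenFeatures(ft, stg, "go_nogo", alpha),
          screenFeatures(ft, stg, "n_back", alpha))
  }))

  sig <- screen[screen$significant, ]
  per_subject <- if (nrow(sig) > 0) {
    do.call(rbind, lapply(seq_len(nrow(sig)), function(i) {
      ps <- perSubjectSpearman(ft, sig$feature[i], sig$setting[i],
                               sig$task[i])
      data.frame(feature = sig$feature[i], setting = sig$setting[i],
                 task = sig$task[i], subject = names(ps$rho),
                 rho = unname(ps$rho), row.names = NULL)
    }))
  } else {
    data.frame(feature = character(0), setting = character(0),
               task = character(0), subject = character(0),
               rho = numeric(0))
  }

  gait_metrics <- NULL; side_comparison <- NULL; comparisons <- NULL
  if ("walking" %in% settings && length(study@gait[[1]]) > 0) {
    ref <- study@gaitConfig$reference
    gait_metrics <- do.call(rbind, lapply(subjects, function(sid) {
      do.call(rbind, lapply(conds, function(cn) {
        trials <- study@gait[[sid]][[cn]]
        do.call(rbind, lapply(c("left", "right"), function(side) {
          per_trial <- lapply(trials, function(tr) {
            cbind(spatiotemporalParams(tr, side),
                  trialGaitProfile(tr, ref, side, gps_method))
          })
          m <- colMeans(do.call(rbind, per_trial))
          cbind(data.frame(subject = sid, condition = cn, side = side),
                as.data.frame(as.list(m)))
        }))
      }))
    }))
    num_cols <- names(gait_metrics)[vapply(gait_metrics, is.numeric, TRUE)]
    subj_side <- function(side) {
      g <- gait_metrics[gait_metrics$side == side, ]
      out <- aggregate(g[num_cols], by = list(subject = g$subject), mean)
      out[order(out$subject), ]
    }
    side_comparison <- compareSides(subj_side("left")[num_cols],
                                    subj_side("right")[num_cols], alpha)
    left <- gait_metrics[gait_metrics$side == "left",
                         c("subject", "condition", num_cols)]
    comparisons <- gaitComparisons(left, alpha)
  }

  scores <- do.call(rbind, lapply(subjects, function(sid) {
    do.call(rbind, lapply(names(study@responses[[sid]]), function(cn) {
      task <- .condition_map$task[.condition_map$condition == cn]
      lvl <- as.integer(substr(cn, nchar(cn), nchar(cn)))
      sp <- if (task == "go_nogo") {
        taskSpec("go_nogo", lvl, n_trials = study@protocol$go_nogo_trials)
      } else {
        taskSpec("n_back", lvl, n_trials = study@protocol$n_back_trials)
      }
      sc <- scoreResponses(study@schedules[[cn]],
                           study@responses[[sid]][[cn]], sp)
      data.frame(subject = sid, condition = cn,
                 n_correct = sc$n_correct, n_scored = sc$n_scored,
                 percent_correct = sc$percent_correct)
    }))
  }))

  structure(list(features = ft, screen = screen,
                 per_subject_rho = per_subject,
                 gait_metrics = gait_metrics,
                 side_comparison = side_comparison,
                 gait_comparisons = comparisons,
                 task_scores = scores, alpha = alpha),
            class = "study_analysis")
}

#' @export
print.study_analysis <- function(x, ...) {
  cat("Dual-task study analysis\n")
  cat("  features:", nrow(x$features), "x", ncol(x$features), "cells\n")
  cat("  screened in:", sum(x$screen$passes_screen), "of",
      nrow(x$screen), "feature/context pairs;",
      sum(x$screen$significant), "significant at alpha =", x$alpha, "\n")
  if (!is.null(x$gait_comparisons)) {
    cat("  gait comparisons significant:",
        sum(x$gait_comparisons$significant), "of",
        nrow(x$gait_comparisons), "\n")
  }
  invisible(x)
}

# the six between-condition contrasts of the gait analysis
.gait_contrasts <- data.frame(
  label = c("walking_vs_n_back_1", "walking_vs_n_back_2",
            "walking_vs_go_nogo_1", "walking_vs_go_nogo_2",
            "n_back_1_vs_n_back_2", "go_nogo_1_vs_go_nogo_2"),
  a = c("baseline", "baseline", "baseline", "baseline", "n_back_1",
        "go_nogo_1"),
  b = c("n_back_1", "n_back_2", "go_nogo_1", "go_nogo_2", "n_back_2",
        "go_nogo_2")
)

#' Between-condition gait comparisons
#'
#' The six Wilcoxon-Mann-Whitney contrasts of the gait analysis
#' (unpaired, as the study analysis prescribes): unperturbed walking
#' against each dual-task condition, and the two within-task level
#' contrasts, for every gait parameter.
#'
#' @param metrics data.frame with columns `subject`, `condition` and one
#'   numeric column per gait parameter (one row per subject x condition).
#' @param alpha significance level.
#' @param paired use the paired signed-rank alternative instead of the
#'   unpaired test (default FALSE, matching the study analysis).
#' @return data.frame: `comparison`, `parameter`, `statistic`, `p_value`,
#'   `significant`.
#' @export
gaitComparisons <- function(metrics, alpha = 0.05, paired = FALSE) {
  params <- setdiff(names(metrics)[vapply(metrics, is.numeric, TRUE)],
                    c("level"))
  do.call(rbind, lapply(seq_len(nrow(.gait_contrasts)), function(i) {
    ca <- .gait_contrasts$a[i]; cb <- .gait_contrasts$b[i]
    ma <- metrics[metrics$condition == ca, ]
    mb <- metrics[metrics$condition == cb, ]
    if (paired) {
      ord <- order(ma$subject); ma <- ma[ord, ]
      mb <- mb[order(mb$subject), ]
    }
    do.call(rbind, lapply(params, function(p) {
      res <- if (paired) wilcoxonSignedRank(ma[[p]], mb[[p]]) else
        mannWhitneyU(ma[[p]], mb[[p]])
      data.frame(comparison = .gait_contrasts$label[i], parameter = p,
                 statistic = res$statistic, p_value = res$p_value,
                 significant = res$p_value < alpha)
    }))
  }))
}

#' Write an analysis report
#'
#' Writes the analysis tables as CSV plus a short markdown summary.
#' Deterministic: identical input produces byte-identical files.
#'
#' @param analysis a `study_analysis` from [runStudyAnalysis()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeAnalysisReport <- function(analysis, dir) {
  stopifnot(inherits(analysis, "study_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    if (!is.null(x)) write.csv(x, file.path(dir, name), row.names = FALSE)
  }
  wr(analysis$screen, "screen.csv")
  wr(analysis$per_subject_rho, "per_subject_rho.csv")
  wr(analysis$gait_metrics, "gait_metrics.csv")
  wr(analysis$gait_comparisons, "gait_comparisons.csv")
  wr(analysis$task_scores, "task_scores.csv")
  writeFeatureCSV(analysis$features, file.path(dir, "features.csv"))
  lines <- c(
    "# Dual-task study analysis report", "",
    sprintf("- feature/context pairs screened in: %d of %d",
            sum(analysis$screen$passes_screen), nrow(analysis$screen)),
    sprintf("- significant after Friedman test (alpha = %g): %d",
            analysis$alpha, sum(analysis$screen$significant)))
  sig <- analysis$screen[analysis$screen$significant, ]
  if (nrow(sig) > 0) {
    lines <- c(lines, "", "## Significant monotone features", "")
    lines <- c(lines, sprintf(
      "- %s (%s, %s): rho = %+d, chi2 = %.2f, p = %.4g, W = %.2f (%s)",
      sig$feature, sig$setting, sig$task, as.integer(sig$rho), sig$chi2,
      sig$p_value, sig$kendalls_w, sig$effect_class))
  }
  if (!is.null(analysis$gait_comparisons)) {
    gc <- analysis$gait_comparisons[analysis$gait_comparisons$significant, ]
    lines <- c(lines, "", "## Significant gait contrasts", "",
               if (nrow(gc) > 0) sprintf("- %s / %s: p = %.4g",
                                         gc$comparison, gc$parameter,
                                         gc$p_value) else "- none")
  }
  writeLines(lines, file.path(dir, "report.md"))
  invisible(dir)
}
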