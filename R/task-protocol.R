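#' Create a graded cognitive task specification
#'
#' Returns the study defaults for one difficulty level of either task:
#' \describe{
#'   \item{Go/NoGo}{150 auditory stimuli; inter-trial distance 2.0 s at
#'     level 1 and 1.3 s at level 2, so the runs last 300 s and 195 s.
#'     Difficulty is scaled by shortening the interval.}
#'   \item{N-Back}{75 letter stimuli of 1.5 s each at both levels
#'     (about 113 s); difficulty is scaled by the load factor N = level.
#'     Scores are normalized on a 44-trial window.}
#' }
#'
#' @param task `"go_nogo"` or `"n_back"`.
#' @param level difficulty level, 1 or 2.
#' @param n_trials number of stimuli; defaults to 150 (Go/NoGo) or 75
#'   (N-Back).
#' @param target_fraction fraction of no-go trials (Go/NoGo) or of N-back
#'   match trials; default 0.30.
#' @param inter_trial_interval,trial_duration,load_factor overrides of the
#'   level defaults; rarely needed.
#' @param n_scored scoring denominator; defaults to `n_trials` for Go/NoGo
#'   and 44 for N-Back.
#' @return A [TaskSpec-class] object.
#' @examples
#' taskSpec("go_nogo", 2)
#' taskSpec("n_back", 1)
#' @export
taskSpec <- function(task = c("go_nogo", "n_back"), level = 1,
                     n_trials = NULL, target_fraction = 0.30,
                     inter_trial_interval = NULL, trial_duration = NULL,
                     load_factor = NULL, n_scored = NULL) {
  task <- match.arg(task)
  if (!level %in% 1:2) stop("'level' must be 1 or 2")
  if (task == "go_nogo") {
    n_trials <- if (is.null(n_trials)) 150L else as.integer(n_trials)
    iti <- if (is.null(inter_trial_interval)) c(2.0, 1.3)[level] else
      inter_trial_interval
    new("TaskSpec", taskName = task, level = as.integer(level),
        nTrials = n_trials, interTrialInterval = iti, trialDuration = iti,
        loadFactor = 0L, targetFraction = target_fraction,
        nScored = if (is.null(n_scored)) n_trials else as.integer(n_scored))
  } else {
    n_trials <- if (is.null(n_trials)) 75L else as.integer(n_trials)
    td <- if (is.null(trial_duration)) 1.5 else trial_duration
    nf <- if (is.null(load_factor)) as.integer(level) else
      as.integer(load_factor)
    if (nf >= n_trials) stop("load factor must be smaller than n_trials")
    ns <- if (is.null(n_scored)) min(44L, n_trials - nf) else
      as.integer(n_scored)
    new("TaskSpec", taskName = task, level = as.integer(level),
        nTrials = n_trials, interTrialInterval = td, trialDuration = td,
        loadFactor = nf, targetFraction = target_fraction, nScored = ns)
  }
}

# consonant alphabet for N-Back letter stimuli
.nback_tokens <- c("B", "D", "G", "K", "P", "Q", "T", "V")

#' Build a stimulus schedule
#'
#' Generates the ordered stimulus sequence for one task run. Onsets are
#' equally spaced at the task's inter-trial interval (Go/NoGo) or trial
#' duration (N-Back), starting at 0 s. The number of target trials (no-go
#' stimuli, or N-back matches among the eligible trials `N+1..n`) is fixed
#' to `round(target_fraction * n)` so the realized fraction is honored to
#' the nearest trial; their positions are randomized by `seed`.
#'
#' @param spec a [TaskSpec-class].
#' @param seed integer seed; schedules are reproducible per seed.
#' @return data.frame with columns `trial_index`, `onset_s`, `stimulus`
#'   (`"go"`/`"nogo"` or a letter token) and `is_target` (logical).
#' @examples
#' sch <- buildSchedule(taskSpec("go_nogo", 1), seed = 7)
#' head(sch)
#' range(diff(sch$onset_s))
#' @export
buildSchedule <- function(spec, seed) {
  stopifnot(is(spec, "TaskSpec"))
  validObject(spec)
  n <- spec@nTrials
  onsets <- (seq_len(n) - 1) * spec@interTrialInterval
  set.seed(as.integer(seed))
  if (spec@taskName == "go_nogo") {
    n_nogo <- round(spec@targetFraction * n)
    stim <- rep("go", n)
    stim[sample.int(n, n_nogo)] <- "nogo"
    data.frame(trial_index = seq_len(n), onset_s = onsets, stimulus = stim,
               is_target = stim == "nogo")
  } else {
    N <- spec@loadFactor
    eligible <- seq(N + 1, n)
    n_match <- round(spec@targetFraction * length(eligible))
    match_at <- sort(sample(eligible, n_match))
    tok <- character(n)
    tok[seq_len(N)] <- sample(.nback_tokens, N, replace = TRUE)
    for (i in eligible) {
      if (i %in% match_at) {
        tok[i] <- tok[i - N]
      } else {
        tok[i] <- sample(setdiff(.nback_tokens, tok[i - N]), 1)
      }
    }
    data.frame(trial_index = seq_len(n), onset_s = onsets, stimulus = tok,
               is_target = c(rep(FALSE, N), tok[eligible] == tok[eligible - N]))
  }
}

#' Total duration of a task run
#'
#' The run spans one full inter-trial interval (Go/NoGo) or trial duration
#' (N-Back) per stimulus: 150 x 2.0 s = 300 s for Go/NoGo level 1,
#' 150 x 1.3 s = 195 s for level 2, 75 x 1.5 s = 112.5 s for N-Back.
#'
#' @param schedule a schedule from [buildSchedule()].
#' @param spec the matching [TaskSpec-class].
#' @return duration in seconds.
#' @examples
#' sp <- taskSpec("go_nogo", 2)
#' scheduleDuration(buildSchedule(sp, 1), sp)
#' @export
scheduleDuration <- function(schedule, spec) {
  if (is.null(schedule) || nrow(schedule) == 0) stop("empty schedule")
  stopifnot(is(spec, "TaskSpec"))
  per_trial <- if (spec@taskName == "go_nogo") spec@interTrialInterval else
    spec@trialDuration
  nrow(schedule) * per_trial
}

#' Score a response log against a schedule
#'
#' A Go/NoGo trial is correct when the button was pressed on a go stimulus
#' or withheld on a no-go stimulus; an N-Back trial is correct when the
#' press matches the N-back identity of the letter tokens. Trials absent
#' from the log count as "not pressed". Go/NoGo scores all `n` trials;
#' N-Back scores the window of trials after the first N, truncated to the
#' configured denominator (default 44), and percentages are normalized on
#' that denominator.
#'
#' @param schedule a schedule from [buildSchedule()].
#' @param log data.frame with columns `trial_index` and `pressed`
#'   (logical); at most one row per trial.
#' @param spec the matching [TaskSpec-class].
#' @return list with `n_correct`, `n_scored` and `percent_correct`.
#' @examples
#' sp <- taskSpec("go_nogo", 1)
#' sch <- buildSchedule(sp, 1)
#' log <- data.frame(trial_index = sch$trial_index, pressed = !sch$is_target)
#' scoreResponses(sch, log, sp)$percent_correct
#' @export
scoreResponses <- function(schedule, log, spec) {
  stopifnot(is(spec, "TaskSpec"))
  if (anyDuplicated(log$trial_index)) {
    stop("duplicate trial_index in response log")
  }
  if (nrow(log) > 0 &&
      (any(log$trial_index < 1) || any(log$trial_index > nrow(schedule)))) {
    stop("response log references trials outside the schedule")
  }
  pressed <- rep(FALSE, nrow(schedule))
  pressed[log$trial_index] <- as.logical(log$pressed)
  if (spec@taskName == "go_nogo") {
    scored <- seq_len(nrow(schedule))
    correct <- ifelse(schedule$is_target[scored], !pressed[scored],
                      pressed[scored])
  } else {
    N <- spec@loadFactor
    scored <- seq(N + 1, nrow(schedule))
    scored <- scored[seq_len(min(spec@nScored, length(scored)))]
    correct <- pressed[scored] == schedule$is_target[scored]
  }
  n_scored <- spec@nScored
  n_correct <- sum(correct)
  list(n_correct = n_correct, n_scored = n_scored,
       percent_correct = 100 * n_correct / n_scored)
}

#' Simulate a response log
#'
#' Generates a plausible button-press log: every scored trial is answered
#' correctly with probability `accuracy`, independently.
#'
#' @param schedule a schedule from [buildSchedule()].
#' @param spec the matching [TaskSpec-class].
#' @param accuracy per-trial probability of a correct response.
#' @param seed integer seed.
#' @return data.frame with columns `trial_index`, `pressed`.
#' @export
simulateResponses <- function(schedule, spec, accuracy = 0.9, seed = 1) {
  stopifnot(is(spec, "TaskSpec"))
  set.seed(as.integer(seed))
  n <- nrow(schedule)
  correct <- runif(n) < accuracy
  ideal <- if (spec@taskName == "go_nogo") !schedule$is_target else
    schedule$is_target
  data.frame(trial_index = seq_len(n),
             pressed = ifelse(correct, ideal, !ideal))
}

#' Read and write schedules and response logs as TSV
#'
#' Schedules use columns `trial_index`, `onset_s`, `stimulus`, `is_target`;
#' response logs use `trial_index`, `pressed`.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `readScheduleTSV`/`readResponsesTSV` return a data.frame.
#' @export
writeScheduleTSV <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScheduleTSV
#' @export
readScheduleTSV <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  x$is_target <- as.logical(x$is_target)
  x
}

#' @rdname writeScheduleTSV
#' @export
writeResponsesTSV <- writeScheduleTSV

#' @rdname writeScheduleTSV
#' @export
readResponsesTSV <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  x$pressed <- as.logical(x$pressed)
  x
}
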