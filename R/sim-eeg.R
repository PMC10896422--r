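#' EEG simulation configuration
#'
#' Describes the generative model for synthetic EEG: a 1/f background plus
#' band-limited Gaussian components (one per generation band: delta,
#' theta, alpha, low beta, high beta, gamma), with component amplitudes
#' scaled per difficulty level at chosen channels, Poisson-arriving
#' transient burst artifacts, and a broadband noise gain for the walking
#' setting (the wireless dry-electrode signal degrades by about 10 dB
#' when the subject walks).
#'
#' The default `level_effects` inject the two headline modulations: delta
#' amplitude at Fz increasing with Go/NoGo difficulty (which raises both
#' absolute and relative delta power, the relative one being the
#' registered ground-truth effect), and high-beta amplitude at Fz
#' decreasing with N-Back difficulty. Level-1 factors must be 1: level 1
#' is the shared no-task baseline.
#'
#' @param sampling_rate sampling rate in Hz (> 90 so the gamma band is
#'   resolvable).
#' @param channels channel labels; default the eight-channel montage.
#' @param background list: `exponent` of the 1/f spectrum and `scale`
#'   (background RMS, uV).
#' @param band_amplitudes named numeric, RMS amplitude (uV) of each
#'   band-limited component.
#' @param level_effects data.frame with columns `task`, `channel`, `band`,
#'   `power_type`, `l1`, `l2`, `l3`: multiplicative amplitude factors per
#'   difficulty level. `power_type` records which feature the effect is
#'   expected to surface in (the ground-truth registry).
#' @param artifact_rate burst artifacts per minute.
#' @param artifact_amplitude burst amplitude as a multiple of the
#'   background RMS.
#' @param walking_noise_gain multiplier on the background amplitude in
#'   the walking setting; default `10^(10/20)` (+10 dB).
#' @param subject_sd standard deviation of the log-normal per-subject,
#'   per-band amplitude jitter.
#' @return list of class `eeg_sim_config`.
#' @examples
#' cfg <- eegSimConfig()
#' cfg$band_amplitudes
#' @export
eegSimConfig <- function(sampling_rate = 512,
                         channels = eegChannels(),
                         background = list(exponent = 1, scale = 5),
                         band_amplitudes = c(delta = 8, theta = 6,
                                             alpha = 10, low_beta = 5,
                                             high_beta = 4, gamma = 2),
                         level_effects = defaultLevelEffects(),
                         artifact_rate = 2,
                         artifact_amplitude = 20,
                         walking_noise_gain = 10^(10 / 20),
                         subject_sd = 0.2) {
  stopifnot(sampling_rate > 2 * 45, all(band_amplitudes >= 0),
            artifact_rate >= 0, artifact_amplitude >= 0)
  if (nrow(level_effects) > 0) {
    stopifnot(all(c("task", "channel", "band", "power_type",
                    "l1", "l2", "l3") %in% names(level_effects)))
    if (any(level_effects$l1 != 1)) {
      stop("level-1 factors must be 1 (level 1 is the shared baseline)")
    }
  }
  structure(list(sampling_rate = sampling_rate, channels = channels,
                 background = background, band_amplitudes = band_amplitudes,
                 level_effects = level_effects, artifact_rate = artifact_rate,
                 artifact_amplitude = artifact_amplitude,
                 walking_noise_gain = walking_noise_gain,
                 subject_sd = subject_sd),
            class = "eeg_sim_config")
}

#' @rdname eegSimConfig
#' @export
defaultLevelEffects <- function() {
  data.frame(
    task = c("go_nogo", "n_back"),
    channel = c("Fz", "Fz"),
    band = c("delta", "high_beta"),
    power_type = c("relative", "absolute"),
    l1 = c(1, 1), l2 = c(1.3, 0.85), l3 = c(1.6, 0.7)
  )
}

#' @rdname eegSimConfig
#' @export
nullLevelEffects <- function() {
  defaultLevelEffects()[0, ]
}

# generation bands (beta split so sub-band effects can be injected)
.gen_bands <- data.frame(
  band = c("delta", "theta", "alpha", "low_beta", "high_beta", "gamma"),
  low_hz = c(1, 4, 8, 13, 20, 30),
  high_hz = c(4, 8, 13, 20, 30, 45)
)

# 1/f^exponent noise via spectral synthesis, scaled to unit variance
.pink_noise <- function(n, exponent) {
  nf <- floor(n / 2)
  amp <- (seq_len(nf))^(-exponent / 2)
  ph <- runif(nf, 0, 2 * pi)
  half <- amp * exp(1i * ph)
  spec <- complex(n)
  spec[2:(nf + 1)] <- half
  spec[n:(n - nf + 2)] <- Conj(half[seq_len(nf - 1)])
  x <- Re(fft(spec, inverse = TRUE)) / n
  x / sd(x)
}

# band-limited Gaussian noise with unit variance: white noise through the
# module's own Butterworth bandpass (single causal pass)
.band_noise <- function(n, low, high, fs) {
  bf <- .butter_design(low, high, fs)
  x <- as.numeric(signal::filter(bf, rnorm(n + 2 * fs)))
  x <- x[(fs + 1):(fs + n)]   # drop the filter warm-up
  x / sd(x)
}

# amplitude factor for (task, channel, band) at a difficulty level
.level_factor <- function(cfg, task, channel, band, level) {
  le <- cfg$level_effects
  if (is.null(task) || nrow(le) == 0) return(1)
  i <- which(le$task == task & le$channel == channel & le$band == band)
  if (length(i) == 0) return(1)
  le[[paste0("l", level)]][i[1]]
}

#' Simulate one EEG recording
#'
#' Generates `duration` seconds of multichannel EEG as a 1/f background
#' plus independent band-limited Gaussian components per channel, each
#' component's amplitude scaled by the configured level effect for the
#' given task and difficulty level. Deterministic for a fixed seed.
#'
#' @param config an [eegSimConfig()].
#' @param level difficulty level in 1:3 (1 = no-task baseline).
#' @param duration recording length in seconds.
#' @param seed integer seed.
#' @param task task context the level effects refer to (`"go_nogo"` or
#'   `"n_back"`); `NULL` for a plain baseline.
#' @param setting `"sitting"` or `"walking"`; walking multiplies the
#'   background amplitude by `walking_noise_gain`.
#' @param band_gains optional named multiplier per generation band
#'   (per-subject jitter applied by [simulateStudy()]).
#' @return an [EEGRecording-class].
#' @examples
#' rec <- simulateEEGRecording(eegSimConfig(sampling_rate = 128),
#'                             level = 2, duration = 10, seed = 1)
#' rec
#' @export
simulateEEGRecording <- function(config, level, duration, seed,
                                 task = "go_nogo",
                                 setting = c("sitting", "walking"),
                                 band_gains = NULL) {
  stopifnot(inherits(config, "eeg_sim_config"), duration > 0,
            level %in% 1:3)
  setting <- match.arg(setting)
  fs <- config$sampling_rate
  n <- round(duration * fs)
  set.seed(as.integer(seed))
  bg_scale <- config$background$scale *
    if (setting == "walking") config$walking_noise_gain else 1
  chans <- config$channels
  X <- matrix(0, length(chans), n, dimnames = list(chans, NULL))
  for (ci in seq_along(chans)) {
    sig <- bg_scale * .pink_noise(n, config$background$exponent)
    for (bi in seq_len(nrow(.gen_bands))) {
      b <- .gen_bands$band[bi]
      amp <- config$band_amplitudes[[b]] *
        .level_factor(config, task, chans[ci], b, level) *
        (if (!is.null(band_gains)) band_gains[[b]] else 1)
      if (amp > 0) {
        sig <- sig + amp *
          .band_noise(n, .gen_bands$low_hz[bi], .gen_bands$high_hz[bi], fs)
      }
    }
    X[ci, ] <- sig
  }
  EEGRecording(X, fs)
}

#' Inject transient burst artifacts
#'
#' Adds Poisson-arriving bursts (0.2-0.5 s, Hann-enveloped broadband
#' noise of `artifact_amplitude` times the recording's background RMS) on
#' 1-3 randomly chosen channels each, and returns the burst intervals as
#' ground truth.
#'
#' @param rec an [EEGRecording-class].
#' @param config an [eegSimConfig()]; uses `artifact_rate` (bursts/min)
#'   and `artifact_amplitude`.
#' @param seed integer seed.
#' @return list with `recording` (the corrupted [EEGRecording-class]) and
#'   `bursts` (data.frame: `start_s`, `end_s`, `channels` as a
#'   comma-separated string; zero rows when `artifact_rate` is 0).
#' @examples
#' rec <- simulateEEGRecording(eegSimConfig(sampling_rate = 128), 1, 10, 1)
#' out <- injectArtifacts(rec, eegSimConfig(artifact_rate = 6), seed = 2)
#' nrow(out$bursts)
#' @export
injectArtifacts <- function(rec, config, seed) {
  stopifnot(is(rec, "EEGRecording"), config$artifact_rate >= 0)
  dur <- duration(rec)
  fs <- samplingRate(rec)
  set.seed(as.integer(seed))
  n_burst <- rpois(1, config$artifact_rate * dur / 60)
  X <- eegSamples(rec)
  base_rms <- median(sqrt(rowMeans(X^2)))
  bursts <- data.frame(start_s = numeric(0), end_s = numeric(0),
                       channels = character(0))
  if (n_burst > 0) {
    for (k in seq_len(n_burst)) {
      blen <- runif(1, 0.2, 0.5)
      bstart <- runif(1, 0, max(dur - blen, 0))
      chs <- sample(nrow(X), sample(1:3, 1))
      i0 <- floor(bstart * fs) + 1L
      i1 <- min(ncol(X), i0 + floor(blen * fs) - 1L)
      L <- i1 - i0 + 1L
      env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / L)
      for (ch in chs) {
        X[ch, i0:i1] <- X[ch, i0:i1] +
          config$artifact_amplitude * base_rms * env * rnorm(L)
      }
      bursts <- rbind(bursts, data.frame(
        start_s = (i0 - 1) / fs, end_s = i1 / fs,
        channels = paste(rownames(X)[chs], collapse = ",")))
    }
  }
  list(recording = EEGRecording(X, fs), bursts = bursts)
}
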