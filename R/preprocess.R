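#' EEG cleaner configuration
#'
#' Defaults follow the study pipeline: a fourth-order Butterworth bandpass
#' over 0.5-45 Hz applied forward-backward (zero phase), and a subspace
#' artifact remover with threshold multiplier 15 operating on 0.5 s
#' half-overlapping Hann windows.
#'
#' @param band numeric length-2, passband edges in Hz.
#' @param filter_order Butterworth design order.
#' @param asr_cutoff threshold multiplier on the robust spread of windowed
#'   component variances (unitless).
#' @param window_s analysis window length in seconds.
#' @param window_overlap overlap between consecutive windows, in (0, 1).
#' @return list of class `cleaner_config`.
#' @examples
#' cleanerConfig()
#' @export
cleanerConfig <- function(band = c(0.5, 45), filter_order = 4,
                          asr_cutoff = 15, window_s = 0.5,
                          window_overlap = 0.5) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2],
            asr_cutoff > 0, window_s > 0,
            window_overlap > 0, window_overlap < 1)
  structure(list(band = band, filter_order = filter_order,
                 asr_cutoff = asr_cutoff, window_s = window_s,
                 window_overlap = window_overlap),
            class = "cleaner_config")
}

# Zero-phase IIR filtering with steady-state initial conditions and
# odd-reflection padding, so constant offsets leave no edge transient.
.zerophase <- function(b, a, x) {
  m <- max(length(a), length(b)) - 1
  h1 <- sum(b) / sum(a)
  one_pass <- function(x) {
    as.numeric(signal::filter(filt = b, a = a, x = x,
                              init.x = rep(x[1], m),
                              init.y = rep(h1 * x[1], m)))
  }
  n <- length(x)
  npad <- min(48 * m, n - 1)
  xx <- c(2 * x[1] - x[(npad + 1):2], x,
          2 * x[n] - x[(n - 1):(n - npad)])
  y <- one_pass(xx)
  y <- rev(one_pass(rev(y)))
  y[(npad + 1):(npad + n)]
}

.butter_design <- function(low, high, fs, order = 4) {
  nyq <- fs / 2
  if (high >= nyq) stop("band edge at or above Nyquist frequency")
  signal::butter(order, c(low, high) / nyq, type = "pass")
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies the configured fourth-order Butterworth bandpass design forward
#' and backward over each channel, for zero phase distortion. Output
#' length equals input length. (Forward-backward application doubles the
#' effective order and squares the magnitude response.)
#'
#' @param rec an [EEGRecording-class].
#' @param cfg a [cleanerConfig()] list.
#' @return the filtered [EEGRecording-class].
#' @examples
#' x <- matrix(rnorm(8 * 1024), 8, dimnames = list(eegChannels(), NULL))
#' rec <- EEGRecording(x, 256)
#' filt <- bandpassFilter(rec)
#' @export
bandpassFilter <- function(rec, cfg = cleanerConfig()) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- samplingRate(rec)
  bf <- .butter_design(cfg$band[1], cfg$band[2], fs, cfg$filter_order)
  out <- t(apply(eegSamples(rec), 1, function(ch) .zerophase(bf$b, bf$a, ch)))
  rownames(out) <- channelLabels(rec)
  EEGRecording(out, fs)
}

#' Variance-threshold subspace artifact removal
#'
#' Removes transient high-variance activity the way the study pipeline
#' describes: the recording is decomposed into principal components
#' (directions from the whole-recording covariance); within sliding Hann
#' windows the variance of each component is measured; a per-component
#' threshold is set from the variance distribution over all windows
#' (median + `asr_cutoff` x 1.4826 x MAD); components exceeding their
#' threshold are discarded within that window; the signal is rebuilt from
#' the remaining components by weighted overlap-add.
#'
#' On artifact-free data no component crosses the threshold and the
#' reconstruction returns the input unchanged (to overlap-add rounding).
#' The outermost window at each end carries the zero-phase filter's edge
#' transient; those two windows are excluded from the threshold
#' calibration and passed through uncleaned.
#'
#' @param rec a bandpassed [EEGRecording-class].
#' @param cfg a [cleanerConfig()] list; `asr_cutoff` is the threshold
#'   multiplier (study default 15).
#' @return list with elements `recording` (cleaned [EEGRecording-class])
#'   and `report` (data.frame: `window`, `start_s`, `end_s`,
#'   `n_discarded`).
#' @examples
#' x <- matrix(rnorm(8 * 2048), 8, dimnames = list(eegChannels(), NULL))
#' cl <- asrClean(EEGRecording(x, 256))
#' sum(cl$report$n_discarded)
#' @export
asrClean <- function(rec, cfg = cleanerConfig()) {
  stopifnot(is(rec, "EEGRecording"))
  X <- eegSamples(rec)
  fs <- samplingRate(rec)
  L <- floor(cfg$window_s * fs)
  if (L > ncol(X)) stop("window longer than recording")
  if (ncol(X) < 10 * L) {
    stop("recording shorter than 10 analysis windows; cannot calibrate")
  }
  hop <- max(1L, floor(L * (1 - cfg$window_overlap)))
  starts <- seq(1L, ncol(X) - L + 1L, by = hop)
  if (starts[length(starts)] + L - 1L < ncol(X)) {
    starts <- c(starts, ncol(X) - L + 1L)
  }
  # fixed decomposition directions from the whole-recording covariance
  V <- eigen(tcrossprod(X) / ncol(X), symmetric = TRUE)$vectors
  Y <- crossprod(V, X)                       # components x time
  wvar <- vapply(starts, function(s) {
    rowMeans(Y[, s:(s + L - 1L), drop = FALSE]^2)
  }, numeric(nrow(X)))                       # components x windows
  # the outermost windows carry the zero-phase filter's edge transient;
  # they are excluded from calibration and passed through uncleaned
  edge <- c(1L, length(starts))
  interior <- setdiff(seq_along(starts), edge)
  ctr <- apply(wvar[, interior, drop = FALSE], 1, median)
  spr <- apply(wvar[, interior, drop = FALSE], 1, mad)   # 1.4826 x MAD
  thr <- ctr + cfg$asr_cutoff * spr
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / L)  # periodic Hann
  w <- pmax(w, 1e-12)
  acc <- matrix(0, nrow(X), ncol(X))
  den <- numeric(ncol(X))
  n_disc <- integer(length(starts))
  for (j in seq_along(starts)) {
    idx <- starts[j]:(starts[j] + L - 1L)
    Yw <- Y[, idx, drop = FALSE]
    bad <- if (j %in% edge) rep(FALSE, nrow(X)) else wvar[, j] > thr
    n_disc[j] <- sum(bad)
    if (any(bad)) Yw[bad, ] <- 0
    acc[, idx] <- acc[, idx] + (V %*% Yw) * rep(w, each = nrow(X))
    den[idx] <- den[idx] + w
  }
  out <- acc / rep(den, each = nrow(X))
  rownames(out) <- channelLabels(rec)
  list(recording = EEGRecording(out, fs),
       report = data.frame(window = seq_along(starts),
                           start_s = (starts - 1) / fs,
                           end_s = (starts - 1 + L) / fs,
                           n_discarded = n_disc))
}

#' Cut a recording into trial-locked epochs
#'
#' One epoch per stimulus onset, starting at the onset sample and spanning
#' `floor(epoch_duration * fs)` samples (all epochs equal length). Onsets
#' whose window runs past the end of the recording are dropped and listed
#' in the `dropped` slot.
#'
#' @param rec an [EEGRecording-class].
#' @param schedule a stimulus schedule ([buildSchedule()]) or a numeric
#'   vector of onset times in seconds.
#' @param epoch_duration epoch length in seconds.
#' @param condition optional condition label stored with the epochs.
#' @return an [EpochSet-class].
#' @examples
#' x <- matrix(rnorm(8 * 512 * 10), 8, dimnames = list(eegChannels(), NULL))
#' ep <- epochRecording(EEGRecording(x, 512), seq(0, 8, by = 2), 2)
#' nEpochs(ep)
#' @export
epochRecording <- function(rec, schedule, epoch_duration,
                           condition = NA_character_) {
  stopifnot(is(rec, "EEGRecording"), epoch_duration > 0)
  onsets <- if (is.data.frame(schedule)) schedule$onset_s else
    as.numeric(schedule)
  if (length(onsets) == 0) stop("empty schedule")
  fs <- samplingRate(rec)
  nsamp <- floor(epoch_duration * fs)
  start_idx <- floor(onsets * fs) + 1L
  ok <- start_idx >= 1L & (start_idx + nsamp - 1L) <= nSamples(rec)
  if (!any(ok)) stop("no epoch window fits inside the recording")
  X <- eegSamples(rec)
  keep <- which(ok)
  ep <- array(0, dim = c(length(keep), nrow(X), nsamp),
              dimnames = list(NULL, channelLabels(rec), NULL))
  for (i in seq_along(keep)) {
    s <- start_idx[keep[i]]
    ep[i, , ] <- X[, s:(s + nsamp - 1L)]
  }
  new("EpochSet", epochs = ep, samplingRate = fs,
      epochDuration = epoch_duration, onsets = onsets[keep],
      dropped = onsets[!ok], condition = condition)
}
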