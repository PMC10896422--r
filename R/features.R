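#' Canonical EEG frequency bands
#'
#' The seven bands of the feature set. The five canonical bands (delta,
#' theta, alpha, beta, gamma) tile 1-45 Hz without overlap; low beta and
#' high beta partition beta. Band intervals are half-open `[low, high)`
#' except gamma, which is closed at 45 Hz.
#'
#' @return data.frame with columns `band`, `low_hz`, `high_hz`.
#' @examples
#' eegBands()
#' @export
eegBands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "low_beta", "high_beta",
             "gamma"),
    low_hz = c(1, 4, 8, 13, 13, 20, 30),
    high_hz = c(4, 8, 13, 30, 20, 30, 45)
  )
}

.canonical_bands <- c("delta", "theta", "alpha", "beta", "gamma")

#' Welch power spectral density
#'
#' One-sided PSD by Welch's method: the signal is split into
#' `segment_s`-second segments with `overlap` fractional overlap, each
#' windowed (Hann by default) and periodogram-averaged. Scaling is such
#' that the integral of the density over frequency recovers the signal
#' variance (Parseval). With `window = "boxcar"` and a single full-length
#' segment the result is the raw periodogram.
#'
#' @param x numeric vector, or channels x samples matrix.
#' @param fs sampling rate in Hz.
#' @param segment_s segment length in seconds; default
#'   `min(1, length/fs)`.
#' @param overlap fractional overlap between segments.
#' @param window `"hann"` or `"boxcar"`.
#' @return list of class `eeg_spectrum`: `freq` (Hz grid) and `density`
#'   (channels x frequencies matrix, uV^2/Hz).
#' @examples
#' t <- seq(0, 10, by = 1 / 256)[-1]
#' sp <- psdWelch(sin(2 * pi * 10 * t), 256)
#' sp$freq[which.max(sp$density)]
#' @export
psdWelch <- function(x, fs, segment_s = NULL, overlap = 0.5,
                     window = c("hann", "boxcar")) {
  window <- match.arg(window)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (is.null(segment_s)) segment_s <- min(1, n / fs)
  nseg <- min(n, floor(segment_s * fs))
  if (nseg < 2) stop("epoch shorter than one Welch segment")
  hop <- max(1L, floor(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = hop)
  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1) / nseg)
  } else rep(1, nseg)
  scale <- 1 / (fs * sum(w^2))
  nfreq <- floor(nseg / 2) + 1L
  dens <- matrix(0, nrow(x), nfreq)
  for (s in starts) {
    seg <- x[, s:(s + nseg - 1L), drop = FALSE] * rep(w, each = nrow(x))
    ft <- t(apply(seg, 1, fft))
    if (nrow(x) == 1) ft <- matrix(ft, nrow = 1)
    p <- Mod(ft[, seq_len(nfreq), drop = FALSE])^2 * scale
    # fold the two-sided density onto one side (not DC; not Nyquist if even)
    dbl <- seq(2L, nfreq - (nseg %% 2L == 0L))
    p[, dbl] <- 2 * p[, dbl]
    dens <- dens + p
  }
  dens <- dens / length(starts)
  rownames(dens) <- rownames(x)
  structure(list(freq = (seq_len(nfreq) - 1L) * fs / nseg, density = dens),
            class = "eeg_spectrum")
}

# frequency-bin selector: [low, high), closed at the upper edge when the
# band (or the broadband denominator) ends at 45 Hz
.band_bins <- function(freq, low, high) {
  if (low < min(freq) - 1e-9 || high > max(freq) + 1e-9) {
    stop("band outside the spectral range")
  }
  if (high >= 45) freq >= low & freq <= high else freq >= low & freq < high
}

#' Absolute band power
#'
#' Integral of the spectral density over a frequency band: sum of density
#' times bin width over bins whose centre frequency falls in
#' `[low, high)` (gamma and the broadband total are closed at 45 Hz).
#'
#' @param spec an `eeg_spectrum` from [psdWelch()].
#' @param band band name from [eegBands()], or a numeric `c(low, high)`.
#' @return named numeric vector, one value per channel, in uV^2.
#' @examples
#' t <- seq(0, 10, by = 1 / 256)[-1]
#' bandPower(psdWelch(sin(2 * pi * 10 * t), 256), "alpha")
#' @export
bandPower <- function(spec, band) {
  stopifnot(inherits(spec, "eeg_spectrum"))
  if (is.character(band)) {
    bd <- eegBands()
    i <- match(band, bd$band)
    if (is.na(i)) stop("unknown band: ", band)
    lo <- bd$low_hz[i]; hi <- bd$high_hz[i]
  } else {
    lo <- band[1]; hi <- band[2]
  }
  df <- spec$freq[2] - spec$freq[1]
  sel <- .band_bins(spec$freq, lo, hi)
  rowSums(spec$density[, sel, drop = FALSE]) * df
}

#' Relative band power
#'
#' Band power expressed as a percentage of the broadband 1-45 Hz power,
#' so the five canonical bands sum to exactly 100.
#'
#' @inheritParams bandPower
#' @return named numeric vector of percentages per channel.
#' @export
relativePower <- function(spec, band) {
  total <- bandPower(spec, c(1, 45))
  if (any(total <= 0)) stop("zero total power; relative power undefined")
  100 * bandPower(spec, band) / total
}

# 112-value feature vector for one epoch (8 channels x 7 bands x 2 types)
.epoch_features <- function(epoch, fs, segment_s = NULL) {
  sp <- psdWelch(epoch, fs, segment_s = segment_s)
  bd <- eegBands()
  chans <- rownames(epoch)
  out <- numeric(0)
  for (type in c("absolute", "relative")) {
    for (b in bd$band) {
      v <- if (type == "absolute") bandPower(sp, b) else relativePower(sp, b)
      names(v) <- paste(chans, b, type, sep = "_")
      out <- c(out, v)
    }
  }
  out
}

#' Band-power features for one condition
#'
#' Computes the 112 band-power features (8 channels x 7 bands x
#' absolute/relative) for every epoch and averages them arithmetically
#' over epochs, the per-condition summary used by the screening stage.
#'
#' @param epochs an [EpochSet-class].
#' @param segment_s Welch segment length in seconds (default: up to 1 s,
#'   capped at the epoch length).
#' @return named numeric vector of 112 features
#'   (`<channel>_<band>_<absolute|relative>`).
#' @examples
#' x <- matrix(rnorm(8 * 512 * 8), 8, dimnames = list(eegChannels(), NULL))
#' ep <- epochRecording(EEGRecording(x, 512), seq(0, 6, 2), 2)
#' length(extractConditionFeatures(ep))
#' @export
extractConditionFeatures <- function(epochs, segment_s = NULL) {
  stopifnot(is(epochs, "EpochSet"))
  ne <- nEpochs(epochs)
  if (ne < 1) stop("empty epoch set")
  fs <- samplingRate(epochs)
  rows <- vapply(seq_len(ne), function(i) {
    e <- epochs@epochs[i, , , drop = TRUE]
    if (is.null(dim(e))) e <- matrix(e, nrow = dim(epochs@epochs)[2])
    rownames(e) <- channelLabels(epochs)
    .epoch_features(e, fs, segment_s)
  }, numeric(112))
  rowMeans(rows)
}

#' Assemble a FeatureTable
#'
#' Stacks per-condition feature vectors into a [FeatureTable-class]
#' (a `SummarizedExperiment` with features as rows).
#'
#' @param rows named list of 112-value feature vectors, or a matrix with
#'   one column per (subject, setting, condition) cell.
#' @param info data.frame with one row per cell: `subject`, `setting`,
#'   `condition`, `level` (difficulty level 1-3 within each task context,
#'   `NA` allowed).
#' @return a [FeatureTable-class].
#' @export
buildFeatureTable <- function(rows, info) {
  m <- if (is.list(rows)) do.call(cbind, rows) else rows
  stopifnot(nrow(m) == 112, nrow(info) == ncol(m))
  # parse <channel>_<band>_<type> against the known band names (band
  # names themselves contain underscores: low_beta, high_beta)
  ptype <- sub(".*_", "", rownames(m))
  rest <- sub("_[^_]+$", "", rownames(m))
  bands <- eegBands()$band[order(-nchar(eegBands()$band))]
  band <- vapply(rest, function(r) {
    hit <- bands[vapply(bands, function(b) endsWith(r, paste0("_", b)),
                        TRUE)]
    if (length(hit) == 0) stop("unparseable feature id: ", r)
    hit[1]
  }, "", USE.NAMES = FALSE)
  rd <- DataFrame(
    channel = substr(rest, 1, nchar(rest) - nchar(band) - 1),
    band = band,
    power_type = ptype
  )
  colnames(m) <- paste(info$subject, info$setting, info$condition, sep = ".")
  se <- SummarizedExperiment(assays = list(power = m), rowData = rd,
                             colData = DataFrame(info,
                                                 row.names = colnames(m)))
  new("FeatureTable", se)
}

# row name helper used throughout: channel_band_type
.feature_id <- function(channel, band, power_type) {
  paste(channel, band, power_type, sep = "_")
}

#' Write / read a feature table as tidy CSV
#'
#' Long format with one row per (subject, setting, condition, channel,
#' band, power_type) cell.
#'
#' @param ft a [FeatureTable-class].
#' @param path CSV file path.
#' @return `readFeatureCSV` returns a [FeatureTable-class].
#' @export
writeFeatureCSV <- function(ft, path) {
  stopifnot(is(ft, "FeatureTable"))
  m <- assay(ft, "power")
  rd <- as.data.frame(rowData(ft))
  cd <- as.data.frame(colData(ft))
  long <- do.call(rbind, lapply(seq_len(ncol(m)), function(j) {
    data.frame(cd[j, c("subject", "setting", "condition", "level")],
               rd, value = m[, j], row.names = NULL)
  }))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  long$feature <- .feature_id(long$channel, long$band, long$power_type)
  cells <- unique(long[, c("subject", "setting", "condition", "level")])
  feats <- unique(long$feature)
  m <- matrix(NA_real_, length(feats), nrow(cells),
              dimnames = list(feats, NULL))
  for (j in seq_len(nrow(cells))) {
    sel <- long$subject == cells$subject[j] &
      long$setting == cells$setting[j] &
      long$condition == cells$condition[j]
    m[long$feature[sel], j] <- long$value[sel]
  }
  buildFeatureTable(m, cells)
}
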