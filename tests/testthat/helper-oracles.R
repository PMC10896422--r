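# Exhaustive-enumeration oracles for the rank tests, independent of the
# stats:: implementations the package wraps.

# two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  list(statistic = v_obs, p_value = min(1, p))
}

# two-sided Mann-Whitney p by enumerating all group assignments
oracle_mann_whitney <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + n, m)
  u_all <- apply(idx, 2, function(i) sum(r[i]) - m * (m + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(statistic = u_obs, p_value = min(1, p))
}

# Friedman chi-square from first principles (tie-free matrices)
oracle_friedman_chi2 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  R <- colSums(t(apply(m, 1, rank)))
  12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
}

# Kendall's W directly from ranks (tie-free matrices)
oracle_kendalls_w <- function(m) {
  n <- nrow(m); k <- ncol(m)
  R <- colSums(t(apply(m, 1, rank)))
  S <- sum((R - n * (k + 1) / 2)^2)
  12 * S / (n^2 * k * (k^2 - 1))
}

# one-sided raw periodogram straight from the DFT
oracle_periodogram <- function(x, fs) {
  n <- length(x)
  nf <- floor(n / 2) + 1
  p <- Mod(fft(x)[seq_len(nf)])^2 / (fs * n)
  dbl <- seq(2, nf - (n %% 2 == 0))
  p[dbl] <- 2 * p[dbl]
  list(freq = (seq_len(nf) - 1) * fs / n, density = p)
}

# random tie-free sample helper
tie_free <- function(n, seed) {
  set.seed(seed)
  round(rnorm(n), 3) + seq_len(n) * 1e-6
}

# small multichannel test recording
toy_recording <- function(n_channels = 8, n = 2048, fs = 256, seed = 1,
                          sd = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n_channels * n, sd = sd), n_channels,
              dimnames = list(eegChannels()[seq_len(n_channels)], NULL))
  EEGRecording(x, fs)
}
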