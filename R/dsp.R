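#' Normalize amplitude to [-1, 1]
#'
#' Divides the signal by its maximum absolute value so the largest-magnitude
#' sample is exactly 1 (or -1).
#'
#' @param signal Numeric vector with at least one nonzero sample.
#' @return Numeric vector of the same length.
#' @export
normalize_amplitude <- function(signal) {
  m <- max(abs(signal))
  if (!is.finite(m) || m == 0) {
    stop("cannot normalize an all-zero (or non-finite) signal")
  }
  signal / m
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a low-pass Butterworth filter forward and backward
#' (zero-phase, magnitude response squared), passing DC at unit gain.
#'
#' @param signal Numeric vector.
#' @param rate Sampling rate in samples/second.
#' @param cutoff_hz Cutoff frequency in Hz (default 150).
#' @param order Filter order (default 2).
#' @return Filtered numeric vector of the same length.
#' @export
butterworth_lowpass <- function(signal, rate, cutoff_hz = 150, order = 2) {
  stopifnot_scalar_number(rate, "rate", lower = 1)
  if (cutoff_hz <= 0 || cutoff_hz >= rate / 2) {
    stop("`cutoff_hz` must lie in (0, rate/2)")
  }
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  as.numeric(signal::filtfilt(bf, as.numeric(signal)))
}

#' Hilbert envelope of a signal
#'
#' Magnitude of the analytic signal, computed with the frequency-domain
#' construction (positive frequencies doubled, negative zeroed).
#'
#' @param signal Numeric vector of length >= 2.
#' @param rate Sampling rate in samples/second.
#' @return An `envelope_signal`: list with nonnegative `values` and `rate`.
#' @export
hilbert_envelope <- function(signal, rate) {
  n <- length(signal)
  if (n < 2L) stop("signal must have length >= 2")
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  analytic <- stats::fft(stats::fft(as.numeric(signal)) * h, inverse = TRUE) / n
  envelope_signal(Mod(analytic), rate)
}

#' Envelope signal container
#'
#' @param values Nonnegative numeric vector.
#' @param rate Sampling rate in samples/second.
#' @return A list with class `envelope_signal`.
#' @export
envelope_signal <- function(values, rate) {
  values <- as.numeric(values)
  if (any(values < 0)) stop("envelope values must be nonnegative")
  structure(list(values = values, rate = rate), class = "envelope_signal")
}

env_values <- function(env) {
  if (inherits(env, "envelope_signal")) env$values else as.numeric(env)
}

#' Causal moving-average smoothing
#'
#' Convolution with a length-`window_size` window of ones divided by the
#' window size, applied causally with zero-padded history, so the output has
#' the input's length and `window_size = 1` is the identity.
#'
#' @param signal Numeric vector or an `envelope_signal`.
#' @param window_size Integer window size N >= 1 (default 70).
#' @return Same type as `signal`.
#' @export
smooth_moving_average <- function(signal, window_size = 70L) {
  if (!is.numeric(window_size) || length(window_size) != 1L || window_size < 1) {
    stop("`window_size` must be an integer >= 1")
  }
  N <- as.integer(window_size)
  v <- env_values(signal)
  if (N == 1L) {
    out <- v
  } else {
    cs <- cumsum(v)
    lag <- c(rep(0, N), cs[seq_len(max(0L, length(v) - N))])
    out <- (cs - lag) / N
  }
  if (inherits(signal, "envelope_signal")) {
    envelope_signal(pmax(out, 0), signal$rate)
  } else {
    out
  }
}

#' Envelope threshold: mean plus population standard deviation
#'
#' @param env Numeric vector or `envelope_signal`.
#' @return The threshold value.
#' @export
compute_threshold <- function(env) {
  v <- env_values(env)
  if (!length(v)) stop("empty envelope")
  mu <- mean(v)
  mu + sqrt(mean((v - mu)^2))
}

#' Detect fundamental-heart-sound boundaries by thresholding
#'
#' Marks envelope samples at or above the threshold as fundamental heart
#' sound (S1/S2) activity. Raw thresholding of noisy envelopes produces
#' ragged boundaries, so short gaps are filled and short runs removed.
#'
#' @param env An `envelope_signal` (or numeric vector with `rate` supplied).
#' @param thsh Threshold (>= 0), typically from [compute_threshold()].
#' @param min_run_s Runs of 1s shorter than this (seconds) are removed.
#' @param max_gap_s Gaps of 0s shorter than this (seconds) are filled first.
#' @param rate Sampling rate, required when `env` is a bare numeric vector.
#' @return Integer 0/1 mask of the envelope's length.
#' @export
detect_fhs_boundaries <- function(env, thsh, min_run_s = 0.02,
                                  max_gap_s = 0.01, rate = NULL) {
  if (thsh < 0) stop("`thsh` must be >= 0")
  v <- env_values(env)
  rate <- if (inherits(env, "envelope_signal")) env$rate else rate
  mask <- as.integer(v >= thsh)
  if (is.null(rate) || !any(mask == 1L) || all(mask == 1L)) return(mask)
  fill_n <- max(0L, as.integer(round(max_gap_s * rate)))
  drop_n <- max(0L, as.integer(round(min_run_s * rate)))
  r <- rle(mask)
  if (fill_n > 0L) {
    interior <- seq_along(r$values) > 1L & seq_along(r$values) < length(r$values)
    r$values[r$values == 0L & r$lengths < fill_n & interior] <- 1L
    r <- rle(inverse.rle(r))
  }
  if (drop_n > 0L) {
    r$values[r$values == 1L & r$lengths < drop_n] <- 0L
  }
  inverse.rle(r)
}

#' Split an envelope into FHS and murmur channels
#'
#' Partitions the envelope by the boundary mask: the FHS channel keeps
#' samples where the mask is 1 (S1/S2 activity), the murmur channel keeps
#' samples where it is 0 (systolic/diastolic noise). The two channels sum to
#' the envelope exactly.
#'
#' @param env An `envelope_signal` or numeric vector.
#' @param mask Integer 0/1 mask of the same length.
#' @return A list with numeric elements `fhs` and `murmur`.
#' @export
split_channels <- function(env, mask) {
  v <- env_values(env)
  if (length(v) != length(mask)) stop("envelope and mask lengths differ")
  list(fhs = v * mask, murmur = v * (1 - mask))
}

#' Mel scale
#'
#' `mel(f) = 2595 log10(1 + f/700)`, monotone increasing with `mel(0) = 0`.
#'
#' @param f_hz Frequency (Hz), nonnegative.
#' @return Mel value(s).
#' @export
mel_scale <- function(f_hz) {
  if (any(f_hz < 0)) stop("frequency must be nonnegative")
  2595 * log10(1 + f_hz / 700)
}

mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank
#'
#' `n_mels` triangular filters with centers equally spaced on the mel scale
#' between `fmin` and `fmax`, sampled at the FFT bin frequencies.
#'
#' @param n_mels Number of filters.
#' @param n_fft FFT size (window length).
#' @param rate Sampling rate in samples/second.
#' @param fmin,fmax Frequency range in Hz (defaults 0 and `rate/2`).
#' @return Matrix of shape `n_mels x (n_fft/2 + 1)`.
#' @export
mel_filterbank <- function(n_mels, n_fft, rate, fmin = 0, fmax = rate / 2) {
  n_bins <- n_fft %/% 2L + 1L
  bin_hz <- (seq_len(n_bins) - 1L) * rate / n_fft
  pts <- mel_to_hz(seq(mel_scale(fmin), mel_scale(fmax), length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- pts[m]; ce <- pts[m + 1L]; hi <- pts[m + 2L]
    up <- (bin_hz - lo) / (ce - lo)
    down <- (hi - bin_hz) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Log-mel spectrogram
#'
#' Short-time Fourier transform with a Hamming window (no end padding: frame
#' count is `1 + floor((length - window)/hop)`), power spectrum, triangular
#' mel filterbank, then conversion to decibels `10 log10(power/ref)` with a
#' small floor guarding the logarithm.
#'
#' @param signal Numeric vector, at least one window long.
#' @param cfg A [mel_config()].
#' @return Matrix of shape `n_mels x frames`, in dB.
#' @export
log_mel_spectrogram <- function(signal, cfg = mel_config()) {
  mel_power <- mel_power_spectrogram(signal, cfg)
  ref <- if (identical(cfg$ref_mode, "max")) max(mel_power) else cfg$ref_value
  10 * log10(mel_power / ref)
}

#' Mel power spectrogram (linear scale)
#'
#' The mel-filtered STFT power spectrogram underlying
#' [log_mel_spectrogram()], floored at `cfg$log_floor`, before dB conversion.
#'
#' @inheritParams log_mel_spectrogram
#' @return Matrix of shape `n_mels x frames` (linear power).
#' @export
mel_power_spectrogram <- function(signal, cfg = mel_config()) {
  x <- as.numeric(signal)
  win <- cfg$window
  if (length(x) < win) {
    stop("signal shorter than one analysis window (", win, " samples)")
  }
  hop <- cfg$hop
  n_frames <- 1L + (length(x) - win) %/% hop
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(win), starts, `+`)
  frames <- matrix(x[idx], nrow = win) * signal::hamming(win)
  spec <- stats::mvfft(frames)[seq_len(win %/% 2L + 1L), , drop = FALSE]
  power <- Mod(spec)^2
  fb <- mel_filterbank(cfg$n_mels, win, cfg$rate)
  pmax(fb %*% power, cfg$log_floor)
}

#' Mel spectrogram configuration
#'
#' @param window STFT window size in samples (default 512).
#' @param hop Hop length in samples (default 256; must be <= `window`).
#' @param n_mels Number of mel bands (default 140).
#' @param rate Sampling rate in samples/second (default 4000).
#' @param ref_mode Reference for dB conversion: `"max"` (per-signal maximum,
#'   so the global maximum is 0 dB) or `"fixed"` (use `ref_value`).
#' @param ref_value Fixed dB reference when `ref_mode = "fixed"`.
#' @param log_floor Small positive floor applied to mel power before the log.
#' @return A list with class `mel_config`.
#' @export
mel_config <- function(window = 512L, hop = 256L, n_mels = 140L, rate = 4000,
                       ref_mode = c("max", "fixed"), ref_value = 1,
                       log_floor = 1e-10) {
  ref_mode <- match.arg(ref_mode)
  if (hop > window) stop("`hop` must be <= `window`")
  if (n_mels < 1L) stop("`n_mels` must be >= 1")
  structure(
    list(window = as.integer(window), hop = as.integer(hop),
         n_mels = as.integer(n_mels), rate = rate, ref_mode = ref_mode,
         ref_value = ref_value, log_floor = log_floor),
    class = "mel_config"
  )
}

# local maxima indices of v (strict rise, non-strict fall to tolerate plateaus)
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] >= v[3:n]) + 1L
}

# topographic prominence of each candidate peak
peak_prominence <- function(v, peaks) {
  vapply(peaks, function(p) {
    h <- v[p]
    left <- if (p > 1L) {
      higher <- which(v[seq_len(p - 1L)] > h)
      lo <- if (length(higher)) max(higher) + 1L else 1L
      min(v[lo:p])
    } else h
    right <- if (p < length(v)) {
      idx <- (p + 1L):length(v)
      higher <- idx[v[idx] > h]
      hi <- if (length(higher)) min(higher) - 1L else length(v)
      min(v[p:hi])
    } else h
    h - max(left, right)
  }, numeric(1))
}

#' Mean interval between envelope peaks
#'
#' Detects prominent local maxima on the smoothed Hilbert envelope of the
#' signal and returns the mean spacing between successive peaks in seconds.
#' Peaks must have topographic prominence at least
#' `kappa * (max(envelope) - median(envelope))` and be at least
#' `min_spacing_s` apart (higher peaks win). When fewer than two peaks are
#' found, the signal duration is returned as a sentinel.
#'
#' The default spacing of 0.05 s is half the S1 burst duration: it merges
#' duplicate detections within one acoustic event but still admits separate
#' events inside a systole, which is what lets murmur activity shorten the
#' mean interval. Spacings near or above the S1-to-S2 gap (about 0.17-0.38 s
#' over 60-120 bpm) would suppress every intra-cycle peak and erase that
#' signal.
#'
#' Peak search runs on the envelope decimated to ~500 Hz; with smoothing and a
#' 0.2 s spacing floor this does not move peak times materially.
#'
#' @param signal Numeric vector.
#' @param rate Sampling rate in samples/second.
#' @param smooth_window Moving-average window (samples) applied to the
#'   envelope before peak search (default 70).
#' @param kappa Prominence factor (default 0.25).
#' @param min_spacing_s Minimum peak spacing in seconds (default 0.05).
#' @return Mean successive-peak interval in seconds (or the duration).
#' @export
mean_peak_interval <- function(signal, rate, smooth_window = 70L,
                               kappa = 0.25, min_spacing_s = 0.05) {
  if (length(signal) < 2L) stop("signal must have length >= 2")
  env <- hilbert_envelope(signal, rate)
  sm <- smooth_moving_average(env, smooth_window)$values
  dec <- max(1L, floor(rate / 500))
  v <- sm[seq(1L, length(sm), by = dec)]
  eff_rate <- rate / dec
  duration <- length(signal) / rate

  cand <- local_maxima(v)
  if (length(cand) < 2L) return(duration)
  prom <- peak_prominence(v, cand)
  keep <- cand[prom >= kappa * (max(v) - stats::median(v))]
  if (length(keep) < 2L) return(duration)
  # enforce minimum spacing, keeping higher peaks first
  ord <- keep[order(v[keep], decreasing = TRUE)]
  sel <- integer(0)
  min_gap <- min_spacing_s * eff_rate
  for (p in ord) {
    if (!length(sel) || all(abs(sel - p) >= min_gap)) sel <- c(sel, p)
  }
  sel <- sort(sel)
  if (length(sel) < 2L) return(duration)
  mean(diff(sel)) / eff_rate
}

#' Crop or tile a signal to a fixed duration
#'
#' Trims `trim` samples from both ends, then crops longer signals from the
#' start and cyclically tiles shorter ones, so the output has exactly
#' `round(sample_sec * rate)` samples.
#'
#' @param signal Numeric vector.
#' @param rate Sampling rate in samples/second.
#' @param sample_sec Target duration in seconds (default 50).
#' @param trim Samples removed from each end before cropping/tiling.
#' @return Numeric vector of length `round(sample_sec * rate)`.
#' @export
fix_duration <- function(signal, rate, sample_sec = 50, trim = 0L) {
  x <- as.numeric(signal)
  trim <- as.integer(trim)
  if (trim < 0L) stop("`trim` must be >= 0")
  if (2L * trim >= length(x)) stop("`trim` removes the whole signal")
  if (trim > 0L) x <- x[(trim + 1L):(length(x) - trim)]
  target <- as.integer(round(sample_sec * rate))
  if (target < 1L) stop("`sample_sec` too small")
  if (length(x) >= target) {
    x[seq_len(target)]
  } else {
    rep_len(x, target)
  }
}
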