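#' Feature combination
#'
#' Selects which channels and scalars the extractor produces. The spectrogram
#' channel is the log-mel of the normalized signal; the `s1s2`, `murmurs` and
#' `envelope` channels are log-mels of the corresponding envelope components
#' (FHS part, murmur part, whole envelope); each envelope-derived channel can
#' be computed from the moving-average-smoothed envelope instead (the
#' threshold and boundary mask then also derive from the smoothed envelope).
#' The `pi` flag attaches the scalar mean peak interval.
#'
#' `feature_id` selects one of the named combinations used throughout the
#' package (all include the spectrogram channel):
#' 1 = peak interval only; 3 = + S1S2 + murmurs; 4 = + S1S2; 5 = + murmurs;
#' 6 = + envelope; 7 = + smoothed S1S2 + smoothed murmurs; 8 = + smoothed
#' S1S2; 9 = + smoothed murmurs; 10 = + smoothed envelope; 11 = S1S2 +
#' murmurs without peak interval; 12 = smoothed murmurs without peak interval.
#' (Id 2, a demographic-feature variant, is not provided.)
#'
#' @param feature_id Optional integer id of a predefined combination.
#' @param spec,pi,s1s2,murmurs,envelope Logical channel/scalar flags.
#' @param smooth_s1s2,smooth_murmurs,smooth_envelope Logical: use the smoothed
#'   envelope for (and include) the respective channel.
#' @param trim Samples trimmed from both signal ends (default 0).
#' @param sample_sec Fixed analysis duration in seconds (default 50).
#' @return A list with class `feature_set`.
#' @export
feature_set <- function(feature_id = NULL, spec = TRUE, pi = TRUE,
                        s1s2 = FALSE, murmurs = FALSE, envelope = FALSE,
                        smooth_s1s2 = FALSE, smooth_murmurs = FALSE,
                        smooth_envelope = FALSE, trim = 0L, sample_sec = 50) {
  if (!is.null(feature_id)) {
    fid <- as.integer(feature_id)
    combos <- list(
      `1` = list(),
      `3` = list(s1s2 = TRUE, murmurs = TRUE),
      `4` = list(s1s2 = TRUE),
      `5` = list(murmurs = TRUE),
      `6` = list(envelope = TRUE),
      `7` = list(smooth_s1s2 = TRUE, smooth_murmurs = TRUE),
      `8` = list(smooth_s1s2 = TRUE),
      `9` = list(smooth_murmurs = TRUE),
      `10` = list(smooth_envelope = TRUE),
      `11` = list(s1s2 = TRUE, murmurs = TRUE, pi = FALSE),
      `12` = list(smooth_murmurs = TRUE, pi = FALSE)
    )
    if (fid == 2L) stop("feature id 2 (demographic variant) is not provided")
    co <- combos[[as.character(fid)]]
    if (is.null(co)) stop("unknown feature id: ", feature_id)
    spec <- TRUE; pi <- co$pi %||% TRUE
    s1s2 <- co$s1s2 %||% FALSE; murmurs <- co$murmurs %||% FALSE
    envelope <- co$envelope %||% FALSE
    smooth_s1s2 <- co$smooth_s1s2 %||% FALSE
    smooth_murmurs <- co$smooth_murmurs %||% FALSE
    smooth_envelope <- co$smooth_envelope %||% FALSE
  }
  if (!spec) stop("at least the spectrogram channel must be enabled")
  structure(
    list(feature_id = feature_id, spec = spec, pi = pi,
         s1s2 = s1s2 || smooth_s1s2,
         murmurs = murmurs || smooth_murmurs,
         envelope = envelope || smooth_envelope,
         smooth_s1s2 = smooth_s1s2, smooth_murmurs = smooth_murmurs,
         smooth_envelope = smooth_envelope,
         trim = as.integer(trim), sample_sec = sample_sec),
    class = "feature_set"
  )
}

#' Smoothing configuration
#'
#' @param window_size Moving-average window size N >= 1 (default 70).
#' @return A list with class `smoothing_config`.
#' @export
smoothing_config <- function(window_size = 70L) {
  if (window_size < 1) stop("`window_size` must be >= 1")
  structure(list(window_size = as.integer(window_size)),
            class = "smoothing_config")
}

#' Build the multi-channel feature tensor for one recording
#'
#' Pipeline: fix duration -> amplitude normalization -> Butterworth low-pass
#' -> Hilbert envelope -> (optional smoothing) -> mean+sd threshold ->
#' boundary mask -> FHS/murmur channel split -> log-mel spectrogram per
#' enabled channel. The spectrogram channel is the log-mel of the normalized
#' (unfiltered) signal. Channel order is fixed: `spec`, `s1s2`, `murmurs`,
#' `envelope` (enabled ones only). The mean peak interval is attached as a
#' scalar when requested.
#'
#' @param rec A [pcg_recording].
#' @param fs A [feature_set].
#' @param mel A [mel_config]; its `rate` is taken from the recording.
#' @param smoothing A [smoothing_config] for the smoothed channel variants
#'   (also used inside the peak-interval feature).
#' @param cutoff_hz,order Butterworth low-pass parameters.
#' @return A list with class `feature_tensor`: `channels` (array
#'   `n_mels x frames x n_channels`), `channel_names`, and `scalars`
#'   (named numeric).
#' @export
build_feature_tensor <- function(rec, fs = feature_set(feature_id = 9),
                                 mel = mel_config(),
                                 smoothing = smoothing_config(),
                                 cutoff_hz = 150, order = 2) {
  stopifnot(inherits(rec, "pcg_recording"))
  mel$rate <- rec$rate
  x <- fix_duration(rec$samples, rec$rate, sample_sec = fs$sample_sec,
                    trim = fs$trim)
  x <- normalize_amplitude(x)

  # mel powers per channel; dB conversion at the end against the recording's
  # global maximum so channel levels stay comparable across channels
  channels <- list(spec = mel_power_spectrogram(x, mel))

  need_env <- fs$s1s2 || fs$murmurs || fs$envelope
  if (need_env) {
    filtered <- butterworth_lowpass(x, rec$rate, cutoff_hz = cutoff_hz,
                                    order = order)
    env_raw <- hilbert_envelope(filtered, rec$rate)
    env_smooth <- NULL
    if (fs$smooth_s1s2 || fs$smooth_murmurs || fs$smooth_envelope) {
      env_smooth <- smooth_moving_average(env_raw, smoothing$window_size)
    }
    channel_env <- function(smoothed) if (smoothed) env_smooth else env_raw
    split_for <- function(smoothed) {
      e <- channel_env(smoothed)
      mask <- detect_fhs_boundaries(e, compute_threshold(e))
      split_channels(e, mask)
    }
    parts_raw <- if ((fs$s1s2 && !fs$smooth_s1s2) ||
                     (fs$murmurs && !fs$smooth_murmurs)) split_for(FALSE)
    parts_smooth <- if (fs$smooth_s1s2 || fs$smooth_murmurs) split_for(TRUE)
    if (fs$s1s2) {
      src <- if (fs$smooth_s1s2) parts_smooth else parts_raw
      channels$s1s2 <- mel_power_spectrogram(src$fhs, mel)
    }
    if (fs$murmurs) {
      src <- if (fs$smooth_murmurs) parts_smooth else parts_raw
      channels$murmurs <- mel_power_spectrogram(src$murmur, mel)
    }
    if (fs$envelope) {
      e <- channel_env(fs$smooth_envelope)
      channels$envelope <- mel_power_spectrogram(e$values, mel)
    }
  }
  ref <- if (identical(mel$ref_mode, "max")) {
    max(vapply(channels, max, numeric(1)))
  } else {
    mel$ref_value
  }
  channels <- lapply(channels, function(p) 10 * log10(p / ref))

  scalars <- numeric(0)
  if (fs$pi) {
    scalars <- c(mean_peak_interval = mean_peak_interval(
      x, rec$rate, smooth_window = smoothing$window_size))
  }
  arr <- array(unlist(channels, use.names = FALSE),
               dim = c(nrow(channels[[1]]), ncol(channels[[1]]),
                       length(channels)))
  structure(
    list(channels = arr, channel_names = names(channels), scalars = scalars),
    class = "feature_tensor"
  )
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("<feature_tensor> %d channel(s) [%s], %d mel bands x %d frames; scalars: %s\n",
              d[3], paste(x$channel_names, collapse = ", "), d[1], d[2],
              if (length(x$scalars)) paste(names(x$scalars), collapse = ", ") else "none"))
  invisible(x)
}
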