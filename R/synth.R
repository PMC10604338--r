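#' Specification for one synthetic PCG recording
#'
#' Describes the simulated cardiac cycle: S1 and S2 are raised-cosine
#' (Hann-windowed) tone bursts at ~80 and ~110 Hz laid out periodically with
#' per-cycle jitter; an optional murmur adds band-limited noise inside the
#' systolic and/or diastolic truth segments; white background noise is added to
#' meet a target SNR; the output is peak-normalized to 0.9.
#'
#' @param heart_rate_bpm Heart rate in beats/minute. `NULL` (default) draws
#'   one from Uniform(60, 120) with the seeded RNG.
#' @param n_seconds Recording duration in seconds.
#' @param rate Sampling rate in samples/second.
#' @param murmur One of `"none"`, `"systolic"`, `"diastolic"`, `"both"`.
#' @param murmur_amplitude Murmur noise RMS relative to the S1 peak amplitude.
#' @param murmur_band_hz Length-2 numeric, murmur noise band (low, high) in Hz.
#'   The default (60, 250) keeps substantial murmur energy below the 150 Hz
#'   analysis low-pass.
#' @param snr_db Signal-to-noise ratio of added white background noise, in dB;
#'   `Inf` adds none.
#' @param s1_duration_s,s2_duration_s Burst durations in seconds.
#' @param s2_offset_fraction S2 onset as a fraction of the cardiac cycle.
#' @param s1_freq_hz,s2_freq_hz Burst center frequencies in Hz.
#' @param s2_relative_amplitude S2 peak amplitude relative to S1.
#' @param cycle_jitter,amplitude_jitter Relative uniform jitter applied per
#'   cycle to the cycle length (±3%) and burst amplitudes (±10%).
#' @param seed Integer seed; the recording is deterministic given the spec.
#' @return A list with class `synth_spec`.
#' @export
synth_spec <- function(heart_rate_bpm = NULL,
                       n_seconds = 20,
                       rate = 4000,
                       murmur = c("none", "systolic", "diastolic", "both"),
                       murmur_amplitude = 0.4,
                       murmur_band_hz = c(60, 250),
                       snr_db = 25,
                       s1_duration_s = 0.10,
                       s2_duration_s = 0.08,
                       s2_offset_fraction = 0.35,
                       s1_freq_hz = 80,
                       s2_freq_hz = 110,
                       s2_relative_amplitude = 0.8,
                       cycle_jitter = 0.03,
                       amplitude_jitter = 0.10,
                       seed = 1L) {
  murmur <- match.arg(murmur)
  if (length(murmur_band_hz) != 2L || murmur_band_hz[1] >= murmur_band_hz[2]) {
    stop("`murmur_band_hz` must be (low, high) with low < high")
  }
  stopifnot_scalar_number(n_seconds, "n_seconds", lower = 1e-6)
  stopifnot_scalar_number(rate, "rate", lower = 1)
  if (!is.null(heart_rate_bpm)) {
    stopifnot_scalar_number(heart_rate_bpm, "heart_rate_bpm", lower = 1)
    if (n_seconds < 60 / heart_rate_bpm) {
      stop("recording must cover at least one cardiac cycle")
    }
  }
  structure(
    list(
      heart_rate_bpm = heart_rate_bpm, n_seconds = n_seconds, rate = rate,
      murmur = murmur, murmur_amplitude = murmur_amplitude,
      murmur_band_hz = murmur_band_hz, snr_db = snr_db,
      s1_duration_s = s1_duration_s, s2_duration_s = s2_duration_s,
      s2_offset_fraction = s2_offset_fraction,
      s1_freq_hz = s1_freq_hz, s2_freq_hz = s2_freq_hz,
      s2_relative_amplitude = s2_relative_amplitude,
      cycle_jitter = cycle_jitter, amplitude_jitter = amplitude_jitter,
      seed = as.integer(seed)
    ),
    class = "synth_spec"
  )
}

# Hann-windowed tone burst added in place
add_burst <- function(x, rate, t0, duration, freq, amplitude) {
  i0 <- floor(t0 * rate) + 1L
  n <- max(1L, round(duration * rate))
  i1 <- min(length(x), i0 + n - 1L)
  if (i0 > length(x)) return(x)
  idx <- i0:i1
  tt <- (seq_along(idx) - 1L) / rate
  win <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = length(idx))))
  x[idx] <- x[idx] + amplitude * win * sin(2 * pi * freq * tt)
  x
}

# zero-mean band-limited unit-RMS noise over the whole duration
band_noise <- function(n, rate, band) {
  w <- stats::rnorm(n)
  ny <- rate / 2
  bf <- signal::butter(2, c(band[1] / ny, band[2] / ny), type = "pass")
  v <- signal::filtfilt(bf, w)
  v / sqrt(mean(v^2))
}

#' Generate one synthetic PCG recording with ground truth
#'
#' @param spec A [synth_spec].
#' @param site Auscultation site label for the generated recording.
#' @param recording_id Identifier for the generated recording.
#' @return A list with class `synth_result`: `recording` ([pcg_recording]),
#'   `truth` ([segment_table] tiling each cycle S1, systole, S2, diastole),
#'   and `murmur_label` (`"Present"` or `"Absent"`).
#' @export
generate_recording <- function(spec = synth_spec(), site = "AV",
                               recording_id = "synthetic") {
  with_seed(spec$seed, {
    rate <- spec$rate
    n <- round(spec$n_seconds * rate)
    hr <- spec$heart_rate_bpm %||% stats::runif(1, 60, 120)
    cycle0 <- 60 / hr

    # cycle layout first, so layouts match across murmur settings at one seed
    starts <- numeric(0); cycles <- numeric(0)
    cur <- 0
    repeat {
      cyc <- cycle0 * (1 + stats::runif(1, -spec$cycle_jitter, spec$cycle_jitter))
      s2_end <- cur + spec$s2_offset_fraction * cyc + spec$s2_duration_s
      if (s2_end > spec$n_seconds) break
      starts <- c(starts, cur); cycles <- c(cycles, cyc)
      cur <- cur + cyc
    }
    if (!length(starts)) stop("recording too short for one cardiac cycle")
    amp1 <- 1 + stats::runif(length(starts), -spec$amplitude_jitter, spec$amplitude_jitter)
    amp2 <- spec$s2_relative_amplitude *
      (1 + stats::runif(length(starts), -spec$amplitude_jitter, spec$amplitude_jitter))

    x <- numeric(n)
    rows <- vector("list", length(starts))
    for (k in seq_along(starts)) {
      c0 <- starts[k]; cyc <- cycles[k]
      s1_end <- c0 + spec$s1_duration_s
      s2_start <- c0 + spec$s2_offset_fraction * cyc
      s2_end <- s2_start + spec$s2_duration_s
      dia_end <- min(c0 + cyc, spec$n_seconds)
      if (s1_end >= s2_start) stop("cycle too short for S1 + systole layout")
      x <- add_burst(x, rate, c0, spec$s1_duration_s, spec$s1_freq_hz, amp1[k])
      x <- add_burst(x, rate, s2_start, spec$s2_duration_s, spec$s2_freq_hz, amp2[k])
      rows[[k]] <- data.frame(
        start = c(c0, s1_end, s2_start, s2_end),
        end = c(s1_end, s2_start, s2_end, dia_end),
        label = c("S1", "systole", "S2", "diastole"),
        stringsAsFactors = FALSE
      )
    }
    truth_df <- do.call(rbind, rows)
    truth_df <- truth_df[truth_df$end > truth_df$start, ]
    truth <- segment_table(truth_df$start, truth_df$end, truth_df$label)

    if (spec$murmur != "none") {
      bank <- band_noise(n, rate, spec$murmur_band_hz)
      want <- c(
        if (spec$murmur %in% c("systolic", "both")) "systole",
        if (spec$murmur %in% c("diastolic", "both")) "diastole"
      )
      segs <- truth[truth$label %in% want, , drop = FALSE]
      for (r in seq_len(nrow(segs))) {
        i0 <- floor(segs$start[r] * rate) + 1L
        i1 <- min(n, floor(segs$end[r] * rate))
        if (i1 <= i0) next
        idx <- i0:i1
        m <- length(idx)
        ramp <- max(2L, min(round(0.01 * rate), floor(m / 4)))
        taper <- rep(1, m)
        up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
        taper[seq_len(ramp)] <- up
        taper[m + 1L - seq_len(ramp)] <- up
        x[idx] <- x[idx] + spec$murmur_amplitude * taper * bank[idx]
      }
    }

    if (is.finite(spec$snr_db)) {
      sig_pow <- mean(x^2)
      noise_sd <- sqrt(sig_pow / 10^(spec$snr_db / 10))
      x <- x + stats::rnorm(n, sd = noise_sd)
    }
    x <- 0.9 * x / max(abs(x))

    structure(
      list(
        recording = pcg_recording(x, rate, site = site, recording_id = recording_id),
        truth = truth,
        murmur_label = if (spec$murmur == "none") "Absent" else "Present"
      ),
      class = "synth_result"
    )
  })
}

#' Generate a synthetic PCG cohort on disk
#'
#' Writes, per patient, 1-4 site recordings (`<id>_<SITE>.wav`), ground-truth
#' segmentations (`<id>_<SITE>.tsv`), a metadata file (`<id>.txt`) and a
#' cohort-level `manifest.json`. All recordings of a patient share murmur
#' status and (approximately) heart rate. Murmur-present patients receive a
#' systolic murmur at the default amplitude; optional "Unknown" patients
#' receive a weak, ambiguous murmur.
#'
#' @param n_patients Number of patients (>= 1).
#' @param murmur_prevalence Probability that a patient is murmur-present.
#' @param sites_per_patient Integer range (e.g. `1:4`) from which the number of
#'   auscultation sites per patient is drawn.
#' @param seed Integer seed; the cohort (including the manifest) is
#'   deterministic given the seed.
#' @param out_dir Output directory (created if missing).
#' @param n_seconds Duration of each recording in seconds.
#' @param snr_db Background SNR passed to each recording.
#' @param unknown_fraction Fraction of patients relabeled "Unknown" (weak
#'   murmur), applied after the Present/Absent draw.
#' @param murmur_amplitude Murmur RMS (relative to S1 peak) for Present
#'   patients.
#' @return The manifest, invisibly: a list with `patients` (per-patient id,
#'   murmur label, file names) and generation parameters.
#' @export
generate_cohort <- function(n_patients, murmur_prevalence = 0.19,
                            sites_per_patient = 1:4, seed = 1L,
                            out_dir = tempfile("pcg_cohort_"),
                            n_seconds = 20, snr_db = 25,
                            unknown_fraction = 0,
                            murmur_amplitude = 0.4) {
  if (n_patients < 1L) stop("`n_patients` must be >= 1")
  stopifnot_scalar_number(murmur_prevalence, "murmur_prevalence", 0, 1)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  patients <- vector("list", n_patients)
  with_seed(seed, {
    for (i in seq_len(n_patients)) {
      pid <- sprintf("P%04d", i)
      lab <- if (stats::runif(1) < murmur_prevalence) "Present" else "Absent"
      if (unknown_fraction > 0 && stats::runif(1) < unknown_fraction) {
        lab <- "Unknown"
      }
      hr <- stats::runif(1, 60, 120)
      n_sites <- if (length(sites_per_patient) > 1L) {
        sample(sites_per_patient, 1L)
      } else {
        sites_per_patient
      }
      sites <- sample(c("AV", "PV", "TV", "MV"), n_sites)
      age <- sample(c("Neonate", "Infant", "Child", "Adolescent"), 1L)
      sex <- sample(c("Female", "Male"), 1L)
      files <- character(0)
      for (s in sites) {
        rseed <- draw_seed()
        sp <- synth_spec(
          heart_rate_bpm = hr * (1 + stats::runif(1, -0.05, 0.05)),
          n_seconds = n_seconds,
          murmur = if (lab == "Absent") "none" else "systolic",
          murmur_amplitude = if (lab == "Unknown") 0.15 else murmur_amplitude,
          snr_db = snr_db,
          seed = rseed
        )
        res <- generate_recording(sp, site = s,
                                  recording_id = sprintf("%s_%s", pid, s))
        wav <- sprintf("%s_%s.wav", pid, s)
        tsv <- sprintf("%s_%s.tsv", pid, s)
        write_wav(res$recording, file.path(out_dir, wav))
        write_segment_tsv(res$truth, file.path(out_dir, tsv))
        files <- c(files, wav)
      }
      rec <- patient_record(pid, lab,
                            demographics = list(Age = age, Sex = sex))
      write_patient_metadata(rec, file.path(out_dir, sprintf("%s.txt", pid)))
      patients[[i]] <- list(patient_id = pid, murmur = lab,
                            recordings = as.list(files))
    }
  })
  manifest <- list(
    dir = normalizePath(out_dir),
    n_patients = n_patients,
    murmur_prevalence = murmur_prevalence,
    seed = as.integer(seed),
    patients = patients
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort directory into patient records
#'
#' Scans `dir` for `<id>.txt` metadata files and attaches every matching
#' `<id>_<SITE>.wav` recording.
#'
#' @param dir Cohort directory, as written by [generate_cohort()].
#' @return A list of [patient_record] objects with audio attached.
#' @export
read_cohort <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(txts)) stop("no patient metadata files in ", dir)
  lapply(txts, function(txt) {
    rec <- read_patient_metadata(txt)
    wavs <- sort(list.files(
      dir,
      pattern = sprintf("^%s_[A-Za-z]+\\.wav$", rec$patient_id),
      full.names = TRUE
    ))
    rec$recordings <- lapply(wavs, read_wav)
    rec
  })
}
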