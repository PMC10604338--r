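#' PCG recording object
#'
#' Container for one auscultation recording: an amplitude vector, its sampling
#' rate and the auscultation site.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units).
#' @param rate Sampling rate in samples/second (positive; nominal 4000).
#' @param site Auscultation site, one of `"AV"`, `"PV"`, `"TV"`, `"MV"`,
#'   `"OTHER"` (aortic, pulmonic, tricuspid, mitral valve, or unspecified).
#' @param recording_id Identifier string.
#' @return An object of class `pcg_recording`.
#' @export
pcg_recording <- function(samples, rate, site = "OTHER", recording_id = "") {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop("`samples` must be a non-empty numeric vector")
  }
  stopifnot_scalar_number(rate, "rate", lower = 1)
  site <- toupper(as.character(site))
  if (!site %in% PCG_SITES) {
    stop("`site` must be one of ", paste(PCG_SITES, collapse = ", "))
  }
  structure(
    list(
      samples = as.numeric(samples),
      rate = as.integer(round(rate)),
      site = site,
      recording_id = as.character(recording_id)
    ),
    class = "pcg_recording"
  )
}

PCG_SITES <- c("AV", "PV", "TV", "MV", "OTHER")

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf(
    "<pcg_recording> %s  site=%s  %d samples @ %d Hz (%.2f s)\n",
    if (nzchar(x$recording_id)) x$recording_id else "(unnamed)",
    x$site, length(x$samples), x$rate, length(x$samples) / x$rate
  ))
  invisible(x)
}

# parse "<patient>_<SITE>.wav" -> site, else OTHER
site_from_filename <- function(path) {
  base <- sub("\\.wav$", "", basename(path), ignore.case = TRUE)
  m <- regmatches(base, regexec("^.+_([A-Za-z]+)$", base))[[1]]
  if (length(m) == 2L && toupper(m[2]) %in% c("AV", "PV", "TV", "MV")) {
    toupper(m[2])
  } else {
    "OTHER"
  }
}

#' Read a PCM WAV file as a PCG recording
#'
#' Reads a 16-bit PCM mono WAV file. Sample values are mapped to `[-1, 1)` by
#' dividing by 32768. The auscultation site is parsed from a
#' `<patient>_<SITE>.wav` filename suffix when present, else `"OTHER"`.
#'
#' @param path Path to a WAV file.
#' @return A [pcg_recording].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  readBin(con, "integer", 1L, size = 4L, endian = "little") # total size, unused
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || !nzchar(id)) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(sz) == 0L) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1L, size = 2L, endian = "little"),
        channels = readBin(body[3:4], "integer", 1L, size = 2L, endian = "little"),
        rate = readBin(body[5:8], "integer", 1L, size = 4L, endian = "little"),
        bits = readBin(body[15:16], "integer", 1L, size = 2L, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz) # skip unknown chunk
    }
    if (sz %% 2L == 1L) readBin(con, "raw", 1L) # chunk padding byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV (missing fmt/data chunk): ", path)
  }
  if (fmt$audio_format != 1L || fmt$bits != 16L) {
    stop("unsupported WAV format (need 16-bit PCM): ", path)
  }
  if (fmt$channels != 1L) {
    stop("multichannel WAV not supported (need mono): ", path)
  }
  ints <- readBin(data_raw, "integer", length(data_raw) %/% 2L,
                  size = 2L, signed = TRUE, endian = "little")
  if (length(ints) < 1L) stop("WAV contains no samples: ", path)
  pcg_recording(
    samples = ints / 32768,
    rate = fmt$rate,
    site = site_from_filename(path),
    recording_id = sub("\\.wav$", "", basename(path), ignore.case = TRUE)
  )
}

#' Write a PCG recording as a 16-bit PCM mono WAV file
#'
#' Amplitudes are clipped to `[-1, 1)` and quantized to 16 bits.
#'
#' @param x A [pcg_recording], or a numeric vector (then `rate` is required).
#' @param path Output path.
#' @param rate Sampling rate, used when `x` is a bare numeric vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, rate = NULL) {
  if (inherits(x, "pcg_recording")) {
    samples <- x$samples
    rate <- x$rate
  } else {
    if (is.null(rate)) stop("`rate` is required when `x` is a numeric vector")
    samples <- as.numeric(x)
  }
  rate <- as.integer(rate)
  ints <- as.integer(pmax(-32768, pmin(32767, round(samples * 32768))))
  n_bytes <- length(ints) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")              # PCM
  writeBin(1L, con, size = 2L, endian = "little")              # mono
  writeBin(rate, con, size = 4L, endian = "little")
  writeBin(rate * 2L, con, size = 4L, endian = "little")       # byte rate
  writeBin(2L, con, size = 2L, endian = "little")              # block align
  writeBin(16L, con, size = 2L, endian = "little")             # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(ints, con, size = 2L, endian = "little")
  invisible(path)
}
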