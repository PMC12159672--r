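# Audio substrate: clip container, PCM WAV I/O, spectrograms, band filtering,
# mean spectrum and amplitude envelope. All downstream indices consume these.

#' Construct an audio clip
#'
#' An `audio_clip` holds a mono waveform normalized to \[-1, 1\] together with
#' its sample rate and recording metadata (clip id, site, timestamp).
#'
#' @param samples Numeric vector of amplitudes in \[-1, 1\].
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param clip_id Optional clip identifier (defaults to `NA`).
#' @param site Optional site identifier.
#' @param timestamp Optional `POSIXct` recording start time.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate, clip_id = NA_character_,
                       site = NA_character_, timestamp = as.POSIXct(NA)) {
  if (length(samples) == 0L) stop("audio_clip: 'samples' must be non-empty")
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop("audio_clip: 'sample_rate' must be a positive number")
  }
  m <- max(abs(samples))
  if (is.na(m)) stop("audio_clip: samples contain NA")
  if (m > 1 + 1e-9) stop("audio_clip: samples exceed full scale [-1, 1]")
  structure(
    list(samples = as.numeric(samples), sample_rate = as.numeric(sample_rate),
         clip_id = clip_id, site = site, timestamp = timestamp),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %s: %.2f s @ %g Hz (site %s)\n",
              ifelse(is.na(x$clip_id), "<unnamed>", x$clip_id),
              length(x$samples) / x$sample_rate, x$sample_rate,
              ifelse(is.na(x$site), "?", x$site)))
  invisible(x)
}

#' Duration of a clip in seconds
#' @param clip An `audio_clip`.
#' @return Duration in seconds.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$sample_rate

#' Parse site and timestamp from a recording filename
#'
#' Recordings follow the convention `<site>_<YYYYMMDD>_<HHMMSS>.wav`. Files
#' not matching the convention yield `NA` fields.
#'
#' @param path File path or name.
#' @return List with `clip_id`, `site`, `timestamp`.
#' @export
parse_clip_filename <- function(path) {
  base <- tools::file_path_sans_ext(basename(path))
  m <- regmatches(base, regexec("^(.+)_([0-9]{8})_([0-9]{6})$", base))[[1]]
  if (length(m) == 4L) {
    ts <- as.POSIXct(paste0(m[2L + 1L], m[3L + 1L]), format = "%Y%m%d%H%M%S",
                     tz = "UTC")
    list(clip_id = base, site = m[2L], timestamp = ts)
  } else {
    list(clip_id = base, site = NA_character_, timestamp = as.POSIXct(NA))
  }
}

#' Read a PCM WAV file
#'
#' Reads 16-bit (or 8/32-bit integer) PCM WAV. Multi-channel files are reduced
#' to channel 1 with a warning. Samples are scaled to \[-1, 1\]. Site and
#' timestamp are parsed from the filename when it follows
#' `<site>_<YYYYMMDD>_<HHMMSS>.wav`.
#'
#' @param path Path to a WAV file.
#' @return An `audio_clip`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("read_wav: not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("read_wav: not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1L, 2L, endian = "little",
                               signed = FALSE),
        n_channels = readBin(con, "integer", 1L, 2L, endian = "little",
                             signed = FALSE),
        sample_rate = readBin(con, "integer", 1L, 4L, endian = "little"),
        byte_rate = readBin(con, "integer", 1L, 4L, endian = "little"),
        block_align = readBin(con, "integer", 1L, 2L, endian = "little",
                              signed = FALSE),
        bits = readBin(con, "integer", 1L, 2L, endian = "little",
                       signed = FALSE)
      )
      if (size > 16L) invisible(readBin(con, "raw", size - 16L))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("read_wav: missing fmt or data chunk in ", path)
  }
  if (fmt$audio_format != 1L) {
    stop("read_wav: only PCM (format 1) supported, got format ",
         fmt$audio_format)
  }
  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes
  x <- switch(as.character(fmt$bits),
    "8"  = (as.numeric(readBin(data_raw, "integer", n, 1L,
                               signed = FALSE)) - 128) / 128,
    "16" = readBin(data_raw, "integer", n, 2L, endian = "little") / 32768,
    "32" = readBin(data_raw, "integer", n, 4L, endian = "little") / 2147483648,
    stop("read_wav: unsupported bit depth ", fmt$bits)
  )
  if (fmt$n_channels > 1L) {
    warning("read_wav: ", fmt$n_channels,
            " channels found; using channel 1 only")
    x <- x[seq(1L, length(x), by = fmt$n_channels)]
  }
  meta <- parse_clip_filename(path)
  audio_clip(x, fmt$sample_rate, clip_id = meta$clip_id, site = meta$site,
             timestamp = meta$timestamp)
}

#' Write an audio clip as 16-bit PCM WAV
#'
#' @param clip An `audio_clip`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- pmax(pmin(clip$samples, 1), -1)
  ints <- as.integer(pmax(pmin(round(x * 32768), 32767), -32768))
  n_bytes <- length(ints) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")            # PCM
  writeBin(1L, con, 2L, endian = "little")            # mono
  writeBin(as.integer(clip$sample_rate), con, 4L, endian = "little")
  writeBin(as.integer(clip$sample_rate * 2L), con, 4L, endian = "little")
  writeBin(2L, con, 2L, endian = "little")            # block align
  writeBin(16L, con, 2L, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4L, endian = "little")
  writeBin(ints, con, 2L, endian = "little")
  invisible(path)
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

#' Magnitude spectrogram (short-time Fourier transform)
#'
#' Frames the waveform with a Hann window (no zero padding), takes the FFT of
#' each frame and keeps magnitudes for the `window_length / 2` bins from DC up
#' to (but excluding) the Nyquist frequency.
#'
#' @param clip An `audio_clip`.
#' @param window_length FFT window length in samples (default 512).
#' @param overlap Fractional window overlap in \[0, 1) (default 0).
#' @return A `spectrogram`: list with `amplitude` (bins x frames), `freq_axis`
#'   (Hz), `time_axis` (s, frame centres), `window_length`, `overlap`,
#'   `sample_rate`.
#' @export
compute_spectrogram <- function(clip, window_length = 512, overlap = 0) {
  stopifnot(inherits(clip, "audio_clip"))
  n <- length(clip$samples)
  if (window_length > n) {
    stop("compute_spectrogram: window_length (", window_length,
         ") exceeds clip length (", n, ")")
  }
  if (overlap < 0 || overlap >= 1) {
    stop("compute_spectrogram: overlap must be in [0, 1)")
  }
  hop <- max(1L, as.integer(round(window_length * (1 - overlap))))
  starts <- seq.int(1L, n - window_length + 1L, by = hop)
  w <- hann_window(window_length)
  idx <- outer(seq_len(window_length) - 1L, starts, "+")
  frames <- matrix(clip$samples[idx], nrow = window_length) * w
  spec <- Mod(stats::mvfft(frames))[seq_len(window_length %/% 2L), ,
                                    drop = FALSE]
  structure(
    list(amplitude = spec,
         freq_axis = (seq_len(window_length %/% 2L) - 1L) *
           clip$sample_rate / window_length,
         time_axis = (starts - 1L + window_length / 2) / clip$sample_rate,
         window_length = window_length, overlap = overlap,
         sample_rate = clip$sample_rate),
    class = "spectrogram"
  )
}

#' Band-pass filter by FFT-domain masking
#'
#' Zeroes all Fourier coefficients outside \[`f_low`, `f_high`\] and inverts,
#' giving a linear-phase brick-wall filter (unit passband gain, stopband
#' numerically nulled).
#'
#' @param clip An `audio_clip`.
#' @param f_low,f_high Band edges in Hz; `0 <= f_low < f_high <= Nyquist`.
#' @return The filtered `audio_clip`.
#' @export
bandpass_filter <- function(clip, f_low = 3000, f_high = 10000) {
  stopifnot(inherits(clip, "audio_clip"))
  nyq <- clip$sample_rate / 2
  if (!(f_low >= 0 && f_low < f_high && f_high <= nyq)) {
    stop("bandpass_filter: need 0 <= f_low < f_high <= ", nyq, " Hz")
  }
  n <- length(clip$samples)
  freqs <- (seq_len(n) - 1L) / n * clip$sample_rate
  freqs <- pmin(freqs, clip$sample_rate - freqs)  # fold to [0, Nyquist]
  mask <- freqs >= f_low & freqs <= f_high
  y <- Re(stats::fft(stats::fft(clip$samples) * mask, inverse = TRUE)) / n
  y <- pmax(pmin(y, 1), -1)
  out <- clip
  out$samples <- y
  out
}

mean_spectrum_of <- function(sp) {
  w <- hann_window(sp$window_length)
  m <- rowMeans(sp$amplitude) * 2 / sum(w)
  silent <- max(m) <= 0
  if (!silent) m <- m / max(m)
  list(freq = sp$freq_axis, amplitude = m, silent = silent)
}

#' Time-averaged mean spectrum
#'
#' Averages amplitude-corrected STFT magnitudes over time and normalizes the
#' result so that the maximum is 1. The amplitude correction divides by the
#' window mean so a full-scale sine maps to unit bin amplitude before
#' normalization.
#'
#' @param clip An `audio_clip`.
#' @param window_length FFT window length (default 512).
#' @param spec Optional precomputed `spectrogram` of `clip` (avoids
#'   recomputing the STFT).
#' @return List with `freq` (Hz), `amplitude` (max-normalized, or all zeros
#'   for silence) and `silent` flag.
#' @export
mean_spectrum <- function(clip, window_length = 512, spec = NULL) {
  if (is.null(spec)) {
    spec <- compute_spectrogram(clip, window_length = window_length)
  }
  mean_spectrum_of(spec)
}

# Band-limited analytic signal in one FFT pair: the real part is the
# brick-wall band-passed waveform, the modulus its amplitude envelope.
band_analytic <- function(clip, f_low, f_high) {
  n <- length(clip$samples)
  freqs <- (seq_len(n) - 1L) / n * clip$sample_rate
  pos <- freqs <= clip$sample_rate / 2
  folded <- pmin(freqs, clip$sample_rate - freqs)
  mask <- as.numeric(folded >= f_low & folded <= f_high)
  h <- ifelse(pos & freqs > 0 & freqs < clip$sample_rate / 2, 2,
              ifelse(pos, 1, 0))
  a <- stats::fft(stats::fft(clip$samples) * mask * h, inverse = TRUE) / n
  list(filtered = Re(a), envelope = Mod(a))
}

#' Amplitude envelope via the analytic signal
#'
#' Magnitude of the Hilbert analytic signal, same length as the input.
#'
#' @param clip An `audio_clip`.
#' @return Nonnegative numeric vector of the same length as the waveform.
#' @export
amplitude_envelope <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- clip$samples
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}
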