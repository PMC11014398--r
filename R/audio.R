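#' Construct an audio clip
#'
#' The basic waveform container used throughout the package: a numeric vector
#' of dimensionless amplitudes in `[-1, 1]` with a sample rate and a provenance
#' tag. Lengths always satisfy `length(samples) == round(duration * sample_rate)`.
#'
#' @param samples numeric vector of amplitudes; values are clamped-checked, not
#'   rescaled — out-of-range input is an error.
#' @param sample_rate integer sampling frequency in Hz.
#' @param kind one of `"speech"`, `"background"`, `"bird"`, `"soundscape"`,
#'   `"mixed"`.
#' @param seed integer seed the clip was generated from, or `NULL`.
#' @param meta optional named list of extra provenance fields (register,
#'   class_id, species_id, gain, ...).
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate, kind, seed = NULL, meta = list()) {
  if (!is.numeric(samples) || length(samples) < 1) {
    abort_invalid("audio_clip: samples must be a non-empty numeric vector")
  }
  if (!is_count(sample_rate) || sample_rate <= 0) {
    abort_invalid("audio_clip: sample_rate must be a positive integer")
  }
  kind <- match.arg(kind, c("speech", "background", "bird", "soundscape", "mixed"))
  if (max(abs(samples)) > 1 + 1e-12) {
    abort_invalid("audio_clip: samples outside [-1, 1]")
  }
  structure(
    list(samples = as.numeric(samples), sample_rate = as.integer(sample_rate),
         kind = kind, seed = if (is.null(seed)) NULL else as.integer(seed),
         meta = meta),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip %s: %.3f s @ %d Hz, peak %.3f, rms %.4f>\n",
              x$kind, length(x$samples) / x$sample_rate, x$sample_rate,
              max(abs(x$samples)), rms(x$samples)))
  invisible(x)
}

#' @export
length.audio_clip <- function(x) length(x$samples)

clip_duration <- function(clip) length(clip$samples) / clip$sample_rate

## ---- WAV I/O (16-bit PCM mono RIFF) -----------------------------------------
## No WAV package ships with this R stack, so the canonical-format reader and
## writer live here. Only the subset the pipeline emits is supported.

#' Write a clip as a 16-bit PCM mono WAV file
#'
#' @param clip an [audio_clip] (or bare numeric vector with `sample_rate`).
#' @param path output file path.
#' @param sample_rate required if `clip` is a bare vector.
#' @return `path`, invisibly.
#' @export
wav_write <- function(clip, path, sample_rate = NULL) {
  if (inherits(clip, "audio_clip")) {
    x <- clip$samples
    sr <- clip$sample_rate
  } else {
    if (is.null(sample_rate)) abort_invalid("wav_write: sample_rate required for bare vectors")
    x <- clip
    sr <- as.integer(sample_rate)
  }
  pcm <- as.integer(round(clamp(x) * 32767))
  n <- length(pcm)
  con <- tryCatch(file(path, "wb"), error = function(e) abort_io("wav_write: cannot open ", path))
  on.exit(close(con))
  data_bytes <- 2L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")      # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path WAV file path.
#' @param kind provenance tag to attach; defaults to `"mixed"`.
#' @return An [audio_clip].
#' @export
wav_read <- function(path, kind = "mixed") {
  if (!file.exists(path)) abort_io("wav_read: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort_io("wav_read: not a RIFF/WAVE file: ", path)
  }
  sr <- NA_integer_; bits <- NA_integer_; channels <- NA_integer_; fmt <- NA_integer_
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) abort_io("wav_read: no data chunk in ", path)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(id, "data")) {
      if (is.na(fmt)) abort_io("wav_read: data chunk before fmt chunk in ", path)
      if (fmt != 1L || bits != 16L || channels != 1L) {
        abort_io("wav_read: only 16-bit PCM mono supported (", path, ")")
      }
      pcm <- readBin(con, "integer", size / 2, size = 2, endian = "little", signed = TRUE)
      if (length(pcm) < size / 2) abort_io("wav_read: truncated data chunk in ", path)
      return(audio_clip(pcm / 32767, sr, kind = kind))
    } else {
      readBin(con, "raw", size + (size %% 2))
    }
  }
}

## ---- DSP helpers ------------------------------------------------------------

#' Band-limited resampling
#'
#' FFT-domain resampling (truncate or zero-pad the spectrum), the single
#' resampler used by the whole pipeline. Equivalent to classical band-limited
#' (sinc) interpolation on the periodic extension of the signal.
#'
#' @param x numeric vector.
#' @param from,to source and target sample rates in Hz.
#' @return Numeric vector of length `round(length(x) * to / from)`.
#' @export
resample_audio <- function(x, from, to) {
  if (from == to) return(x)
  n_in <- length(x)
  n_out <- round(n_in * to / from)
  X <- fft(x)
  Y <- complex(n_out)
  half <- min(n_in, n_out) %/% 2
  # DC + positive frequencies
  Y[seq_len(half + 1)] <- X[seq_len(half + 1)]
  # negative frequencies
  if (half > 1) {
    Y[n_out - seq_len(half - 1) + 1] <- X[n_in - seq_len(half - 1) + 1]
  }
  # split the Nyquist bin when downsampling onto an even-length grid
  if (n_out < n_in && n_out %% 2 == 0) {
    Y[half + 1] <- X[half + 1] + X[n_in - half + 1]
    Y[half + 1] <- Re(Y[half + 1]) / 2
  }
  Re(fft(Y, inverse = TRUE)) / n_in
}

# One-pole low-pass filter, cutoff in Hz (first-order IIR smoother).
lowpass1 <- function(x, cutoff_hz, sample_rate) {
  if (cutoff_hz >= sample_rate / 2) return(x)
  a <- exp(-2 * pi * cutoff_hz / sample_rate)
  as.numeric(stats::filter(x * (1 - a), filter = a, method = "recursive"))
}

# Two-pole resonator (formant-style peak) at centre frequency f with bandwidth bw.
resonator <- function(x, f, bw, sample_rate) {
  r <- exp(-pi * bw / sample_rate)
  theta <- 2 * pi * f / sample_rate
  g <- (1 - r^2) * sin(theta)  # approximate unit peak gain
  as.numeric(stats::filter(x * g, filter = c(2 * r * cos(theta), -r^2),
                           method = "recursive"))
}

# Power periodogram of a clip (one-sided), returned as data.frame(freq, power).
periodogram <- function(clip) {
  x <- if (inherits(clip, "audio_clip")) clip$samples else clip
  sr <- if (inherits(clip, "audio_clip")) clip$sample_rate else stop("need audio_clip")
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  k <- seq_len(n %/% 2 + 1)
  data.frame(freq = (k - 1) * sr / n, power = p[k])
}

# Fraction of periodogram power inside [lo, hi) Hz.
band_energy_fraction <- function(clip, lo, hi) {
  pg <- periodogram(clip)
  sum(pg$power[pg$freq >= lo & pg$freq < hi]) / sum(pg$power)
}

# Power-weighted mean frequency in Hz.
spectral_centroid <- function(clip) {
  pg <- periodogram(clip)
  sum(pg$freq * pg$power) / sum(pg$power)
}
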