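## Featurization: 3-s 16 kHz clips -> 128x128 normalized log-Mel grids.
## STFT: 1024-sample Hann window (64 ms), hop 512 (50% overlap), centred with
## reflection padding -> 94 frames; a 128-band Mel filterbank (0 Hz..Nyquist)
## compresses frequency; log(1 + S) compresses power; the time axis is then
## linearly interpolated to exactly 128 frames so the model input is square.

MEL_PARAMS <- list(sample_rate = 16000L, n_fft = 1024L, hop = 512L, n_mels = 128L,
                   n_frames = 128L)

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel filterbank matrix
#'
#' Triangular filters on the Mel scale spanning 0 Hz to Nyquist.
#'
#' @param n_mels number of bands.
#' @param n_fft FFT size (filters cover `n_fft/2 + 1` bins).
#' @param sample_rate sampling rate in Hz.
#' @return `n_mels x (n_fft/2 + 1)` matrix.
#' @export
mel_filterbank <- function(n_mels = 128, n_fft = 1024, sample_rate = 16000) {
  n_bins <- n_fft %/% 2 + 1
  fft_freqs <- (seq_len(n_bins) - 1) * sample_rate / n_fft
  mel_pts <- seq(hz_to_mel(0), hz_to_mel(sample_rate / 2), length.out = n_mels + 2)
  hz_pts <- mel_to_hz(mel_pts)
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ctr <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (fft_freqs - lo) / (ctr - lo)
    down <- (hi - fft_freqs) / (hi - ctr)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  attr(fb, "center_hz") <- hz_pts[2:(n_mels + 1)]
  fb
}

# Centred magnitude STFT with reflection padding and a Hann window.
stft_power <- function(x, n_fft = 1024, hop = 512) {
  half <- n_fft %/% 2
  # reflection padding (no repeated edge sample)
  left <- rev(x[2:(half + 1)])
  right <- rev(x[(length(x) - half):(length(x) - 1)])
  xp <- c(left, x, right)
  n_frames <- 1 + (length(xp) - n_fft) %/% hop
  starts <- (seq_len(n_frames) - 1) * hop
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_fft) - 1) / n_fft)  # periodic Hann
  frames <- vapply(starts, function(s) xp[(s + 1):(s + n_fft)] * win,
                   numeric(n_fft))
  sp <- stats::mvfft(frames)
  Mod(sp[seq_len(half + 1), , drop = FALSE])^2
}

# Linear interpolation of columns (time frames) to n_out frames.
interp_time <- function(grid, n_out) {
  n_in <- ncol(grid)
  if (n_in == n_out) return(grid)
  # endpoints aligned: frame centres mapped linearly
  pos <- seq(1, n_in, length.out = n_out)
  i0 <- floor(pos)
  i1 <- pmin(i0 + 1, n_in)
  w <- pos - i0
  grid[, i0, drop = FALSE] * rep(1 - w, each = nrow(grid)) +
    grid[, i1, drop = FALSE] * rep(w, each = nrow(grid))
}

#' Compute a 128 x 128 log-Mel spectrogram
#'
#' @param clip an [audio_clip] at 16 kHz with exactly 48,000 samples.
#' @return A `mel_spec`: list with `grid` (128 mel bins x 128 time frames),
#'   `params`, and `normalized = FALSE`.
#' @export
mel_spectrogram <- function(clip) {
  if (!inherits(clip, "audio_clip")) abort_invalid("mel_spectrogram: need an audio_clip")
  p <- MEL_PARAMS
  if (clip$sample_rate != p$sample_rate) {
    abort_invalid("mel_spectrogram: clip must be at ", p$sample_rate, " Hz")
  }
  if (length(clip$samples) != CLIP_SECONDS * p$sample_rate) {
    abort_invalid("mel_spectrogram: clip must have ", CLIP_SECONDS * p$sample_rate,
                  " samples, got ", length(clip$samples))
  }
  S <- stft_power(clip$samples, p$n_fft, p$hop)
  fb <- mel_filterbank(p$n_mels, p$n_fft, p$sample_rate)
  M <- log1p(fb %*% S)
  grid <- interp_time(M, p$n_frames)
  structure(list(grid = grid, params = p, normalized = FALSE), class = "mel_spec")
}

#' @export
print.mel_spec <- function(x, ...) {
  cat(sprintf("<mel_spec %dx%d, %s>\n", nrow(x$grid), ncol(x$grid),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Z-score each Mel bin along time
#'
#' Per-clip normalization: every one of the 128 mel-bin rows is centred and
#' scaled to unit standard deviation along the time axis (population sd).
#' Constant rows map to zeros. Normalizing twice is an error.
#'
#' @param spec a `mel_spec`.
#' @return The normalized `mel_spec`.
#' @export
normalize_per_bin <- function(spec) {
  if (!inherits(spec, "mel_spec")) abort_invalid("normalize_per_bin: need a mel_spec")
  if (isTRUE(spec$normalized)) abort_state("normalize_per_bin: spectrogram already normalized")
  g <- spec$grid
  mu <- rowMeans(g)
  centered <- g - mu
  sdev <- sqrt(rowMeans(centered^2))
  # rows that are constant up to floating-point noise map to zeros; the
  # threshold is relative so affine rescaling cannot flip a row's status
  near_const <- sdev < 1e-8 * pmax(1, abs(mu))
  scale <- ifelse(near_const, 0, 1 / pmax(sdev, 1e-300))
  spec$grid <- centered * scale
  spec$normalized <- TRUE
  spec
}

#' Featurize every record of a manifest into an archive
#'
#' Reads each WAV, computes the normalized 128x128 log-Mel grid, and stores
#' grids, labels and split tags (manifest order preserved) in a serialized
#' archive. The archive round-trips bit-identically.
#'
#' @param manifest a `dataset_manifest` (or data.frame with path/label/split).
#' @param outpath archive path (`.rds`); `NULL` keeps the archive in memory.
#' @return A `feature_archive`: list with `features`
#'   (array `[128 mel, 128 time, 1, n]`), `labels`, `split`, `paths`, `params`.
#' @export
featurize_manifest <- function(manifest, outpath = NULL) {
  rec <- if (inherits(manifest, "dataset_manifest")) manifest$records else manifest
  n <- nrow(rec)
  if (n == 0) abort_invalid("featurize_manifest: empty manifest")
  p <- MEL_PARAMS
  feats <- array(0, dim = c(p$n_mels, p$n_frames, 1L, n))
  for (i in seq_len(n)) {
    path <- rec$path[i]
    if (!file.exists(path)) abort_io("featurize_manifest: missing file: ", path)
    clip <- tryCatch(wav_read(path), error = function(e) {
      abort_io("featurize_manifest: failed to read record ", i, " (", path, "): ",
               conditionMessage(e))
    })
    spec <- normalize_per_bin(mel_spectrogram(clip))
    feats[, , 1L, i] <- spec$grid
  }
  archive <- structure(
    list(features = feats, labels = as.integer(rec$label),
         split = as.character(rec$split %||% rep("none", n)),
         paths = rec$path, params = p, version = 1L),
    class = "feature_archive")
  if (!is.null(outpath)) write_feature_archive(archive, outpath)
  archive
}

#' Write / read a feature archive
#'
#' Archives are stored with R's native serialization (version 3) — the
#' in-memory and on-disk grids are bit-identical.
#'
#' @param archive a `feature_archive`.
#' @param path archive file path.
#' @return `path` (write) or the `feature_archive` (read).
#' @export
write_feature_archive <- function(archive, path) {
  saveRDS(archive, path, version = 3)
  invisible(path)
}

#' @rdname write_feature_archive
#' @export
read_feature_archive <- function(path) {
  if (!file.exists(path)) abort_io("read_feature_archive: no such file: ", path)
  a <- readRDS(path)
  if (!inherits(a, "feature_archive")) abort_io("read_feature_archive: not a feature archive")
  a
}

#' @export
print.feature_archive <- function(x, ...) {
  cat(sprintf("<feature_archive: %d grids %dx%d, splits: %s>\n",
              dim(x$features)[4], dim(x$features)[1], dim(x$features)[2],
              paste(names(table(x$split)), table(x$split), sep = "=", collapse = " ")))
  invisible(x)
}

# Subset an archive by split tag.
archive_split <- function(archive, split) {
  idx <- which(archive$split == split)
  if (length(idx) == 0) abort_invalid("archive_split: no records in split '", split, "'")
  list(features = archive$features[, , , idx, drop = FALSE],
       labels = archive$labels[idx], idx = idx)
}
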