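## Dataset builder: segments ambient soundscapes into 3-s windows, mixes speech
## / background / bird events into them at controlled SNR, and emits a balanced
## labelled corpus of 16 kHz WAV clips plus a manifest, along with a
## playback-style evaluation set stratified by distance, voice type and
## environment. A pure function of (pools, config, seed).

CLIP_SECONDS <- 3
TARGET_RATE <- 16000L

#' Segment a soundscape into fixed-length clips
#'
#' Cuts non-overlapping consecutive `segment_s`-second windows (half-open
#' sample ranges, 0-based starts) from a clip, discarding any trailing
#' remainder, and resamples each window to `target_rate`. A clip shorter than
#' one window yields an empty list.
#'
#' @param clip an [audio_clip].
#' @param segment_s segment length in seconds (default 3).
#' @param target_rate output sampling rate in Hz (default 16000).
#' @return List of [audio_clip]s, each exactly `segment_s * target_rate`
#'   samples long.
#' @export
segment_soundscape <- function(clip, segment_s = CLIP_SECONDS, target_rate = TARGET_RATE) {
  if (!inherits(clip, "audio_clip")) abort_invalid("segment_soundscape: need an audio_clip")
  seg_in <- round(segment_s * clip$sample_rate)
  n_seg <- length(clip$samples) %/% seg_in
  if (n_seg == 0) return(list())
  lapply(seq_len(n_seg), function(i) {
    x <- clip$samples[((i - 1) * seg_in + 1):(i * seg_in)]
    y <- clamp(resample_audio(x, clip$sample_rate, target_rate))
    audio_clip(y, target_rate, clip$kind, seed = clip$seed,
               meta = c(clip$meta, list(segment = i)))
  })
}

#' Mix an event into a base clip at a target SNR
#'
#' Scales the event so that `10*log10(rms(event)^2 / rms(base)^2) = snr_db`,
#' places it at a random offset fully inside the base (events longer than the
#' base are randomly cropped to fit first), and sums. The mix is peak-normalized
#' only if the sum exceeds full scale.
#'
#' @param base,event [audio_clip]s at the same sample rate.
#' @param snr_db event-to-base SNR in dB.
#' @param seed optional integer seed for the placement offset; when `NULL` the
#'   current RNG stream is used.
#' @return An [audio_clip] of kind `"mixed"`, with the gain and offset recorded
#'   in `meta$components`.
#' @export
mix_at_snr <- function(base, event, snr_db, seed = NULL) {
  if (!inherits(base, "audio_clip") || !inherits(event, "audio_clip")) {
    abort_invalid("mix_at_snr: base and event must be audio_clips")
  }
  if (base$sample_rate != event$sample_rate) {
    abort_invalid("mix_at_snr: sample rates differ (", base$sample_rate, " vs ",
                  event$sample_rate, ")")
  }
  base_rms <- rms(base$samples)
  if (base_rms < 1e-12) abort_invalid("mix_at_snr: silent base (rms 0)")
  run <- function() {
    ev <- event$samples
    nb <- length(base$samples)
    if (length(ev) > nb) {
      start <- sample.int(length(ev) - nb + 1, 1)
      ev <- ev[start:(start + nb - 1)]
    }
    ev_rms <- rms(ev)
    if (ev_rms < 1e-12) abort_invalid("mix_at_snr: silent event (rms 0)")
    gain <- base_rms * db_to_amp(snr_db) / ev_rms
    offset <- if (length(ev) < nb) sample.int(nb - length(ev) + 1, 1) - 1L else 0L
    y <- base$samples
    idx <- offset + seq_along(ev)
    y[idx] <- y[idx] + ev * gain
    peak <- max(abs(y))
    if (peak > 1) y <- y / peak
    comp <- list(list(kind = event$kind, id = event$meta$class_id %||%
                        event$meta$species_id %||% event$meta$register %||% NA,
                      gain = gain, offset = offset, snr_db = snr_db))
    audio_clip(y, base$sample_rate, "mixed", seed = seed,
               meta = list(components = c(base$meta$components, comp)))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw one base segment (by index) and the per-clip event plan for a record.
components_string <- function(components) {
  if (is.null(components) || length(components) == 0) return("")
  paste(vapply(components, function(co) {
    sprintf("%s:%s:%.6g", co$kind, as.character(co$id), co$gain)
  }, character(1)), collapse = "|")
}

#' Build a balanced labelled mixing dataset
#'
#' The core preprocessing pipeline: every record takes a (resampled, 3-s)
#' soundscape segment as its base; label-1 records mix in exactly one speech
#' event at an SNR drawn uniformly from `snr_range_db` (plus, with probability
#' `p_extra`, one background or bird event); label-0 records mix in one or two
#' background/bird events only. Clips are written as 16 kHz 16-bit WAV files
#' and described in a manifest.
#'
#' @param pools a [build_fixture_pools()] result.
#' @param n_total total number of clips; `n_total * balance` must be integral.
#' @param balance fraction of label-1 (speech) clips, default 0.5.
#' @param snr_range_db uniform SNR range for speech events, default c(-6, 18).
#' @param seed integer seed; the builder is a pure function of
#'   (pools, config, seed).
#' @param outdir directory for WAVs and `manifest.csv`.
#' @param p_extra probability of one extra non-speech event in label-1 clips.
#' @param write_audio write WAV files (default TRUE); when FALSE only the
#'   manifest is produced (paths are still assigned) — used for dry runs.
#' @return A `dataset_manifest`: list with `records` (data.frame with columns
#'   path, label, split, snr_db, components, seed), `class_balance`, `outdir`.
#' @export
build_dataset <- function(pools, n_total = 20000, balance = 0.5,
                          snr_range_db = c(-6, 18), seed = 0, outdir,
                          p_extra = 0.5, write_audio = TRUE) {
  if (!inherits(pools, "fixture_pools")) abort_invalid("build_dataset: need fixture_pools")
  if (length(pools$speech) == 0 || (length(pools$background) + length(pools$bird)) == 0 ||
      length(pools$soundscape) == 0) {
    abort_invalid("build_dataset: empty pools")
  }
  n_pos <- n_total * balance
  if (abs(n_pos - round(n_pos)) > 1e-9) {
    abort_invalid("build_dataset: n_total * balance must be an integer")
  }
  n_pos <- as.integer(round(n_pos))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) abort_io("build_dataset: cannot create ", outdir)
  clip_dir <- file.path(outdir, "clips")
  if (write_audio) dir.create(clip_dir, showWarnings = FALSE)

  # segment + resample every soundscape once; reuse segments with replacement
  bases <- unlist(lapply(pools$soundscape, segment_soundscape), recursive = FALSE)
  if (length(bases) == 0) abort_invalid("build_dataset: soundscapes shorter than one segment")

  labels <- c(rep(1L, n_pos), rep(0L, n_total - n_pos))
  n_seg_samples <- CLIP_SECONDS * TARGET_RATE

  records <- with_seed(derive_seed(seed, "build_dataset"), {
    rows <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      base <- bases[[sample.int(length(bases), 1)]]
      lab <- labels[i]
      comps <- list()
      y <- base$samples
      add_event <- function(y, event, snr) {
        ev <- event$samples
        if (length(ev) > n_seg_samples) {
          st <- sample.int(length(ev) - n_seg_samples + 1, 1)
          ev <- ev[st:(st + n_seg_samples - 1)]
        }
        gain <- rms(base$samples) * db_to_amp(snr) / rms(ev)
        off <- if (length(ev) < n_seg_samples) sample.int(n_seg_samples - length(ev) + 1, 1) - 1L else 0L
        idx <- off + seq_along(ev)
        y[idx] <- y[idx] + ev * gain
        comps[[length(comps) + 1]] <<- list(
          kind = event$kind,
          id = event$meta$class_id %||% event$meta$species_id %||% event$meta$register %||% NA,
          gain = gain, snr_db = snr)
        y
      }
      snr <- NA_real_
      if (lab == 1L) {
        snr <- runif(1, snr_range_db[1], snr_range_db[2])
        sp <- pools$speech[[sample.int(length(pools$speech), 1)]]
        y <- add_event(y, sp, snr)
        if (runif(1) < p_extra) {
          ev <- sample_nonspeech(pools)
          y <- add_event(y, ev, runif(1, snr_range_db[1], snr_range_db[2]))
        }
      } else {
        for (k in seq_len(sample(1:2, 1))) {
          ev <- sample_nonspeech(pools)
          y <- add_event(y, ev, runif(1, snr_range_db[1], snr_range_db[2]))
        }
      }
      peak <- max(abs(y))
      if (peak > 1) y <- y / peak
      path <- file.path(clip_dir, sprintf("clip_%06d.wav", i))
      if (write_audio) wav_write(audio_clip(y, TARGET_RATE, "mixed"), path)
      rows[[i]] <- data.frame(path = path, label = lab, split = "none",
                              snr_db = snr, components = components_string(comps),
                              seed = seed, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  manifest <- structure(
    list(records = records, class_balance = mean(records$label), outdir = outdir),
    class = "dataset_manifest")
  write_manifest(manifest, file.path(outdir, "manifest.csv"))
  manifest
}

sample_nonspeech <- function(pools) {
  nb <- length(pools$background)
  nv <- length(pools$bird)
  j <- sample.int(nb + nv, 1)
  if (j <= nb) pools$background[[j]] else pools$bird[[j - nb]]
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest: %d records, balance %.3f, splits: %s>\n",
              nrow(x$records), x$class_balance,
              paste(names(table(x$records$split)), table(x$records$split),
                    sep = "=", collapse = " ")))
  invisible(x)
}

#' Write / read a dataset manifest CSV
#' @param manifest a `dataset_manifest`.
#' @param path CSV path.
#' @return `path` (write) or a `dataset_manifest` (read).
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest$records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  rec$split <- as.character(rec$split)
  rec$components <- as.character(rec$components)
  structure(list(records = rec, class_balance = mean(rec$label),
                 outdir = dirname(path)),
            class = "dataset_manifest")
}

#' Assign stratified train/validation/test splits
#'
#' Random split stratified by label: within each label the record count per
#' split is `round(n_label * ratio)` with any remainder assigned to train.
#'
#' @param manifest a `dataset_manifest`.
#' @param ratios length-3 numeric (train, val, test) summing to 1.
#' @param seed integer seed.
#' @return The manifest with the `split` column filled.
#' @export
split_dataset <- function(manifest, ratios = c(0.6, 0.2, 0.2), seed = 0) {
  if (length(ratios) != 3 || abs(sum(ratios) - 1) > 1e-9) {
    abort_invalid("split_dataset: ratios must be length 3 and sum to 1")
  }
  rec <- manifest$records
  rec$split <- NA_character_
  with_seed(derive_seed(seed, "split_dataset"), {
    for (lab in unique(rec$label)) {
      idx <- which(rec$label == lab)
      idx <- sample(idx)
      n <- length(idx)
      n_val <- round(n * ratios[2])
      n_test <- round(n * ratios[3])
      n_train <- n - n_val - n_test
      rec$split[idx] <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
    }
  })
  manifest$records <- rec
  if (!is.null(manifest$outdir) && dir.exists(manifest$outdir %||% "")) {
    write_manifest(manifest, file.path(manifest$outdir, "manifest.csv"))
  }
  manifest
}

#' Build a playback-style evaluation set
#'
#' Emulates a playback experiment: for every cell of
#' (distance, voice type, environment), `n_per_cell` speech clips are passed
#' through [apply_distance()] and summed over a 3-s environment bed, and
#' `n_per_cell` matched non-speech clips (background/bird events over the same
#' kind of bed) are produced. Voice proxies: male = low_pitch register,
#' female = high_pitch, child = raised-fundamental high register.
#'
#' @param pools a [build_fixture_pools()] result (used for non-speech events).
#' @param distances distances in metres (default `c(1, 5, 10, 20)`).
#' @param voice_types subset of `c("male", "female", "child")`.
#' @param environments subset of `c("forest", "grassland")`.
#' @param n_per_cell clips per (distance, voice, environment, label) cell.
#' @param seed integer seed.
#' @param outdir output directory for WAVs and `playback_manifest.csv`.
#' @return data.frame with columns path, label, distance_m, voice_type,
#'   environment, seed.
#' @export
build_playback_set <- function(pools, distances = c(1, 5, 10, 20),
                               voice_types = c("male", "female", "child"),
                               environments = c("forest", "grassland"),
                               n_per_cell = 5, seed = 0, outdir) {
  if (!is_count(n_per_cell) || n_per_cell < 1) abort_invalid("build_playback_set: n_per_cell >= 1")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  register_of <- c(male = "low_pitch", female = "high_pitch", child = "child")
  rows <- list()
  i <- 0
  for (env in environments) {
    bed_master <- synth_soundscape(20, TARGET_RATE, seed = derive_seed(seed, paste0("pb_bed_", env)),
                                   environment = env)
    bed_segs <- segment_soundscape(bed_master)
    for (d in distances) {
      for (vt in voice_types) {
        for (k in seq_len(n_per_cell)) {
          cell_seed <- derive_seed(seed, sprintf("pb_%s_%s_%s_%d", env, d, vt, k))
          out <- with_seed(cell_seed, {
            bed <- bed_segs[[sample.int(length(bed_segs), 1)]]
            sp <- synth_speech_like(CLIP_SECONDS, register_of[[vt]],
                                    seed = cell_seed)
            sp_d <- apply_distance(sp, d)
            y <- bed$samples + sp_d$samples
            if (max(abs(y)) > 1) y <- y / max(abs(y))
            pos <- y
            # matched non-speech clip: same bed population, event at same distance
            bed2 <- bed_segs[[sample.int(length(bed_segs), 1)]]
            ev <- sample_nonspeech(pools)
            ev16 <- if (ev$sample_rate == TARGET_RATE) ev else
              audio_clip(clamp(resample_audio(ev$samples, ev$sample_rate, TARGET_RATE)),
                         TARGET_RATE, ev$kind, meta = ev$meta)
            evl <- ev16$samples
            if (length(evl) > length(bed2$samples)) evl <- evl[seq_along(bed2$samples)]
            ev_d <- apply_distance(audio_clip(evl, TARGET_RATE, ev16$kind, meta = ev16$meta), d)
            y0 <- bed2$samples
            idx <- seq_along(ev_d$samples)
            y0[idx] <- y0[idx] + ev_d$samples
            if (max(abs(y0)) > 1) y0 <- y0 / max(abs(y0))
            list(pos = pos, neg = y0)
          })
          for (lab in c(1L, 0L)) {
            i <- i + 1
            path <- file.path(outdir, sprintf("pb_%05d.wav", i))
            wav_write(audio_clip(if (lab == 1L) out$pos else out$neg, TARGET_RATE, "mixed"),
                      path)
            rows[[i]] <- data.frame(path = path, label = lab, distance_m = d,
                                    voice_type = vt, environment = env,
                                    seed = cell_seed, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(outdir, "playback_manifest.csv"), row.names = FALSE)
  manifest
}
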