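## Synthetic audio pools standing in for the real corpora a field deployment
## would use: long ambient soundscapes, speech in two pitch registers (a
## male/female proxy, plus a raised-fundamental "child" extension), ~40 classes
## of environmental background textures, and frequency-modulated bird-like
## whistles. Parametric signal models, not perceptual synthesis: the goal is a
## learnable, spectrally separable detection task, generated deterministically
## from a seed.

f0_range_for_register <- function(register) {
  switch(register,
    low_pitch  = c(85, 180),
    high_pitch = c(165, 300),
    child      = c(235, 400),
    abort_invalid("unknown register: ", register)
  )
}

#' Generate a speech-like clip
#'
#' A harmonic stack on a slowly drifting fundamental, shaped by 2-3 resonant
#' (formant-like) filters and amplitude-modulated at a syllabic 2-8 Hz rate
#' with silent gaps. `low_pitch` draws the fundamental from 85-180 Hz,
#' `high_pitch` from 165-300 Hz; `"child"` (a raised-fundamental extension used
#' by the playback builder) from 235-400 Hz. Deterministic given `seed`.
#'
#' @param duration_s clip duration in seconds (> 0).
#' @param register `"low_pitch"`, `"high_pitch"`, or `"child"`.
#' @param seed integer seed.
#' @param sample_rate sampling rate in Hz (default 16000).
#' @return An [audio_clip] of kind `"speech"`.
#' @export
synth_speech_like <- function(duration_s, register = c("low_pitch", "high_pitch", "child"),
                              seed = 0, sample_rate = 16000) {
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0) {
    abort_invalid("synth_speech_like: duration_s must be > 0")
  }
  register <- match.arg(register)
  n <- round(duration_s * sample_rate)
  x <- with_seed(derive_seed(seed, paste0("speech_", register)), {
    t <- seq_len(n) / sample_rate
    f0r <- f0_range_for_register(register)
    f0_base <- runif(1, f0r[1], f0r[2])
    # smooth +-8% pitch drift: low-pass filtered noise
    drift <- lowpass1(rnorm(n), 1.5, sample_rate)
    drift <- drift / max(abs(drift), 1e-12) * 0.08
    f0 <- f0_base * (1 + drift)
    phase <- cumsum(2 * pi * f0 / sample_rate)
    n_harm <- max(3, floor((sample_rate / 2 - 200) / f0_base))
    n_harm <- min(n_harm, 40)
    voiced <- numeric(n)
    for (h in seq_len(n_harm)) {
      hp <- h * phase
      if (max(f0) * h >= sample_rate / 2) break
      voiced <- voiced + sin(hp + runif(1, 0, 2 * pi)) / h
    }
    # 2-3 formant-like resonances; kept low so the fundamental region dominates
    n_form <- sample(2:3, 1)
    centers <- sort(runif(n_form, 350, 2600))
    shaped <- voiced
    for (fc in centers) {
      shaped <- shaped + 0.6 * resonator(voiced, fc, bw = 120 + fc / 8, sample_rate)
    }
    # syllabic amplitude modulation with silent gaps
    f_syl <- runif(1, 2, 8)
    env <- (0.5 + 0.5 * sin(2 * pi * f_syl * t + runif(1, 0, 2 * pi)))^1.5
    gate <- lowpass1(as.numeric(env > 0.12), 20, sample_rate)
    y <- shaped * env * pmax(gate, 0)
    y / max(abs(y), 1e-12) * 0.9
  })
  audio_clip(x, sample_rate, "speech", seed = seed, meta = list(register = register))
}

#' Generate an environmental-background clip
#'
#' Class-dependent noise texture: every class has its own spectral slope
#' (white through deep red), and even-numbered classes add impulsive events
#' (click/burst trains) on top. Default duration 5 s, matching the 5-second
#' source intervals the pool emulates.
#'
#' @param duration_s clip duration in seconds.
#' @param class_id integer class label in `1..n_classes`.
#' @param seed integer seed.
#' @param n_classes size of the class inventory (default 40).
#' @param sample_rate sampling rate in Hz.
#' @return An [audio_clip] of kind `"background"`.
#' @export
synth_background <- function(duration_s = 5, class_id, seed = 0, n_classes = 40,
                             sample_rate = 16000) {
  if (!is.numeric(duration_s) || duration_s <= 0) abort_invalid("synth_background: duration_s must be > 0")
  if (!is_count(class_id) || class_id < 1 || class_id > n_classes) {
    abort_invalid("synth_background: class_id ", class_id, " outside 1..", n_classes)
  }
  n <- round(duration_s * sample_rate)
  x <- with_seed(derive_seed(seed, paste0("background_", class_id)), {
    # spectral slope beta in [-2.2, 0.6], deterministic in class_id
    beta <- -2.2 + 2.8 * ((class_id - 1) %% n_classes) / max(1, n_classes - 1)
    y <- colored_noise(n, beta, sample_rate)
    if (class_id %% 2 == 0) {
      # impulsive event train: short decaying bursts at random instants
      k <- sample(3:10, 1)
      at <- sort(sample.int(n - round(0.05 * sample_rate), k))
      burst_len <- round(0.03 * sample_rate)
      burst_env <- exp(-seq_len(burst_len) / (burst_len / 4))
      for (a in at) {
        idx <- a + seq_len(burst_len) - 1
        y[idx] <- y[idx] + rnorm(burst_len) * burst_env * 2.5
      }
    }
    y / max(abs(y), 1e-12) * 0.8
  })
  audio_clip(x, sample_rate, "background", seed = seed,
             meta = list(class_id = as.integer(class_id)))
}

# Gaussian noise with power spectrum |f|^beta, generated in the FFT domain.
colored_noise <- function(n, beta, sample_rate) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))                    # avoid 0 at DC
  f <- pmin(f, n - f + 1)                       # mirror for negative freqs
  shape <- (f / max(f))^(beta / 2)
  Re(fft(W * shape, inverse = TRUE)) / n
}

#' Generate a bird-like clip
#'
#' Bouts of frequency-modulated whistles/chirps in the 2-8 kHz band. The FM
#' pattern (base frequency, sweep direction and depth, chirp length) is a
#' deterministic function of `species_id`; placement jitter comes from `seed`.
#'
#' @param duration_s clip duration in seconds (> 0).
#' @param species_id integer species label.
#' @param seed integer seed.
#' @param sample_rate sampling rate in Hz.
#' @return An [audio_clip] of kind `"bird"`.
#' @export
synth_bird_like <- function(duration_s, species_id, seed = 0, sample_rate = 16000) {
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0) {
    abort_invalid("synth_bird_like: duration_s must be > 0")
  }
  if (!is_count(species_id) || species_id < 1) abort_invalid("synth_bird_like: bad species_id")
  n <- round(duration_s * sample_rate)
  x <- with_seed(derive_seed(seed, paste0("bird_", species_id)), {
    # species-determined FM signature
    base_f <- 2500 + (species_id * 997) %% 4000          # 2.5-6.5 kHz
    sweep <- (if (species_id %% 2 == 0) 1 else -1) * (400 + (species_id * 131) %% 1200)
    chirp_s <- 0.05 + ((species_id * 37) %% 100) / 1000   # 50-150 ms
    y <- numeric(n)
    n_chirp <- max(1, round(duration_s * runif(1, 2, 6)))
    clen <- round(chirp_s * sample_rate)
    for (i in seq_len(n_chirp)) {
      if (clen + 1 >= n) break
      a <- sample.int(n - clen, 1)
      tt <- seq_len(clen) / sample_rate
      f_inst <- base_f + sweep * tt / chirp_s + runif(1, -150, 150)
      f_inst <- pmin(pmax(f_inst, 2100), 7800)
      ph <- cumsum(2 * pi * f_inst / sample_rate)
      env <- sin(pi * seq_len(clen) / clen)^2
      y[a + seq_len(clen) - 1] <- y[a + seq_len(clen) - 1] + sin(ph) * env
    }
    if (max(abs(y)) < 1e-9) {                            # ensure at least one chirp
      tt <- seq_len(min(clen, n)) / sample_rate
      ph <- cumsum(2 * pi * pmin(pmax(base_f + sweep * tt / chirp_s, 2100), 7800) / sample_rate)
      y[seq_along(ph)] <- sin(ph) * sin(pi * seq_along(ph) / length(ph))^2
    }
    y / max(abs(y), 1e-12) * 0.85
  })
  audio_clip(x, sample_rate, "bird", seed = seed,
             meta = list(species_id = as.integer(species_id)))
}

#' Generate an ambient soundscape bed
#'
#' A low-level wind/rain-like colored-noise bed with slow amplitude
#' modulation and occasional faint distant events. Defaults mirror the source
#' recordings this pool emulates: 55 s at 44.1 kHz. The `environment` argument
#' selects a spectral tilt: `"forest"` is redder (wind through canopy),
#' `"grassland"` flatter with stronger broadband gusts.
#'
#' @param duration_s duration in seconds (default 55).
#' @param sample_rate sampling rate in Hz (default 44100).
#' @param seed integer seed.
#' @param environment `"forest"` or `"grassland"`.
#' @return An [audio_clip] of kind `"soundscape"`.
#' @export
synth_soundscape <- function(duration_s = 55, sample_rate = 44100, seed = 0,
                             environment = c("forest", "grassland")) {
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0) {
    abort_invalid("synth_soundscape: duration_s must be > 0")
  }
  environment <- match.arg(environment)
  n <- round(duration_s * sample_rate)
  x <- with_seed(derive_seed(seed, paste0("soundscape_", environment)), {
    beta <- if (environment == "forest") -1.8 else -1.1
    bed <- colored_noise(n, beta, sample_rate)
    # slow gusting: 0.1-0.5 Hz amplitude modulation
    gust <- lowpass1(rnorm(n), 0.3, sample_rate)
    gust <- 1 + 0.5 * gust / max(abs(gust), 1e-12)
    y <- bed * gust
    # occasional faint distant events (filtered bursts at low gain)
    k <- max(1, round(duration_s / 12))
    for (i in seq_len(k)) {
      len <- round(0.4 * sample_rate)
      if (len + 1 >= n) break
      a <- sample.int(n - len, 1)
      ev <- lowpass1(rnorm(len), 1500, sample_rate) * sin(pi * seq_len(len) / len)^2
      y[a + seq_len(len) - 1] <- y[a + seq_len(len) - 1] + 0.3 * ev / max(abs(ev), 1e-12)
    }
    y <- y / max(abs(y), 1e-12)
    y * 0.12                                    # quiet ambience: rms well below voiced speech
  })
  audio_clip(x, sample_rate, "soundscape", seed = seed,
             meta = list(environment = environment))
}

#' Attenuate a clip as if re-recorded at a distance
#'
#' Inverse-distance gain (1 m reference, so `distance_m = 1` applies unit
#' gain) followed by a first-order low-pass whose cutoff decreases with
#' distance — a simple air-absorption proxy. The applied gain and cutoff are
#' recorded in the clip's `meta`.
#'
#' @param clip an [audio_clip].
#' @param distance_m distance in metres, `>= 1`.
#' @return An [audio_clip] with attenuated samples.
#' @export
apply_distance <- function(clip, distance_m) {
  if (!inherits(clip, "audio_clip")) abort_invalid("apply_distance: need an audio_clip")
  if (!is.numeric(distance_m) || length(distance_m) != 1 || distance_m < 1) {
    abort_invalid("apply_distance: distance_m must be >= 1")
  }
  gain <- 1 / distance_m
  cutoff <- 7000 / distance_m^0.7
  y <- lowpass1(clip$samples * gain, cutoff, clip$sample_rate)
  y <- clamp(y)
  meta <- clip$meta
  meta$distance_m <- distance_m
  meta$distance_gain <- gain
  meta$distance_cutoff_hz <- cutoff
  audio_clip(y, clip$sample_rate, clip$kind, seed = clip$seed, meta = meta)
}

#' Default fixture-pool configuration
#'
#' Desk-scale pool sizes: 40 speech clips balanced 1:1 across the two pitch
#' registers, one background clip per class for 40 classes, 20 bird clips, and
#' 4 long soundscape beds.
#'
#' @param speech,background,bird,soundscape pool sizes.
#' @param n_classes number of background classes.
#' @param speech_duration_s,bird_duration_s,background_duration_s,soundscape_duration_s
#'   clip durations in seconds.
#' @param soundscape_rate soundscape sampling rate in Hz.
#' @return A named list.
#' @export
fixture_config <- function(speech = 40, background = 40, bird = 20, soundscape = 4,
                           n_classes = 40, speech_duration_s = 3,
                           bird_duration_s = 3, background_duration_s = 5,
                           soundscape_duration_s = 55, soundscape_rate = 44100) {
  if (speech %% 2 != 0) abort_invalid("fixture_config: speech pool size must be even (1:1 registers)")
  as.list(environment())
}

#' Build all fixture pools
#'
#' Generates the speech/background/bird/soundscape pools, optionally writes
#' each clip as 16-bit PCM WAV under `outdir`, and returns the pools plus a
#' manifest. Speech registers are balanced exactly 1:1; background class ids
#' cycle through `1..n_classes`.
#'
#' @param config a [fixture_config()] list.
#' @param seed integer master seed; per-clip seeds are derived from it.
#' @param outdir output directory for WAVs and `pool_manifest.csv`, or `NULL`
#'   to keep the pools in memory only.
#' @return A list of class `fixture_pools` with elements `speech`,
#'   `background`, `bird`, `soundscape` (lists of [audio_clip]) and `manifest`
#'   (data.frame).
#' @export
build_fixture_pools <- function(config = fixture_config(), seed = 0, outdir = NULL) {
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(outdir)) abort_io("build_fixture_pools: cannot create ", outdir)
  }
  rows <- list()
  # manifest paths are relative to outdir so identical builds checksum equal
  add_row <- function(path, kind, tag, dur, sr, sd) {
    rows[[length(rows) + 1]] <<- data.frame(
      path = if (is.na(path)) path else basename(path), kind = kind,
      register_or_class = as.character(tag),
      duration_s = dur, sample_rate = sr, seed = sd, stringsAsFactors = FALSE)
  }
  persist <- function(clip, name) {
    if (is.null(outdir)) return(NA_character_)
    p <- file.path(outdir, name)
    wav_write(clip, p)
    p
  }

  speech <- vector("list", config$speech)
  regs <- rep(c("low_pitch", "high_pitch"), length.out = config$speech)
  # interleaved, so any even prefix stays balanced
  for (i in seq_len(config$speech)) {
    sd <- derive_seed(seed, paste0("pool_speech_", i))
    cl <- synth_speech_like(config$speech_duration_s, regs[i], seed = sd)
    p <- persist(cl, sprintf("speech_%03d.wav", i))
    cl$meta$path <- p
    speech[[i]] <- cl
    add_row(p, "speech", regs[i], config$speech_duration_s, cl$sample_rate, sd)
  }

  background <- vector("list", config$background)
  classes <- rep(seq_len(config$n_classes), length.out = config$background)
  for (i in seq_len(config$background)) {
    sd <- derive_seed(seed, paste0("pool_background_", i))
    cl <- synth_background(config$background_duration_s, classes[i], seed = sd,
                           n_classes = config$n_classes)
    p <- persist(cl, sprintf("background_%03d.wav", i))
    cl$meta$path <- p
    background[[i]] <- cl
    add_row(p, "background", classes[i], config$background_duration_s, cl$sample_rate, sd)
  }

  bird <- vector("list", config$bird)
  for (i in seq_len(config$bird)) {
    sd <- derive_seed(seed, paste0("pool_bird_", i))
    cl <- synth_bird_like(config$bird_duration_s, species_id = i, seed = sd)
    p <- persist(cl, sprintf("bird_%03d.wav", i))
    cl$meta$path <- p
    bird[[i]] <- cl
    add_row(p, "bird", i, config$bird_duration_s, cl$sample_rate, sd)
  }

  soundscape <- vector("list", config$soundscape)
  for (i in seq_len(config$soundscape)) {
    sd <- derive_seed(seed, paste0("pool_soundscape_", i))
    cl <- synth_soundscape(config$soundscape_duration_s, config$soundscape_rate, seed = sd)
    p <- persist(cl, sprintf("soundscape_%03d.wav", i))
    cl$meta$path <- p
    soundscape[[i]] <- cl
    add_row(p, "soundscape", "ambient", config$soundscape_duration_s, cl$sample_rate, sd)
  }

  manifest <- do.call(rbind, rows)
  if (!is.null(outdir)) {
    write.csv(manifest, file.path(outdir, "pool_manifest.csv"), row.names = FALSE)
  }
  structure(list(speech = speech, background = background, bird = bird,
                 soundscape = soundscape, manifest = manifest, seed = seed,
                 config = config),
            class = "fixture_pools")
}

#' @export
print.fixture_pools <- function(x, ...) {
  cat(sprintf("<fixture_pools: %d speech, %d background, %d bird, %d soundscape (seed %d)>\n",
              length(x$speech), length(x$background), length(x$bird),
              length(x$soundscape), x$seed))
  invisible(x)
}
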