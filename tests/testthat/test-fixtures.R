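# Synthetic audio pools: length arithmetic, determinism, amplitude bounds,
# and the spectral properties that make the detection task learnable.

test_that("speech synthesis: length, determinism, low-band energy", {
  clip <- synth_speech_like(3.0, "low_pitch", seed = 7)
  expect_s3_class(clip, "audio_clip")
  expect_equal(length(clip$samples), 48000L)
  expect_equal(clip$sample_rate, 16000L)
  twin <- synth_speech_like(3.0, "low_pitch", seed = 7)
  expect_identical(clip$samples, twin$samples)
  other <- synth_speech_like(3.0, "low_pitch", seed = 8)
  expect_false(identical(clip$samples, other$samples))
  # a low-register harmonic stack concentrates power below 1 kHz
  frac <- ecodistill:::band_energy_fraction(clip, 0, 1000)
  expect_gt(frac, 0.5)
  expect_error(synth_speech_like(0, "low_pitch", 1),
               class = "ecodistill_invalid_argument")
})

test_that("background synthesis: lengths, class dependence, bounds", {
  clip <- synth_background(5.0, 1, seed = 0, n_classes = 40)
  expect_equal(length(clip$samples), 80000L)
  c2 <- synth_background(5.0, 2, seed = 0, n_classes = 40)
  expect_false(identical(clip$samples, c2$samples))
  expect_error(synth_background(5.0, 41, 0, n_classes = 40),
               class = "ecodistill_invalid_argument")
  # amplitude bound over a parameter sweep
  for (k in seq(1, 40, by = 4)) {
    for (s in 0:1) {
      cl <- synth_background(0.5, k, seed = s, n_classes = 40)
      expect_lte(max(abs(cl$samples)), 1)
    }
  }
})

test_that("bird synthesis: band energy, determinism, degenerate input", {
  clip <- synth_bird_like(3.0, species_id = 12, seed = 3)
  expect_gt(ecodistill:::band_energy_fraction(clip, 2000, 8000), 0.7)
  expect_identical(clip$samples, synth_bird_like(3.0, 12, 3)$samples)
  expect_error(synth_bird_like(0.0, 12, 3), class = "ecodistill_invalid_argument")
})

test_that("soundscape: default duration arithmetic and quiet ambience", {
  # desk-scale duration here; the 55 s x 44.1 kHz default is plain arithmetic
  clip <- synth_soundscape(5.5, 44100, seed = 1)
  expect_equal(length(clip$samples), 242550L)
  expect_identical(clip$samples, synth_soundscape(5.5, 44100, seed = 1)$samples)
  speech <- synth_speech_like(3.0, "low_pitch", seed = 1)
  expect_lt(ecodistill:::rms(clip$samples), ecodistill:::rms(speech$samples))
})

test_that("apply_distance follows the inverse-distance law with low-pass proxy", {
  clip <- synth_speech_like(1.0, "low_pitch", seed = 2)
  d1 <- apply_distance(clip, 1)
  d20 <- apply_distance(clip, 20)
  expect_equal(d1$meta$distance_gain, 1.0)
  gain_db <- 20 * log10(d20$meta$distance_gain / d1$meta$distance_gain)
  expect_equal(gain_db, -26.02, tolerance = 0.005)
  rmses <- vapply(c(1, 5, 10, 20),
                  function(d) ecodistill:::rms(apply_distance(clip, d)$samples),
                  numeric(1))
  expect_true(all(diff(rmses) <= 0))
  expect_true(d20$meta$distance_cutoff_hz < d1$meta$distance_cutoff_hz)
  expect_error(apply_distance(clip, 0.5), class = "ecodistill_invalid_argument")
})

test_that("fixture pools: counts, register balance, manifest determinism", {
  outdir <- file.path(tempdir(), "pools_a")
  unlink(outdir, recursive = TRUE)
  cfg <- tiny_pool_config()
  pools <- build_fixture_pools(cfg, seed = 3, outdir = outdir)
  expect_equal(nrow(pools$manifest), 8 + 8 + 4 + 2)
  # manifest paths are relative to the pool directory
  expect_equal(sum(file.exists(file.path(outdir, pools$manifest$path))),
               nrow(pools$manifest))
  regs <- vapply(pools$speech, function(cl) cl$meta$register, character(1))
  expect_equal(sum(regs == "low_pitch"), 4)
  expect_equal(sum(regs == "high_pitch"), 4)
  classes <- vapply(pools$background, function(cl) cl$meta$class_id, integer(1))
  expect_setequal(classes, 1:8)
  # rerun with the same seed: identical manifest checksum
  outdir2 <- file.path(tempdir(), "pools_b")
  unlink(outdir2, recursive = TRUE)
  build_fixture_pools(cfg, seed = 3, outdir = outdir2)
  expect_identical(unname(tools::md5sum(file.path(outdir, "pool_manifest.csv"))),
                   unname(tools::md5sum(file.path(outdir2, "pool_manifest.csv"))))
  wavs1 <- sort(list.files(outdir, "\\.wav$"))
  expect_identical(unname(tools::md5sum(file.path(outdir, wavs1))),
                   unname(tools::md5sum(file.path(outdir2, wavs1))))
})

test_that("spectral separation: speech centroid sits below bird centroid", {
  sc <- vapply(1:20, function(i)
    ecodistill:::spectral_centroid(synth_speech_like(1.0, "high_pitch", seed = i)),
    numeric(1))
  bc <- vapply(1:20, function(i)
    ecodistill:::spectral_centroid(synth_bird_like(1.0, species_id = i, seed = i)),
    numeric(1))
  expect_lt(mean(sc), mean(bc))
})
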