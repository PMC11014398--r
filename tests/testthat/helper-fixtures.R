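# Shared tiny fixtures, built once per test run.

tiny_pool_config <- function() {
  fixture_config(speech = 8, background = 8, bird = 4, soundscape = 2,
                 n_classes = 8, soundscape_duration_s = 12,
                 soundscape_rate = 44100)
}

tiny_pools <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- build_fixture_pools(tiny_pool_config(), seed = 11)
    val
  }
})

# A small labelled dataset with splits, WAVs under a session temp dir.
tiny_dataset <- local({
  val <- NULL
  function(n_total = 40) {
    if (is.null(val)) {
      dir <- file.path(tempdir(), "ecodistill_tiny_dataset")
      unlink(dir, recursive = TRUE)
      man <- build_dataset(tiny_pools(), n_total = n_total, seed = 5, outdir = dir)
      val <<- split_dataset(man, seed = 5)
    }
    val
  }
})

tiny_archive <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- featurize_manifest(tiny_dataset())
    val
  }
})

# Numeric gradient of f at x (same shape as x), central differences.
num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

expect_rel_equal <- function(actual, expected, tol = 1e-4) {
  denom <- pmax(abs(expected), 1e-8)
  expect_lt(max(abs(actual - expected) / denom), tol)
}

# The full-width teacher is expensive to build (59.6M weights); tests that
# only count or shape-check share one instance.
full_teacher <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- build_teacher(width_mult = 1)
    val
  }
})
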