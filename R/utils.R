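#' @useDynLib ecodistill, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom median quantile fft sd
#' @importFrom utils write.csv read.csv
NULL

abort_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("ecodistill_invalid_argument", "error")))
}

abort_state <- function(...) {
  stop(errorCondition(paste0(...), class = c("ecodistill_invalid_state", "error")))
}

abort_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("ecodistill_io_error", "error")))
}

#' Derive a child seed from a parent seed and a stage label
#'
#' Stages of the pipeline (fixtures, dataset, training, ...) each get their own
#' RNG stream derived from one global seed, so a stage can be re-run in
#' isolation and still reproduce. The derivation hashes the label bytes with a
#' small multiplicative mix and folds the result into the signed 32-bit range
#' accepted by [set.seed()].
#'
#' @param seed integer parent seed.
#' @param label character scalar naming the stage/stream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- as.double(seed %% 2147483647)
  for (b in utf8ToInt(label)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Run code under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is untouched. All fixture/dataset randomness goes through this.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% 2147483647L), code)
}

rms <- function(x) sqrt(mean(x^2))

db_to_amp <- function(db) 10^(db / 20)

clamp <- function(x, lo = -1, hi = 1) pmin(hi, pmax(lo, x))

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x)

md5_file <- function(path) unname(tools::md5sum(path))
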