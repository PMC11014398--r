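## Sequential model container with named layers, tap points for distillation
## (hint/guide feature maps, pre-logit embedding), functional forward/backward,
## and flat parameter access for the optimizer.

new_model <- function(name, layers, taps = character(), embed_layer,
                      input_shape = c(128, 128, 1), width_mult = 1) {
  structure(list(name = name, layers = layers, taps = taps,
                 embed_layer = embed_layer, input_shape = input_shape,
                 width_mult = width_mult),
            class = "vad_model")
}

#' @export
print.vad_model <- function(x, ...) {
  cat(sprintf("<vad_model '%s': %d layers, %s params, input %s, width x%g>\n",
              x$name, length(x$layers),
              format(count_parameters(x), big.mark = ","),
              paste(x$input_shape, collapse = "x"), x$width_mult))
  invisible(x)
}

# Full forward pass. Returns logits (length-N vector), every named layer
# output requested in `collect`, all caches, and the (buffer-updated) model.
model_forward <- function(model, x, training = FALSE, collect = character()) {
  stopifnot(length(dim(x)) == 4)
  caches <- vector("list", length(model$layers))
  names(caches) <- names(model$layers)
  acts <- list()
  h <- x
  for (nm in names(model$layers)) {
    r <- layer_forward(model$layers[[nm]], h, training)
    model$layers[[nm]] <- r$layer
    caches[[nm]] <- r$cache
    h <- r$out
    if (nm %in% collect) acts[[nm]] <- h
  }
  list(logits = as.numeric(h), acts = acts, caches = caches, model = model)
}

# Backward pass from logit gradients, with optional extra gradients injected at
# named tap layers (gradients w.r.t. those layers' outputs).
model_backward <- function(model, caches, grad_logits, tap_grads = list()) {
  nms <- names(model$layers)
  g <- matrix(grad_logits, nrow = 1)
  grads <- list()
  for (nm in rev(nms)) {
    if (nm %in% names(tap_grads)) {
      tg <- tap_grads[[nm]]
      g <- g + tg
    }
    r <- layer_backward(model$layers[[nm]], caches[[nm]], g)
    if (length(r$grads)) {
      for (pn in names(r$grads)) grads[[paste(nm, pn, sep = "/")]] <- r$grads[[pn]]
    }
    g <- r$gx
  }
  grads
}

#' Forward pass exposing distillation taps
#'
#' Runs the model in eval mode (batch-norm running statistics, no dropout) and
#' returns the logits together with the feature map at each registered tap
#' layer and the flattened pre-logit embedding.
#'
#' @param model a `vad_model`.
#' @param x input batch: array `(128, 128, 1, N)` of normalized Mel grids (a
#'   single `mel_spec` or a list of them is also accepted).
#' @param taps tap names to collect; defaults to all registered taps.
#' @param training run in training mode (batch statistics, dropout active).
#' @return List with `logits` (numeric N), `taps` (named list of feature
#'   arrays), `embedding` (matrix `features x N`).
#' @export
forward_with_taps <- function(model, x, taps = names(model$taps), training = FALSE) {
  if (!inherits(model, "vad_model")) abort_invalid("forward_with_taps: need a vad_model")
  x <- as_input_batch(x, model$input_shape)
  bad <- setdiff(taps, names(model$taps))
  if (length(bad)) abort_invalid("forward_with_taps: unregistered tap(s): ",
                                 paste(bad, collapse = ", "))
  layer_names <- unname(model$taps[taps])
  r <- model_forward(model, x, training = training,
                     collect = unique(c(layer_names, model$embed_layer)))
  tap_out <- stats::setNames(r$acts[layer_names], taps)
  emb <- r$acts[[model$embed_layer]]
  list(logits = r$logits, taps = tap_out, embedding = emb)
}

as_input_batch <- function(x, input_shape) {
  if (inherits(x, "mel_spec")) x <- list(x)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "mel_spec"))) {
    arr <- array(0, dim = c(input_shape, length(x)))
    for (i in seq_along(x)) arr[, , 1, i] <- x[[i]]$grid
    return(arr)
  }
  if (is.array(x) && length(dim(x)) == 4) return(x)
  if (is.matrix(x) && all(dim(x) == input_shape[1:2])) {
    return(array(x, dim = c(input_shape, 1)))
  }
  abort_invalid("expected a (H, W, C, N) array or mel_spec input")
}

# Flat named parameter list ("layer/param") and its inverse.
nn_params <- function(model) {
  out <- list()
  for (nm in names(model$layers)) {
    ps <- layer_params(model$layers[[nm]])
    for (pn in names(ps)) out[[paste(nm, pn, sep = "/")]] <- ps[[pn]]
  }
  out
}

nn_set_params <- function(model, flat) {
  for (key in names(flat)) {
    parts <- strsplit(key, "/", fixed = TRUE)[[1]]
    nm <- parts[1]; pn <- parts[2]
    model$layers[[nm]] <- layer_set_params(model$layers[[nm]],
                                           stats::setNames(list(flat[[key]]), pn))
  }
  model
}

#' Count trainable parameters
#'
#' Sums element counts over every trainable array: convolution and dense
#' weights and biases, and batch-norm scale/shift. Running statistics are
#' buffers, not parameters, and are excluded.
#'
#' @param model a `vad_model`.
#' @return Integer-valued numeric count.
#' @export
count_parameters <- function(model) {
  sum(vapply(nn_params(model), length, numeric(1)))
}

#' Count multiply-accumulate operations for one forward pass
#'
#' Walks the layer graph with shape propagation and sums a MAC-style cost per
#' layer: convolutions and dense layers contribute
#' `out_elements * kernel_elements * in_channels / groups` (plus one op per
#' output element when a bias is present), batch norm 2 ops per element,
#' activations 1 op per element, max pooling 1 op per output element, global
#' average pooling 1 op per input element, SE blocks their constituent ops
#' plus the gating multiply, and residual additions 1 op per element.
#'
#' @param model a `vad_model`.
#' @param input_shape input shape `c(H, W, C)`; defaults to the model's own.
#' @return Numeric op count (exceeds 32-bit integer range for the teacher).
#' @export
count_macs <- function(model, input_shape = model$input_shape) {
  shp <- input_shape
  total <- 0
  for (nm in names(model$layers)) {
    l <- model$layers[[nm]]
    total <- total + layer_macs(l, shp)
    shp <- layer_out_shape(l, shp)
  }
  total
}

#' Profile a model's resource budget
#'
#' Parameters, MAC-style operation count (reported as `flops_table`, the
#' convention used for published "FLOPS" figures of this model family),
#' multiplications (`= flops_table / 2` by the same table convention), memory
#' (`params * 4` bytes, i.e. float32 storage, in MiB — `memory_mib` raw and
#' `memory_mib_table` truncated to table precision: whole MiB at >= 10 MiB,
#' two decimals below), and mean single-input inference time over `n_trials`
#' forward passes (reported, never asserted).
#'
#' @param model a `vad_model`.
#' @param n_trials timing repetitions (default 100).
#' @return List of class `efficiency_profile`.
#' @export
profile_model <- function(model, n_trials = 100) {
  params <- count_parameters(model)
  macs <- count_macs(model)
  x <- array(0, dim = c(model$input_shape, 1))
  # warm-up
  invisible(model_forward(model, x))
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(n_trials)) invisible(model_forward(model, x))
  avg_s <- (proc.time()[["elapsed"]] - t0) / n_trials
  mem <- params * 4 / 2^20
  structure(list(name = model$name, params = params, macs = macs,
                 flops_table = macs, mults_table = macs / 2,
                 memory_mib = mem, memory_mib_table = memory_table_mib(params),
                 avg_inference_s = avg_s, n_trials = n_trials),
            class = "efficiency_profile")
}

memory_table_mib <- function(params) {
  mem <- params * 4 / 2^20
  if (mem >= 10) trunc(mem) else trunc(mem * 100) / 100
}

#' @export
print.efficiency_profile <- function(x, ...) {
  cat(sprintf(paste0("<efficiency_profile '%s': %s params, %s MAC-ops, ",
                     "%.4g MiB, %.4g s/inference (%d trials)>\n"),
              x$name, format(x$params, big.mark = ","),
              format(x$macs, big.mark = ",", scientific = FALSE),
              x$memory_mib_table, x$avg_inference_s, x$n_trials))
  invisible(x)
}
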