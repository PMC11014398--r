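## Model zoo: the VGG11 (batch-normalized) teacher adapted to single-channel
## 128x128 spectrograms, and four MobileNetV3-Small-Pi style students whose
## block tables ship as versioned YAML in inst/extdata/model_zoo.yaml.

load_model_zoo <- function() {
  path <- system.file("extdata", "model_zoo.yaml", package = "ecodistill")
  if (path == "") path <- file.path("inst", "extdata", "model_zoo.yaml")
  yaml::read_yaml(path)
}

scale_ch <- function(ch, width_mult, divisor = 4L) {
  if (width_mult == 1) return(as.integer(ch))
  as.integer(max(divisor, round(ch * width_mult / divisor) * divisor))
}

#' Build the teacher network
#'
#' A VGG11 layout with batch normalization: 8 convolutional layers
#' (64/128/256/256/512/512/512/512 channels, 3x3 kernels, each followed by
#' batch norm and ReLU), five 2x2 max-pools, then — on the 512 x 4 x 4 map a
#' 128x128 input produces — fully connected layers 8192 -> 4096 -> 4096 -> 1
#' with dropout (p = 0.5) on both hidden layers and a single output logit.
#' At `width_mult = 1` the parameter count is 59,568,769.
#'
#' The registered hint tap (`hint`) is the 256-channel 16x16 stage (after the
#' third max-pool); the embedding is the second hidden FC activation.
#'
#' @param width_mult channel width multiplier (1 = full size). Used to scale
#'   experiments down to desk scale; resource accounting in published-table
#'   terms always refers to `width_mult = 1`.
#' @param seed seed for weight initialization.
#' @return A `vad_model`.
#' @export
build_teacher <- function(width_mult = 1, seed = 0) {
  zoo <- load_model_zoo()$teacher
  conv_ch <- vapply(zoo$conv, scale_ch, integer(1), width_mult = width_mult)
  fc_w <- vapply(zoo$fc, scale_ch, integer(1), width_mult = width_mult)
  with_seed(derive_seed(seed, "build_teacher"), {
    layers <- list()
    in_ch <- 1L
    pool_i <- 0
    for (i in seq_along(conv_ch)) {
      layers[[paste0("conv", i)]] <- nn_conv2d(in_ch, conv_ch[i], kernel = 3, bias = TRUE)
      layers[[paste0("bn", i)]] <- nn_batchnorm2d(conv_ch[i])
      layers[[paste0("relu", i)]] <- nn_relu()
      if (i %in% zoo$pool_after) {
        pool_i <- pool_i + 1
        layers[[paste0("pool", pool_i)]] <- nn_maxpool2()
      }
      in_ch <- conv_ch[i]
    }
    layers$flatten <- nn_flatten()
    feat <- in_ch * 4 * 4
    layers$fc1 <- nn_linear(feat, fc_w[1])
    layers$fc1_relu <- nn_relu()
    layers$fc1_drop <- nn_dropout(zoo$dropout)
    layers$fc2 <- nn_linear(fc_w[1], fc_w[2])
    layers$fc2_relu <- nn_relu()
    layers$fc2_drop <- nn_dropout(zoo$dropout)
    layers$fc3 <- nn_linear(fc_w[2], 1)
    new_model("teacher", layers, taps = c(hint = zoo$hint),
              embed_layer = "fc2_relu", width_mult = width_mult)
  })
}

#' Build a student network
#'
#' MobileNetV3-Small-Pi style: a 3x3 stem convolution (stride 2), a sequence
#' of inverted-residual bottlenecks (1x1 expand, 3x3 depthwise, optional SE,
#' 1x1 linear projection, skip when stride 1 and widths match; all kernels
#' 3x3, all activations ReLU), a pointwise pre-pool convolution, global
#' average pooling, and a head of two pointwise convolutions (applied to the
#' pooled 1x1 map, hence dense maps) producing a single logit. Block tables
#' come from the versioned model zoo; see `inst/extdata/model_zoo.yaml`.
#'
#' The registered guide tap is each student's 16x16 stage; the embedding is
#' the hidden head activation.
#'
#' @param variant 1-4, `"student1"`..`"student4"`, or `"s1"`..`"s4"`.
#' @param width_mult channel width multiplier.
#' @param seed seed for weight initialization.
#' @return A `vad_model`.
#' @export
build_student <- function(variant, width_mult = 1, seed = 0) {
  if (is.numeric(variant)) variant <- paste0("student", variant)
  variant <- sub("^s(\\d)$", "student\\1", variant)
  zoo <- load_model_zoo()$students
  if (!variant %in% names(zoo)) {
    abort_invalid("build_student: unknown variant '", variant, "' (use 1-4)")
  }
  cfg <- zoo[[variant]]
  with_seed(derive_seed(seed, paste0("build_", variant)), {
    layers <- list()
    stem <- scale_ch(cfg$stem, width_mult)
    layers$stem <- nn_conv2d(1L, stem, kernel = 3, stride = 2, bias = FALSE)
    layers$stem_bn <- nn_batchnorm2d(stem)
    layers$stem_relu <- nn_relu()
    in_ch <- stem
    for (i in seq_along(cfg$blocks)) {
      b <- cfg$blocks[[i]]
      exp_ch <- scale_ch(b[[1]], width_mult)
      out_ch <- scale_ch(b[[2]], width_mult)
      if (exp_ch < in_ch) exp_ch <- in_ch   # expansion never narrows
      layers[[paste0("block", i)]] <- nn_bottleneck(in_ch, exp_ch, out_ch,
                                                    stride = b[[4]],
                                                    se = isTRUE(b[[3]]))
      in_ch <- out_ch
    }
    last <- scale_ch(cfg$last_conv, width_mult)
    layers$last_conv <- nn_conv2d(in_ch, last, kernel = 1, bias = FALSE)
    layers$last_bn <- nn_batchnorm2d(last)
    layers$last_relu <- nn_relu()
    layers$pool <- nn_gap()
    hidden <- scale_ch(cfg$head_hidden, width_mult)
    layers$head1 <- nn_linear(last, hidden)       # pointwise conv on 1x1 map
    layers$head1_relu <- nn_relu()
    layers$head2 <- nn_linear(hidden, 1)
    new_model(variant, layers, taps = c(guide = cfg$guide),
              embed_layer = "head1_relu", width_mult = width_mult)
  })
}

#' Build every model in the zoo
#'
#' @param width_mult channel width multiplier applied to all models.
#' @param seed initialization seed.
#' @return Named list: teacher, student1..student4.
#' @export
build_model_zoo <- function(width_mult = 1, seed = 0) {
  models <- c(list(teacher = build_teacher(width_mult, seed)),
              stats::setNames(lapply(1:4, build_student, width_mult = width_mult,
                                     seed = seed),
                              paste0("student", 1:4)))
  models
}

#' Save / load model weights
#'
#' Checkpoints store the flat parameter list plus batch-norm buffers using R's
#' native serialization.
#'
#' @param model a `vad_model`.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored `vad_model` (load, requires a
#'   freshly built model of the same architecture via `into`).
#' @export
save_checkpoint <- function(model, path) {
  buffers <- lapply(model$layers, collect_buffers)
  saveRDS(list(name = model$name, width_mult = model$width_mult,
               params = nn_params(model), buffers = buffers), path, version = 3)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param into a freshly built `vad_model` with matching architecture.
#' @export
load_checkpoint <- function(path, into) {
  ck <- readRDS(path)
  model <- nn_set_params(into, ck$params)
  for (nm in names(ck$buffers)) {
    model$layers[[nm]] <- restore_buffers(model$layers[[nm]], ck$buffers[[nm]])
  }
  model
}

collect_buffers <- function(layer) {
  if (layer$type == "bottleneck") lapply(layer$sub, collect_buffers)
  else layer$buffers
}

restore_buffers <- function(layer, buffers) {
  if (layer$type == "bottleneck") {
    for (nm in names(buffers)) layer$sub[[nm]] <- restore_buffers(layer$sub[[nm]], buffers[[nm]])
  } else if (length(buffers)) {
    layer$buffers <- buffers
  }
  layer
}

# md5 of the serialized parameter list — used to assert the frozen-teacher
# contract after student training.
params_checksum <- function(model) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(nn_params(model), tmp, version = 3)
  md5_file(tmp)
}
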