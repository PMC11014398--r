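## Minimal CNN framework with analytic backprop.
## Tensor layout: 4-D arrays dim (H, W, C, N); dense activations are matrices
## (features x N). Convolution/pooling kernels live in src/nn_ops.cpp; batch
## norm, SE gating, dense layers and the bookkeeping live here.
##
## Layers are plain lists (class c("nn_<type>", "nn_layer")) with `params`
## (trainable arrays), optional `buffers` (batch-norm running stats), and
## hyper-parameters. The API is functional: `layer_forward()` returns the
## output, a cache for the backward pass, and the (possibly buffer-updated)
## layer; `layer_backward()` returns the input gradient and per-parameter
## gradients named like `params`.

new_layer <- function(type, params = list(), buffers = list(), ...) {
  structure(c(list(type = type, params = params, buffers = buffers), list(...)),
            class = c(paste0("nn_", type), "nn_layer"))
}

make_divisible <- function(x, divisor = 8, min_value = divisor) {
  v <- max(min_value, floor(x + divisor / 2) %/% divisor * divisor)
  if (v < 0.9 * x) v <- v + divisor
  as.integer(v)
}

## ---- constructors -----------------------------------------------------------

nn_conv2d <- function(in_ch, out_ch, kernel = 3, stride = 1, pad = NULL,
                      groups = 1, bias = TRUE) {
  if (is.null(pad)) pad <- (kernel - 1) %/% 2
  # Kaiming, fan-out mode — the convention of the VGG/MobileNet family. With
  # batch norm the forward pass is weight-scale invariant but the effective
  # learning rate is not: fan-in init makes depthwise kernels (fan_in = k^2)
  # an order of magnitude too hot and stalls the thin student networks.
  fan_out <- kernel * kernel * out_ch / groups
  w <- array(rnorm(kernel * kernel * (in_ch / groups) * out_ch, 0, sqrt(2 / fan_out)),
             dim = c(kernel, kernel, in_ch / groups, out_ch))
  params <- list(w = w)
  if (bias) params$b <- numeric(out_ch)
  new_layer("conv2d", params, in_ch = in_ch, out_ch = out_ch, kernel = kernel,
            stride = stride, pad = pad, groups = groups, bias = bias)
}

nn_batchnorm2d <- function(ch, momentum = 0.1, eps = 1e-5) {
  new_layer("batchnorm2d",
            params = list(gamma = rep(1, ch), beta = numeric(ch)),
            buffers = list(running_mean = numeric(ch), running_var = rep(1, ch)),
            ch = ch, momentum = momentum, eps = eps)
}

nn_relu <- function() new_layer("relu")
nn_maxpool2 <- function() new_layer("maxpool2")
nn_gap <- function() new_layer("gap")          # global average pool -> (C, N)
nn_flatten <- function() new_layer("flatten")

nn_linear <- function(in_f, out_f, bias = TRUE, sd = 0.01) {
  # dense layers use N(0, 0.01), the classical VGG / MobileNet classifier init
  w <- matrix(rnorm(out_f * in_f, 0, sd), out_f, in_f)
  params <- list(w = w)
  if (bias) params$b <- numeric(out_f)
  new_layer("linear", params, in_f = in_f, out_f = out_f, bias = bias)
}

nn_dropout <- function(p = 0.5) new_layer("dropout", p = p)

nn_se <- function(ch, reduce = 4) {
  r <- make_divisible(ch / reduce, 8)
  new_layer("se",
            params = list(w1 = matrix(rnorm(r * ch, 0, sqrt(2 / ch)), r, ch),
                          b1 = numeric(r),
                          w2 = matrix(rnorm(ch * r, 0, sqrt(1 / r)), ch, r),
                          b2 = numeric(ch)),
            ch = ch, r = r)
}

# Inverted-residual bottleneck: 1x1 expand -> 3x3 depthwise -> (SE) -> 1x1
# project, batch norm after every conv, ReLU after expand/depthwise, linear
# projection, skip connection when stride 1 and in_ch == out_ch.
nn_bottleneck <- function(in_ch, exp_ch, out_ch, stride = 1, se = FALSE, kernel = 3) {
  sub <- list()
  if (exp_ch != in_ch) {
    sub$expand <- nn_conv2d(in_ch, exp_ch, kernel = 1, bias = FALSE)
    sub$expand_bn <- nn_batchnorm2d(exp_ch)
    sub$expand_relu <- nn_relu()
  }
  sub$dw <- nn_conv2d(exp_ch, exp_ch, kernel = kernel, stride = stride,
                      groups = exp_ch, bias = FALSE)
  sub$dw_bn <- nn_batchnorm2d(exp_ch)
  sub$dw_relu <- nn_relu()
  if (se) sub$se <- nn_se(exp_ch)
  sub$project <- nn_conv2d(exp_ch, out_ch, kernel = 1, bias = FALSE)
  sub$project_bn <- nn_batchnorm2d(out_ch)
  new_layer("bottleneck", sub = sub, in_ch = in_ch, exp_ch = exp_ch,
            out_ch = out_ch, stride = stride, se = se, kernel = kernel)
}

## ---- forward ----------------------------------------------------------------

# per-(channel, sample) means over the spatial plane: (H,W,C,N) -> (C,N)
plane_colmeans <- function(x) {
  dm <- dim(x)
  matrix(.colMeans(x, dm[1] * dm[2], dm[3] * dm[4]), dm[3], dm[4])
}

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv2d = {
      if (layer$groups == layer$in_ch && layer$groups == layer$out_ch && !layer$bias) {
        out <- .dwconv2d_fwd(x, layer$params$w, layer$stride, layer$pad)
      } else {
        b <- if (layer$bias) layer$params$b else NULL
        out <- .conv2d_fwd(x, layer$params$w, b, layer$stride, layer$pad, layer$groups)
      }
      list(out = out, cache = list(x = x), layer = layer)
    },
    batchnorm2d = {
      if (training) {
        st <- .bn_stats(x)
        mu <- st$mean
        v <- st$var
        layer$buffers$running_mean <- (1 - layer$momentum) * layer$buffers$running_mean +
          layer$momentum * mu
        layer$buffers$running_var <- (1 - layer$momentum) * layer$buffers$running_var +
          layer$momentum * v
      } else {
        mu <- layer$buffers$running_mean
        v <- layer$buffers$running_var
      }
      inv <- 1 / sqrt(v + layer$eps)
      out <- .bn_apply(x, mu, inv, layer$params$gamma, layer$params$beta)
      list(out = out, cache = list(x = x, mu = mu, inv = inv, training = training),
           layer = layer)
    },
    relu = {
      out <- .relu_fwd(x)
      list(out = out, cache = list(out = out), layer = layer)
    },
    maxpool2 = {
      r <- .maxpool2_fwd(x)
      list(out = r$out, cache = list(idx = r$idx, in_dim = dim(x)), layer = layer)
    },
    gap = {
      dm <- dim(x)
      list(out = plane_colmeans(x), cache = list(in_dim = dm), layer = layer)
    },
    flatten = {
      dm <- dim(x)
      dim(x) <- c(prod(dm[1:3]), dm[4])
      list(out = x, cache = list(in_dim = dm), layer = layer)
    },
    linear = {
      out <- layer$params$w %*% x
      if (layer$bias) out <- out + layer$params$b
      list(out = out, cache = list(x = x), layer = layer)
    },
    dropout = {
      if (!training || layer$p == 0) {
        list(out = x, cache = list(mask = NULL), layer = layer)
      } else {
        mask <- array(rbinom(length(x), 1, 1 - layer$p) / (1 - layer$p), dim = dim(x))
        list(out = x * mask, cache = list(mask = mask), layer = layer)
      }
    },
    se = {
      s <- plane_colmeans(x)                       # (C, N)
      z_pre <- layer$params$w1 %*% s + layer$params$b1
      z <- z_pre * (z_pre > 0)
      g_pre <- layer$params$w2 %*% z + layer$params$b2
      g <- 1 / (1 + exp(-g_pre))
      out <- .mul_channels(x, g)
      list(out = out, cache = list(x = x, s = s, z_pre = z_pre, z = z, g = g),
           layer = layer)
    },
    bottleneck = {
      caches <- list()
      h <- x
      for (nm in names(layer$sub)) {
        r <- layer_forward(layer$sub[[nm]], h, training)
        layer$sub[[nm]] <- r$layer
        caches[[nm]] <- r$cache
        h <- r$out
      }
      skip <- layer$stride == 1 && layer$in_ch == layer$out_ch
      if (skip) h <- h + x
      list(out = h, cache = list(sub = caches, skip = skip), layer = layer)
    },
    stop("unknown layer type: ", layer$type)
  )
}

## ---- backward ---------------------------------------------------------------

layer_backward <- function(layer, cache, gy) {
  switch(layer$type,
    conv2d = {
      if (layer$groups == layer$in_ch && layer$groups == layer$out_ch && !layer$bias) {
        r <- .dwconv2d_bwd(cache$x, layer$params$w, gy, layer$stride, layer$pad)
        return(list(gx = r$gx, grads = list(w = r$gw)))
      }
      r <- .conv2d_bwd(cache$x, layer$params$w, gy, layer$stride, layer$pad,
                       layer$groups, layer$bias)
      grads <- list(w = r$gw)
      if (layer$bias) grads$b <- as.numeric(r$gb)
      list(gx = r$gx, grads = grads)
    },
    batchnorm2d = {
      r <- .bn_bwd(cache$x, gy, cache$mu, cache$inv, layer$params$gamma,
                   cache$training)
      list(gx = r$gx, grads = list(gamma = as.numeric(r$ggamma),
                                   beta = as.numeric(r$gbeta)))
    },
    relu = list(gx = .relu_bwd(gy, cache$out), grads = list()),
    maxpool2 = list(gx = .maxpool2_bwd(gy, cache$idx, as.integer(cache$in_dim)),
                    grads = list()),
    gap = {
      dm <- cache$in_dim
      gx <- .bcast_channels(as.integer(dm), gy / (dm[1] * dm[2]))
      list(gx = gx, grads = list())
    },
    flatten = {
      dim(gy) <- cache$in_dim
      list(gx = gy, grads = list())
    },
    linear = {
      grads <- list(w = gy %*% t(cache$x))
      if (layer$bias) grads$b <- rowSums(gy)
      list(gx = t(layer$params$w) %*% gy, grads = grads)
    },
    dropout = {
      if (is.null(cache$mask)) list(gx = gy, grads = list())
      else list(gx = gy * cache$mask, grads = list())
    },
    se = {
      dm <- dim(gy)
      hw <- dm[1] * dm[2]
      g <- cache$g
      gx_direct <- .mul_channels(gy, g)
      ggate <- .sum_channels_xy(gy, cache$x)          # (C,N): sum over plane
      dgpre <- ggate * g * (1 - g)
      gw2 <- dgpre %*% t(cache$z)
      gb2 <- rowSums(dgpre)
      gz <- t(layer$params$w2) %*% dgpre
      dz <- gz * (cache$z_pre > 0)
      gw1 <- dz %*% t(cache$s)
      gb1 <- rowSums(dz)
      gs <- t(layer$params$w1) %*% dz                 # (C,N)
      gx <- .add_channels(gx_direct, gs / hw)
      list(gx = gx, grads = list(w1 = gw1, b1 = gb1, w2 = gw2, b2 = gb2))
    },
    bottleneck = {
      nms <- names(layer$sub)
      grads <- list()
      g <- gy
      for (nm in rev(nms)) {
        r <- layer_backward(layer$sub[[nm]], cache$sub[[nm]], g)
        if (length(r$grads)) {
          for (pn in names(r$grads)) grads[[paste(nm, pn, sep = ".")]] <- r$grads[[pn]]
        }
        g <- r$gx
      }
      if (cache$skip) g <- g + gy
      list(gx = g, grads = grads)
    },
    stop("unknown layer type: ", layer$type)
  )
}

## ---- parameters, shapes, op counts ------------------------------------------

layer_params <- function(layer) {
  if (layer$type == "bottleneck") {
    out <- list()
    for (nm in names(layer$sub)) {
      ps <- layer_params(layer$sub[[nm]])
      for (pn in names(ps)) out[[paste(nm, pn, sep = ".")]] <- ps[[pn]]
    }
    out
  } else {
    layer$params
  }
}

layer_set_params <- function(layer, params) {
  if (layer$type == "bottleneck") {
    for (key in names(params)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      nm <- parts[1]; pn <- paste(parts[-1], collapse = ".")
      layer$sub[[nm]] <- layer_set_params(layer$sub[[nm]], stats::setNames(list(params[[key]]), pn))
    }
  } else {
    for (pn in names(params)) layer$params[[pn]] <- params[[pn]]
  }
  layer
}

# Shape propagation; shapes are c(H, W, C) for 4-D stages, or a single integer
# for dense stages.
layer_out_shape <- function(layer, shp) {
  conv_hw <- function(hw, k, s, p) (hw + 2 * p - k) %/% s + 1
  switch(layer$type,
    conv2d = c(conv_hw(shp[1], layer$kernel, layer$stride, layer$pad),
               conv_hw(shp[2], layer$kernel, layer$stride, layer$pad), layer$out_ch),
    batchnorm2d = shp,
    relu = shp,
    maxpool2 = c(shp[1] %/% 2, shp[2] %/% 2, shp[3]),
    gap = shp[3],
    flatten = prod(shp),
    linear = layer$out_f,
    dropout = shp,
    se = shp,
    bottleneck = {
      s <- shp
      for (nm in names(layer$sub)) s <- layer_out_shape(layer$sub[[nm]], s)
      s
    },
    stop("unknown layer type: ", layer$type)
  )
}

# Multiply-accumulate style op count for one layer at the given input shape.
# Convention (documented in the profiler): conv/linear MACs including bias
# adds; batch norm 2 ops/element; activations 1 op/element; max pooling 1
# op/output element; global average pool 1 op/input element; SE constituents
# counted plus 1 op/element for the channel gating; residual adds 1
# op/element.
layer_macs <- function(layer, shp) {
  out <- layer_out_shape(layer, shp)
  n_el <- function(s) prod(s)
  switch(layer$type,
    conv2d = {
      macs <- n_el(out) * layer$kernel^2 * layer$in_ch / layer$groups
      if (layer$bias) macs <- macs + n_el(out)
      macs
    },
    batchnorm2d = 2 * n_el(shp),
    relu = n_el(shp),
    maxpool2 = n_el(out),
    gap = n_el(shp),
    flatten = 0,
    linear = layer$in_f * layer$out_f + if (layer$bias) layer$out_f else 0,
    dropout = 0,
    se = {
      C <- layer$ch; r <- layer$r
      n_el(shp) +                      # squeeze (pool)
        (C * r + r) + r +              # fc1 + bias + relu
        (r * C + C) + C +              # fc2 + bias + sigmoid
        n_el(shp)                      # channel gating multiply
    },
    bottleneck = {
      s <- shp
      macs <- 0
      for (nm in names(layer$sub)) {
        macs <- macs + layer_macs(layer$sub[[nm]], s)
        s <- layer_out_shape(layer$sub[[nm]], s)
      }
      if (layer$stride == 1 && layer$in_ch == layer$out_ch) macs <- macs + n_el(s)
      macs
    },
    stop("unknown layer type: ", layer$type)
  )
}
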