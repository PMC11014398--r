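## Training protocol: Adam (lr 0.001), batch size 32, at most 50 epochs, early
## stopping on validation task loss with patience 3. Students optimize the
## configured composite distillation objective; validation is always monitored
## on the plain task loss so teacher and student runs are comparable.

#' Predict logits / scores for a feature array
#'
#' @param model a `vad_model`.
#' @param features array `(128, 128, 1, n)`.
#' @param batch_size forward batch size (results are batch-size independent:
#'   eval mode uses running batch-norm statistics).
#' @return Numeric vector of raw logits.
#' @export
model_logits <- function(model, features, batch_size = 32) {
  n <- dim(features)[4]
  out <- numeric(n)
  for (b in batch_idx(n, batch_size, shuffle = FALSE)) {
    r <- model_forward(model, features[, , , b, drop = FALSE], training = FALSE)
    out[b] <- r$logits
  }
  out
}

batch_idx <- function(n, batch_size, shuffle = TRUE, drop_min = 1) {
  idx <- if (shuffle) sample.int(n) else seq_len(n)
  starts <- seq(1, n, by = batch_size)
  batches <- lapply(starts, function(s) idx[s:min(s + batch_size - 1, n)])
  batches[vapply(batches, length, integer(1)) >= drop_min]
}

new_train_result <- function(train_losses, val_losses, best_epoch, stopped_epoch,
                             model_name) {
  structure(list(train_losses = train_losses, val_losses = val_losses,
                 best_epoch = best_epoch,
                 stopped_epoch = if (is.na(stopped_epoch)) length(val_losses) else stopped_epoch,
                 best_val_loss = min(val_losses), model = model_name),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result '%s': %d epochs (best %d), best val loss %.4f>\n",
              x$model, length(x$val_losses), x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' Train the teacher network
#'
#' Binary cross-entropy on the train split, Adam, early stopping on the
#' validation task loss; the best-validation model state is restored before
#' returning.
#'
#' @param archive a `feature_archive` with train and val splits.
#' @param config a [distill_config()] (the method field is ignored; the
#'   protocol fields are used).
#' @param width_mult teacher width multiplier (1 = the published-scale model).
#' @param verbose print per-epoch losses.
#' @return List with `model` (trained `vad_model`) and `result`
#'   (`train_result`).
#' @export
train_teacher <- function(archive, config = distill_config(), width_mult = 1,
                          verbose = FALSE) {
  model <- build_teacher(width_mult = width_mult, seed = config$seed)
  train_model(model, archive, config, loss_spec = list(kind = "task"),
              verbose = verbose)
}

#' Train a student under a distillation objective
#'
#' The teacher is frozen (eval mode, no gradient); its logits — and, depending
#' on the method, hint feature maps or embeddings — are precomputed once over
#' the train split. The student minimizes the composite loss of the configured
#' method; validation early stopping monitors the task loss only.
#'
#' @param student a freshly built (or pre-initialized) student `vad_model`.
#' @param teacher a trained teacher `vad_model` (left untouched).
#' @param archive a `feature_archive` with train and val splits.
#' @param config a [distill_config()].
#' @param verbose print per-epoch losses.
#' @return List with `model`, `result`, and (feature method) `regressor`.
#' @export
train_student <- function(student, teacher, archive, config = distill_config(),
                          verbose = FALSE) {
  if (!inherits(student, "vad_model") || !inherits(teacher, "vad_model")) {
    abort_invalid("train_student: student and teacher must be vad_models")
  }
  tr <- archive_split(archive, "train")
  # precompute frozen-teacher signals over the train split
  n <- dim(tr$features)[4]
  t_logits <- numeric(n)
  t_hint <- NULL
  t_emb <- NULL
  need_hint <- config$method == "feature_based"
  need_emb <- config$method == "relational"
  hint_name <- teacher$taps[["hint"]]
  for (b in batch_idx(n, config$batch_size, shuffle = FALSE)) {
    r <- model_forward(teacher, tr$features[, , , b, drop = FALSE],
                       training = FALSE,
                       collect = c(if (need_hint) hint_name,
                                   if (need_emb) teacher$embed_layer))
    t_logits[b] <- r$logits
    if (need_hint) {
      hm <- r$acts[[hint_name]]
      if (is.null(t_hint)) t_hint <- array(0, dim = c(dim(hm)[1:3], n))
      t_hint[, , , b] <- hm
    }
    if (need_emb) {
      em <- r$acts[[teacher$embed_layer]]
      if (is.null(t_emb)) t_emb <- matrix(0, nrow(em), n)
      t_emb[, b] <- em
    }
  }
  loss_spec <- list(kind = config$method, t_logits = t_logits, t_hint = t_hint,
                    t_emb = t_emb)
  if (need_hint) {
    guide_name <- student$taps[["guide"]]
    guide_shape <- tap_shape(student, guide_name)
    hint_shape <- dim(t_hint)[1:3]
    loss_spec$regressor <- make_regressor(guide_shape, hint_shape,
                                          seed = config$seed)
    loss_spec$guide_name <- guide_name
  }
  if (need_emb) loss_spec$embed_name <- student$embed_layer
  train_model(student, archive, config, loss_spec, verbose = verbose)
}

tap_shape <- function(model, layer_name) {
  shp <- model$input_shape
  for (nm in names(model$layers)) {
    shp <- layer_out_shape(model$layers[[nm]], shp)
    if (nm == layer_name) return(shp)
  }
  abort_invalid("tap_shape: no layer named ", layer_name)
}

# Shared optimizer loop. loss_spec$kind in {task, soft_target, feature_based,
# relational}; teacher-side signals are constants indexed by training-set row.
train_model <- function(model, archive, config, loss_spec, verbose = FALSE) {
  tr <- archive_split(archive, "train")
  va <- archive_split(archive, "val")
  n <- dim(tr$features)[4]
  if (n == 0 || dim(va$features)[4] == 0) abort_invalid("train_model: empty split")

  params <- nn_params(model)
  has_reg <- !is.null(loss_spec$regressor)
  if (has_reg) {
    params$`regressor/w` <- loss_spec$regressor$conv$params$w
    params$`regressor/b` <- loss_spec$regressor$conv$params$b
  }
  opt <- adam_init(params)
  train_losses <- numeric(0)
  val_losses <- numeric(0)
  best <- Inf
  best_epoch <- 0L
  best_state <- NULL
  stopped <- NA_integer_
  alpha <- config$alpha %||% 1

  withr::local_seed(derive_seed(config$seed, paste0("train_", model$name)))
  for (epoch in seq_len(config$max_epochs)) {
    batch_losses <- numeric(0)
    for (b in batch_idx(n, config$batch_size, drop_min = 4)) {
      x <- tr$features[, , , b, drop = FALSE]
      y <- tr$labels[b]
      collect <- c(if (!is.null(loss_spec$guide_name)) loss_spec$guide_name,
                   if (!is.null(loss_spec$embed_name)) loss_spec$embed_name)
      fw <- model_forward(model, x, training = TRUE, collect = collect)
      model <- fw$model
      z <- fw$logits
      tap_grads <- list()
      fh <- NULL
      loss <- switch(loss_spec$kind,
        task = {
          g_logits <- task_loss_grad(z, y)
          task_loss(z, y)
        },
        soft_target = {
          zt <- loss_spec$t_logits[b]
          g_logits <- soft_target_loss_grad(z, zt, y, config$temperature, alpha)
          soft_target_loss(z, zt, y, config$temperature, alpha)
        },
        feature_based = {
          g_logits <- alpha * task_loss_grad(z, y)
          guide <- fw$acts[[loss_spec$guide_name]]
          hint <- loss_spec$t_hint[, , , b, drop = FALSE]
          fh <- feature_hint_grad(guide, hint, loss_spec$regressor)
          tap_grads[[loss_spec$guide_name]] <- (1 - alpha) * fh$g_guide
          alpha * task_loss(z, y) + (1 - alpha) * fh$loss
        },
        relational = {
          g_logits <- alpha * task_loss_grad(z, y)
          Es <- t(fw$acts[[loss_spec$embed_name]])
          Et <- t(loss_spec$t_emb[, b, drop = FALSE])
          rd <- rkd_distance_grad(Es, Et)
          ra <- rkd_angle_grad(Es, Et)
          g_emb <- (1 - alpha) * (config$lambda_d * rd$g + config$lambda_a * ra$g)
          tap_grads[[loss_spec$embed_name]] <- t(g_emb)
          alpha * task_loss(z, y) +
            (1 - alpha) * (config$lambda_d * rd$loss + config$lambda_a * ra$loss)
        },
        abort_invalid("train_model: unknown loss kind ", loss_spec$kind)
      )
      grads <- model_backward(model, fw$caches, g_logits, tap_grads)
      if (has_reg && !is.null(fh)) {
        grads$`regressor/w` <- (1 - alpha) * fh$g_regressor$`regressor/w`
        grads$`regressor/b` <- (1 - alpha) * fh$g_regressor$`regressor/b`
      }
      cur <- nn_params(model)
      if (has_reg) {
        cur$`regressor/w` <- loss_spec$regressor$conv$params$w
        cur$`regressor/b` <- loss_spec$regressor$conv$params$b
      }
      st <- adam_step(cur, grads, opt, lr = config$learning_rate)
      opt <- st$state
      upd <- st$params
      if (has_reg) {
        loss_spec$regressor$conv$params$w <- upd$`regressor/w`
        loss_spec$regressor$conv$params$b <- upd$`regressor/b`
        upd$`regressor/w` <- NULL
        upd$`regressor/b` <- NULL
      }
      model <- nn_set_params(model, upd)
      batch_losses <- c(batch_losses, loss)
    }
    train_losses <- c(train_losses, mean(batch_losses))
    val_logits <- model_logits(model, va$features, config$batch_size)
    vloss <- task_loss(val_logits, va$labels)
    val_losses <- c(val_losses, vloss)
    if (verbose) {
      message(sprintf("[%s] epoch %d: train %.4f, val %.4f", model$name, epoch,
                      mean(batch_losses), vloss))
    }
    if (vloss < best) {
      best <- vloss
      best_epoch <- epoch
      best_state <- model
    } else if (epoch - best_epoch >= config$patience) {
      stopped <- epoch
      break
    }
  }
  result <- new_train_result(train_losses, val_losses, best_epoch, stopped,
                             model$name)
  out <- list(model = best_state, result = result)
  if (has_reg) out$regressor <- loss_spec$regressor
  out
}
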