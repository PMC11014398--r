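## Distillation objectives and the training protocol.
##
## The classifier heads output a single logit, so temperature softening uses
## the Bernoulli form sigma(z/T): the knowledge-distillation term is
## T^2 * KL( Bern(sigma(z_t/T)) || Bern(sigma(z_s/T)) ), which is zero at
## z_s = z_t and degenerates to the classic two-class softmax formulation.
## Composite losses are alpha * task + (1 - alpha) * distillation. Every loss
## has an analytic gradient (checked against finite differences in the test
## suite) used by the Adam training loop.

sigmoid <- function(z) 1 / (1 + exp(-z))

# log(1 + exp(z)) without overflow
log1pexp <- function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30))))

#' Distillation training configuration
#'
#' Defaults follow the established protocol for this task: temperature 5,
#' alpha 0.2, Adam at learning rate 0.001, batch size 32, at most 50 epochs,
#' early stopping patience 3.
#'
#' @param method `"soft_target"`, `"feature_based"`, or `"relational"`.
#' @param temperature softening temperature T (> 0).
#' @param alpha weight of the task (ground-truth) loss in `[0, 1]`.
#' @param learning_rate,batch_size,max_epochs,patience training protocol.
#' @param lambda_d,lambda_a relational term weights (distance, angle).
#' @param seed training seed (shuffling, dropout, initialization downstream).
#' @return A `distill_config` list.
#' @export
distill_config <- function(method = c("soft_target", "feature_based", "relational"),
                           temperature = 5, alpha = 0.2, learning_rate = 0.001,
                           batch_size = 32, max_epochs = 50, patience = 3,
                           lambda_d = 1, lambda_a = 2, seed = 0) {
  method <- match.arg(method)
  if (temperature <= 0) abort_invalid("distill_config: temperature must be > 0")
  if (alpha < 0 || alpha > 1) abort_invalid("distill_config: alpha must be in [0, 1]")
  if (patience < 1) abort_invalid("distill_config: patience must be >= 1")
  structure(as.list(environment()), class = "distill_config")
}

## ---- losses -----------------------------------------------------------------

#' Binary cross-entropy task loss from raw logits
#'
#' Numerically stable mean BCE-with-logits:
#' `mean(log(1 + exp(z)) - y * z)`.
#'
#' @param logits numeric vector of raw logits.
#' @param labels 0/1 vector of the same length.
#' @return Scalar loss.
#' @export
task_loss <- function(logits, labels) {
  if (length(logits) == 0) abort_invalid("task_loss: empty batch")
  if (length(logits) != length(labels)) abort_invalid("task_loss: length mismatch")
  if (!all(labels %in% c(0, 1))) abort_invalid("task_loss: labels must be 0/1")
  mean(log1pexp(logits) - labels * logits)
}

#' @rdname task_loss
#' @export
task_loss_grad <- function(logits, labels) {
  (sigmoid(logits) - labels) / length(logits)
}

#' Soft-target (response-based) distillation loss
#'
#' `alpha * task + (1 - alpha) * T^2 * mean KL(Bern(sigma(z_t/T)) || Bern(sigma(z_s/T)))`.
#' Teacher logits are treated as constants.
#'
#' @param student_logits,teacher_logits raw logit vectors.
#' @param labels 0/1 vector.
#' @param temperature softening temperature T (> 0).
#' @param alpha task-loss weight.
#' @return Scalar loss.
#' @export
soft_target_loss <- function(student_logits, teacher_logits, labels,
                             temperature = 5, alpha = 0.2) {
  if (temperature <= 0) abort_invalid("soft_target_loss: temperature must be > 0")
  kd <- mean(bernoulli_kl(sigmoid(teacher_logits / temperature),
                          student_logits / temperature)) * temperature^2
  alpha * task_loss(student_logits, labels) + (1 - alpha) * kd
}

# KL(Bern(p) || Bern(sigma(zs))) written against the student logit for
# stability: -p*zs + log(1+exp(zs)) + p*log(p) + (1-p)*log(1-p)
bernoulli_kl <- function(p, zs) {
  ent <- ifelse(p <= 0 | p >= 1, 0, p * log(p) + (1 - p) * log(1 - p))
  -p * zs + log1pexp(zs) + ent
}

#' @rdname soft_target_loss
#' @export
soft_target_loss_grad <- function(student_logits, teacher_logits, labels,
                                  temperature = 5, alpha = 0.2) {
  n <- length(student_logits)
  g_task <- (sigmoid(student_logits) - labels) / n
  g_kd <- temperature * (sigmoid(student_logits / temperature) -
                           sigmoid(teacher_logits / temperature)) / n
  alpha * g_task + (1 - alpha) * g_kd
}

#' Feature (hint/guide) distillation loss
#'
#' Half mean squared error between a teacher hint feature map and a learned
#' regression of the student guide map: the guide is passed through a 1x1
#' convolution (the regressor, trained jointly with the student) and, if
#' spatial sizes differ, bilinearly resized to the hint's grid.
#'
#' @param guide student feature map, array `(H, W, C_s, N)`.
#' @param hint teacher feature map, array `(H', W', C_t, N)` (constant).
#' @param regressor a regressor created by [make_regressor()]; `"identity"`
#'   compares the maps directly (shapes must then match).
#' @return Scalar loss; use [feature_hint_grad()] for gradients.
#' @export
feature_hint_loss <- function(guide, hint, regressor = "identity") {
  feature_hint_grad(guide, hint, regressor)$loss
}

#' @rdname feature_hint_loss
#' @param lr unused here; gradients are returned for the caller's optimizer.
#' @return `feature_hint_grad`: list with `loss`, `g_guide` (gradient w.r.t.
#'   the guide map) and `g_regressor` (named parameter gradients).
#' @export
feature_hint_grad <- function(guide, hint, regressor = "identity") {
  if (identical(regressor, "identity")) {
    if (!all(dim(guide) == dim(hint))) {
      abort_invalid("feature_hint_loss: shape mismatch under identity regressor")
    }
    d <- guide - hint
    return(list(loss = 0.5 * mean(d^2), g_guide = d / length(d),
                g_regressor = list()))
  }
  fw <- layer_forward(regressor$conv, guide, training = FALSE)
  pred <- fw$out
  if (!is.null(regressor$resize)) pred <- resize_apply(regressor$resize, pred)
  if (!all(dim(pred) == dim(hint))) {
    abort_invalid("feature_hint_loss: regressed guide shape ",
                  paste(dim(pred), collapse = "x"), " != hint shape ",
                  paste(dim(hint), collapse = "x"))
  }
  d <- pred - hint
  loss <- 0.5 * mean(d^2)
  g <- d / length(d)
  if (!is.null(regressor$resize)) g <- resize_backward(regressor$resize, g, dim(fw$out))
  bw <- layer_backward(regressor$conv, fw$cache, g)
  list(loss = loss, g_guide = bw$gx,
       g_regressor = stats::setNames(bw$grads, paste0("regressor/", names(bw$grads))))
}

#' Create a hint/guide regressor
#'
#' A 1x1 convolution mapping the guide's channels to the hint's, plus a
#' bilinear spatial resize when the grids differ.
#'
#' @param guide_shape,hint_shape shapes `c(H, W, C)`.
#' @param seed initialization seed.
#' @return A regressor object for [feature_hint_loss()].
#' @export
make_regressor <- function(guide_shape, hint_shape, seed = 0) {
  conv <- with_seed(derive_seed(seed, "regressor"),
                    nn_conv2d(guide_shape[3], hint_shape[3], kernel = 1, bias = TRUE))
  resize <- NULL
  if (!all(guide_shape[1:2] == hint_shape[1:2])) {
    resize <- make_bilinear(guide_shape[1:2], hint_shape[1:2])
  }
  list(conv = conv, resize = resize, guide_shape = guide_shape,
       hint_shape = hint_shape)
}

# Bilinear resize as a sparse linear map on the flattened spatial plane.
make_bilinear <- function(from_hw, to_hw) {
  w1 <- interp_weights(from_hw[1], to_hw[1])
  w2 <- interp_weights(from_hw[2], to_hw[2])
  # R[(ho,wo),(hi,wi)] = w1[ho,hi] * w2[wo,wi]; Kronecker keeps H fastest
  R <- Matrix::kronecker(w2, w1)
  list(R = R, from_hw = from_hw, to_hw = to_hw)
}

interp_weights <- function(n_in, n_out) {
  pos <- if (n_out == 1) (n_in + 1) / 2 else seq(1, n_in, length.out = n_out)
  i0 <- pmin(floor(pos), n_in)
  i1 <- pmin(i0 + 1, n_in)
  w <- pos - i0
  Matrix::sparseMatrix(i = c(seq_len(n_out), seq_len(n_out)), j = c(i0, i1),
                       x = c(1 - w, w), dims = c(n_out, n_in))
}

resize_apply <- function(rs, x) {
  dm <- dim(x)
  m <- matrix(x, nrow = dm[1] * dm[2])
  y <- as.matrix(rs$R %*% m)
  array(y, dim = c(rs$to_hw, dm[3], dm[4]))
}

resize_backward <- function(rs, gy, in_dim) {
  dm <- dim(gy)
  m <- matrix(gy, nrow = dm[1] * dm[2])
  gx <- as.matrix(Matrix::t(rs$R) %*% m)
  array(gx, dim = in_dim)
}

## ---- relational (RKD) losses -------------------------------------------------

huber <- function(r, delta = 1) {
  a <- abs(r)
  ifelse(a <= delta, 0.5 * r^2, delta * (a - 0.5 * delta))
}

huber_d <- function(r, delta = 1) pmin(pmax(r, -delta), delta)

pairwise_dist <- function(E) {
  # E: n x d matrix of embeddings (rows are samples)
  G <- tcrossprod(E)
  sq <- diag(G)
  D2 <- pmax(outer(sq, sq, "+") - 2 * G, 0)
  sqrt(D2)
}

#' Relational distance-wise distillation loss
#'
#' Pairwise distances within a batch, normalized by their batch mean
#' (separately for student and teacher), compared with a Huber penalty
#' (delta = 1) over unordered pairs. Invariant to translation, rotation, and
#' uniform scaling of either embedding set. A batch where all points coincide
#' (mean distance 0) contributes zero loss.
#'
#' @param E_s,E_t student and teacher embedding matrices (`n x d`, rows are
#'   samples; `d` may differ between the two).
#' @return Scalar loss.
#' @export
rkd_distance_loss <- function(E_s, E_t) {
  rkd_distance_grad(E_s, E_t)$loss
}

#' @rdname rkd_distance_loss
#' @return `rkd_distance_grad`: list with `loss` and `g` (gradient w.r.t.
#'   `E_s`).
#' @export
rkd_distance_grad <- function(E_s, E_t) {
  E_s <- as.matrix(E_s); E_t <- as.matrix(E_t)
  n <- nrow(E_s)
  if (n < 2 || nrow(E_t) != n) abort_invalid("rkd_distance: need matched batches of >= 2")
  Ds <- pairwise_dist(E_s)
  Dt <- pairwise_dist(E_t)
  up <- upper.tri(Ds)
  P <- sum(up)
  mu_s <- mean(Ds[up])
  mu_t <- mean(Dt[up])
  if (mu_s == 0 || mu_t == 0) {
    return(list(loss = 0, g = E_s * 0))
  }
  psi_s <- Ds / mu_s
  psi_t <- Dt / mu_t
  r <- psi_s - psi_t
  loss <- mean(huber(r[up]))
  # dL/d psi_s (symmetric matrix over pairs; each unordered pair counted once)
  gpsi <- huber_d(r) / P
  gpsi[!up & !lower.tri(gpsi)] <- 0
  gpsi[lower.tri(gpsi)] <- t(gpsi)[lower.tri(gpsi)]   # symmetrize
  # dL/dD = gpsi/mu - (sum_{i<j} gpsi_ij * D_ij) / (mu^2 * P)  per pair
  s_gd <- sum((gpsi * Ds)[up])
  gD <- gpsi / mu_s - s_gd / (mu_s^2 * P)
  gD[!up & !lower.tri(gD)] <- 0
  gD[lower.tri(gD)] <- t(gD)[lower.tri(gD)]
  # dD_ij/dE_i = (e_i - e_j)/D_ij
  # dD_ij/dE_i = (e_i - e_j)/D_ij; with symmetric W_ij = gD_ij / D_ij the
  # gradient collapses to a graph-Laplacian form.
  Dsafe <- Ds + diag(n)
  W <- gD / Dsafe
  diag(W) <- 0
  W[Ds == 0] <- 0
  g <- (diag(rowSums(W), n) - W) %*% E_s
  list(loss = loss, g = g)
}

#' Relational angle-wise distillation loss
#'
#' For every ordered triple (i, j, k) of distinct batch indices, the cosine of
#' the angle at j between (e_i - e_j) and (e_k - e_j) is compared between
#' teacher and student with a Huber penalty (delta = 1). Invariant to
#' similarity transforms. Triples with a zero-length difference contribute 0.
#'
#' @param E_s,E_t student and teacher embedding matrices (`n x d`).
#' @return Scalar loss.
#' @export
rkd_angle_loss <- function(E_s, E_t) {
  rkd_angle_grad(E_s, E_t)$loss
}

#' @rdname rkd_angle_loss
#' @return `rkd_angle_grad`: list with `loss` and `g`.
#' @export
rkd_angle_grad <- function(E_s, E_t) {
  E_s <- as.matrix(E_s); E_t <- as.matrix(E_t)
  n <- nrow(E_s)
  if (n < 3 || nrow(E_t) != n) abort_invalid("rkd_angle: need matched batches of >= 3")
  cs <- angle_cosines(E_s)
  ct <- angle_cosines(E_t)
  # count: ordered triples (i, j, k), i != j, k != j, i != k; the cosine is
  # symmetric in (i, k) so each unordered {i,k} pair appears twice
  valid <- cs$valid & ct$valid
  Tn <- n * (n - 1) * (n - 2)
  r <- cs$cos - ct$cos
  loss <- sum(huber(r[valid])) / Tn
  # gradient
  g <- matrix(0, n, ncol(E_s))
  h <- huber_d(r) / Tn
  h[!valid] <- 0
  for (j in seq_len(n)) {
    A <- cs$unit[, , j]            # n x d rows: (e_i - e_j)/|.|  (row j zero)
    Linv <- cs$len_inv[, j]        # 1/|e_i - e_j|, 0 where degenerate
    Hj <- h[, , j]                 # n x n: entry [i, k]
    Cj <- cs$cos[, , j]
    HA <- Hj %*% A                                 # sum_k h[i,k] u_kj
    rowHC <- rowSums(Hj * Cj)
    Gi <- (HA - A * rowHC) * Linv                  # d cos / d e_i parts
    HtA <- t(Hj) %*% A                             # sum_i h[i,k] u_ij
    colHC <- colSums(Hj * Cj)
    Gk <- (HtA - A * colHC) * Linv
    g <- g + Gi + Gk
    g[j, ] <- g[j, ] - colSums(Gi) - colSums(Gk)
  }
  list(loss = loss, g = g)
}

# For each centre j: unit difference vectors u_ij = (e_i - e_j)/|e_i - e_j|
# and the cosine array cos[i, k, j] = <u_ij, u_kj>.
angle_cosines <- function(E) {
  n <- nrow(E)
  unit <- array(0, dim = c(n, ncol(E), n))
  len_inv <- matrix(0, n, n)
  cosarr <- array(0, dim = c(n, n, n))
  valid <- array(FALSE, dim = c(n, n, n))
  for (j in seq_len(n)) {
    D <- sweep(E, 2, E[j, ])
    len <- sqrt(rowSums(D^2))
    li <- ifelse(len > 1e-12, 1 / len, 0)
    U <- D * li
    unit[, , j] <- U
    len_inv[, j] <- li
    Cj <- tcrossprod(U)
    cosarr[, , j] <- Cj
    ok <- li > 0
    v <- outer(ok, ok, "&")
    diag(v) <- FALSE                       # i == k excluded
    v[j, ] <- FALSE; v[, j] <- FALSE       # i == j or k == j excluded
    valid[, , j] <- v
  }
  list(unit = unit, len_inv = len_inv, cos = cosarr, valid = valid)
}

#' Combined relational distillation loss
#'
#' `alpha * task + (1 - alpha) * (lambda_d * distance + lambda_a * angle)`.
#'
#' @param student_logits raw student logits.
#' @param E_s,E_t embedding matrices (`n x d`).
#' @param labels 0/1 vector.
#' @param alpha task weight.
#' @param lambda_d,lambda_a relational term weights (defaults 1 and 2).
#' @return Scalar loss.
#' @export
relational_loss <- function(student_logits, E_s, E_t, labels, alpha = 0.2,
                            lambda_d = 1, lambda_a = 2) {
  alpha * task_loss(student_logits, labels) +
    (1 - alpha) * (lambda_d * rkd_distance_loss(E_s, E_t) +
                     lambda_a * rkd_angle_loss(E_s, E_t))
}

## ---- early stopping ----------------------------------------------------------

#' Early-stopping decision
#'
#' Stop once `patience` consecutive epochs fail to strictly improve on the
#' best validation loss seen so far.
#'
#' @param val_losses numeric vector of per-epoch validation losses (>= 1).
#' @param patience consecutive non-improving epochs tolerated.
#' @return List with `stop` (logical), `best_epoch`, `stopped_epoch` (the
#'   epoch after which training stops, `NA` if it never would).
#' @export
early_stop <- function(val_losses, patience = 3) {
  if (length(val_losses) < 1) abort_invalid("early_stop: need at least one epoch")
  best <- Inf
  best_epoch <- 0L
  since <- 0L
  stopped <- NA_integer_
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      best_epoch <- e
      since <- 0L
    } else {
      since <- since + 1L
      if (since >= patience && is.na(stopped)) stopped <- e
    }
  }
  list(stop = !is.na(stopped), best_epoch = best_epoch, stopped_epoch = stopped)
}
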