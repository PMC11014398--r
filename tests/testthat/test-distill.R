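# Distillation losses: closed forms, independent oracles, gradient agreement,
# invariances, and the early-stopping contract.

test_that("task loss matches closed forms", {
  expect_equal(task_loss(0, 1), log(2), tolerance = 1e-12)
  expect_lt(task_loss(20, 1), 1e-8)
  # batch mean of two symmetric items equals the single-item value
  expect_equal(task_loss(c(1.3, -1.3), c(1, 0)), task_loss(1.3, 1))
  expect_error(task_loss(numeric(0), numeric(0)),
               class = "ecodistill_invalid_argument")
  expect_error(task_loss(c(0, 0), c(0, 2)), class = "ecodistill_invalid_argument")
})

test_that("soft-target loss: endpoints, zero-gap distillation, scalar oracle", {
  # z_s = z_t: distillation term vanishes for any T, alpha
  for (T in c(1, 5)) {
    expect_equal(soft_target_loss(1.7, 1.7, 1, T, 0.3),
                 0.3 * task_loss(1.7, 1), tolerance = 1e-12)
  }
  # alpha = 1 reduces to the task loss
  expect_equal(soft_target_loss(0.4, -2, 0, 5, 1), task_loss(0.4, 0))
  # term-by-term Bernoulli-KL oracle at z_t = 2, z_s = 0, y = 1, T = 5
  T <- 5; alpha <- 0.2
  pt <- 1 / (1 + exp(-2 / T)); ps <- 1 / (1 + exp(0))
  kl <- pt * log(pt / ps) + (1 - pt) * log((1 - pt) / (1 - ps))
  oracle <- alpha * log(2) + (1 - alpha) * T^2 * kl
  expect_equal(soft_target_loss(0, 2, 1, T, alpha), oracle, tolerance = 1e-12)
  expect_error(soft_target_loss(0, 2, 1, temperature = 0),
               class = "ecodistill_invalid_argument")
  # distillation term shrinks monotonically as the logit gap closes
  gaps <- c(2, 1, 0.5, 0.1)
  vals <- vapply(gaps, function(g) soft_target_loss(1 + g, 1, 1, 5, 0), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("feature hint loss: closed forms and element-wise oracle", {
  g <- array(rnorm(2 * 2 * 2 * 2), c(2, 2, 2, 2))
  expect_equal(feature_hint_loss(g, g), 0)
  expect_equal(feature_hint_loss(g, g + 3), 0.5 * 9, tolerance = 1e-12)
  withr::local_seed(1)
  hint <- array(rnorm(16), c(2, 2, 2, 2))
  # element-wise brute force
  expect_equal(feature_hint_loss(g, hint), sum((g - hint)^2) / (2 * 16),
               tolerance = 1e-12)
  expect_error(feature_hint_loss(g, array(0, c(3, 3, 2, 2))),
               class = "ecodistill_invalid_argument")
})

test_that("hint regressor maps guide shape to hint shape with valid gradients", {
  withr::local_seed(2)
  guide <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  hint <- array(rnorm(4 * 4 * 5 * 2), c(4, 4, 5, 2))
  reg <- make_regressor(c(8, 8, 3), c(4, 4, 5), seed = 1)
  r <- feature_hint_grad(guide, hint, reg)
  expect_gt(r$loss, 0)
  # finite-difference check on the guide gradient
  f <- function(gg) feature_hint_loss(gg, hint, reg)
  idx <- sample(length(guide), 5)
  for (i in idx) {
    gp <- guide; gp[i] <- gp[i] + 1e-6
    gm <- guide; gm[i] <- gm[i] - 1e-6
    expect_equal(r$g_guide[i], (f(gp) - f(gm)) / 2e-6, tolerance = 1e-4)
  }
})

test_that("RKD distance: zero at equality, similarity invariance, 3-point oracle", {
  withr::local_seed(3)
  E <- matrix(rnorm(12), 4, 3)
  expect_equal(rkd_distance_loss(E, E), 0)
  expect_equal(rkd_distance_loss(3 * E + 2, E), 0, tolerance = 1e-12)
  # 3-point integer toy sets, hand-enumerated over the 3 pairs
  Es <- matrix(c(0, 0, 3, 0, 0, 4), 3, 2, byrow = TRUE)
  Et <- matrix(c(0, 0, 1, 0, 0, 2), 3, 2, byrow = TRUE)
  ds <- c(3, 4, 5); dt <- c(1, 2, sqrt(5))
  ps <- ds / mean(ds); pt <- dt / mean(dt)
  r <- pt - ps
  hub <- ifelse(abs(r) <= 1, r^2 / 2, abs(r) - 0.5)
  expect_equal(rkd_distance_loss(Es, Et), mean(hub), tolerance = 1e-12)
  expect_error(rkd_distance_loss(E[1, , drop = FALSE], E[1, , drop = FALSE]),
               class = "ecodistill_invalid_argument")
  # all-identical points define zero loss
  Z <- matrix(1, 4, 3)
  expect_equal(rkd_distance_loss(Z, E), 0)
})

test_that("RKD angle: zero at equality and under similarity transforms; oracle", {
  withr::local_seed(4)
  E <- matrix(rnorm(12), 4, 3)
  expect_equal(rkd_angle_loss(E, E), 0)
  th <- 0.6
  R <- diag(3); R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(rkd_angle_loss(2.5 * E %*% R + 7, E), 0, tolerance = 1e-10)
  # right angle vs collinear points, enumerated over ordered triples
  Es <- matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)   # right angle at e1
  Et <- matrix(c(0, 0, 1, 0, 2, 0), 3, 2, byrow = TRUE)   # collinear
  oracle <- local({
    cosine <- function(E, i, j, k) {
      u <- E[i, ] - E[j, ]; w <- E[k, ] - E[j, ]
      sum(u * w) / (sqrt(sum(u^2)) * sqrt(sum(w^2)))
    }
    tot <- 0; cnt <- 0
    for (i in 1:3) for (j in 1:3) for (k in 1:3) {
      if (i == j || k == j || i == k) next
      r <- cosine(Es, i, j, k) - cosine(Et, i, j, k)
      tot <- tot + ifelse(abs(r) <= 1, r^2 / 2, abs(r) - 0.5)
      cnt <- cnt + 1
    }
    tot / cnt
  })
  expect_equal(rkd_angle_loss(Es, Et), oracle, tolerance = 1e-12)
  expect_error(rkd_angle_loss(E[1:2, ], E[1:2, ]),
               class = "ecodistill_invalid_argument")
})

test_that("relational composite reduces correctly and composes its parts", {
  withr::local_seed(5)
  Es <- matrix(rnorm(12), 4, 3)
  Et <- matrix(rnorm(12), 4, 3)
  z <- rnorm(4); y <- c(0, 1, 1, 0)
  expect_equal(relational_loss(z, Es, Et, y, alpha = 1), task_loss(z, y))
  # similarity transform of the teacher: both relational terms vanish
  expect_equal(relational_loss(z, 2 * Et + 1, Et, y, alpha = 0.2),
               0.2 * task_loss(z, y), tolerance = 1e-10)
  lam_d <- 0.7; lam_a <- 1.9; alpha <- 0.3
  expect_equal(relational_loss(z, Es, Et, y, alpha, lam_d, lam_a),
               alpha * task_loss(z, y) +
                 (1 - alpha) * (lam_d * rkd_distance_loss(Es, Et) +
                                  lam_a * rkd_angle_loss(Es, Et)),
               tolerance = 1e-12)
})

test_that("loss gradients agree with finite differences on 3-sample batches", {
  withr::local_seed(6)
  z <- rnorm(3); zt <- rnorm(3); y <- c(1, 0, 1)
  expect_rel_equal(task_loss_grad(z, y),
                   num_grad(function(zz) task_loss(zz, y), z))
  expect_rel_equal(soft_target_loss_grad(z, zt, y, 5, 0.2),
                   num_grad(function(zz) soft_target_loss(zz, zt, y, 5, 0.2), z))
  Es <- matrix(rnorm(9), 3, 3); Et <- matrix(rnorm(9), 3, 3)
  expect_rel_equal(rkd_distance_grad(Es, Et)$g,
                   num_grad(function(E) rkd_distance_loss(E, Et), Es))
  expect_rel_equal(rkd_angle_grad(Es, Et)$g,
                   num_grad(function(E) rkd_angle_loss(E, Et), Es))
})

test_that("early stopping follows patience-k semantics", {
  r <- early_stop(c(1.0, 0.9, 0.91, 0.92, 0.93), patience = 3)
  expect_true(r$stop)
  expect_equal(r$best_epoch, 2L)
  expect_equal(r$stopped_epoch, 5L)
  r2 <- early_stop(c(1.0, 1.1, 1.2, 1.3), patience = 3)
  expect_true(r2$stop)
  expect_equal(r2$best_epoch, 1L)
  expect_equal(r2$stopped_epoch, 4L)
  r3 <- early_stop(seq(1, 0.5, length.out = 10), patience = 3)
  expect_false(r3$stop)
  expect_equal(r3$best_epoch, 10L)
  expect_error(early_stop(numeric(0)), class = "ecodistill_invalid_argument")
})

test_that("distill_config validates its invariants", {
  cfg <- distill_config()
  expect_equal(cfg$temperature, 5)
  expect_equal(cfg$alpha, 0.2)
  expect_equal(cfg$learning_rate, 0.001)
  expect_equal(cfg$batch_size, 32)
  expect_equal(cfg$max_epochs, 50)
  expect_equal(cfg$patience, 3)
  expect_error(distill_config(temperature = 0), class = "ecodistill_invalid_argument")
  expect_error(distill_config(alpha = 1.2), class = "ecodistill_invalid_argument")
  expect_error(distill_config(patience = 0), class = "ecodistill_invalid_argument")
})
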