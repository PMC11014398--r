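# Architectures and resource accounting.

test_that("teacher parameter count equals the closed-form layer sum", {
  teacher <- full_teacher()
  # closed form: conv weights+biases, BN scale+shift, FC weights+biases
  conv_ch <- c(64, 128, 256, 256, 512, 512, 512, 512)
  ins <- c(1, conv_ch[-8])
  conv_p <- sum(9 * ins * conv_ch + conv_ch)
  bn_p <- sum(2 * conv_ch)
  fc_p <- (8192 * 4096 + 4096) + (4096 * 4096 + 4096) + (4096 + 1)
  expect_equal(conv_p, 9219328)
  expect_equal(bn_p, 5504)
  expect_equal(count_parameters(teacher), conv_p + bn_p + fc_p)
  expect_equal(count_parameters(teacher), 59568769)
})

test_that("teacher convolutional stack reduces 128x128 to 512 x 4 x 4", {
  teacher <- build_teacher(width_mult = 0.125)  # shape logic is width-invariant
  shp <- teacher$input_shape
  for (nm in names(teacher$layers)) {
    shp <- ecodistill:::layer_out_shape(teacher$layers[[nm]], shp)
    if (nm == "pool5") break
  }
  expect_equal(shp[1:2], c(4, 4))
  full <- full_teacher()
  expect_equal(ecodistill:::tap_shape(full, "pool5"), c(4, 4, 512))
  expect_equal(prod(ecodistill:::tap_shape(full, "pool5")), 8192)
})

test_that("parameter counting matches closed forms on toy layers", {
  lin <- ecodistill:::nn_linear(10, 1)
  expect_equal(sum(vapply(ecodistill:::layer_params(lin), length, numeric(1))), 11)
  conv <- ecodistill:::nn_conv2d(1, 64, 3)
  bn <- ecodistill:::nn_batchnorm2d(64)
  expect_equal(length(conv$params$w) + length(conv$params$b), 640)
  expect_equal(sum(lengths(bn$params)), 128)
})

test_that("MAC counting matches closed forms and the published convention", {
  # single FC 8192 -> 4096, no bias term counted separately
  lin <- ecodistill:::nn_linear(8192, 4096, bias = FALSE)
  expect_equal(ecodistill:::layer_macs(lin, 8192), 8192 * 4096)
  # depthwise 3x3 on C x H x W costs C*H*W*9
  dw <- ecodistill:::nn_conv2d(16, 16, 3, groups = 16, bias = FALSE)
  expect_equal(ecodistill:::layer_macs(dw, c(10, 10, 16)), 16 * 10 * 10 * 9)
  # teacher total within 1% of the published figure
  teacher <- full_teacher()
  macs <- count_macs(teacher)
  expect_lt(abs(macs - 2485390000) / 2485390000, 0.01)
})

test_that("student resource ordering matches the published table", {
  students <- lapply(1:4, build_student)
  params <- vapply(students, count_parameters, numeric(1))
  macs <- vapply(students, count_macs, numeric(1))
  expect_true(all(diff(params) < 0))   # s1 > s2 > s3 > s4
  expect_true(all(diff(macs) < 0))
  mems <- params * 4 / 2^20
  expect_true(all(diff(mems) < 0))
  expect_error(build_student(9), class = "ecodistill_invalid_argument")
})

test_that("students honor their stated stem and channel-range constraints", {
  zoo <- yaml::read_yaml(system.file("extdata", "model_zoo.yaml",
                                     package = "ecodistill"))$students
  ranges <- list(student1 = c(16, 512), student2 = c(16, 512),
                 student3 = c(4, 128), student4 = c(4, 64))
  stems <- c(student1 = 16, student2 = 16, student3 = 4, student4 = 4)
  for (nm in names(zoo)) {
    cfg <- zoo[[nm]]
    expect_equal(cfg$stem, unname(stems[nm]))
    ch <- unlist(lapply(cfg$blocks, function(b) c(b[[1]], b[[2]])))
    expect_gte(min(ch), ranges[[nm]][1])
    expect_lte(max(ch), ranges[[nm]][2])
  }
  # student 2 raises the pre-pool width to 512; student 1 keeps 256
  expect_equal(zoo$student1$last_conv, 256)
  expect_equal(zoo$student2$last_conv, 512)
  # student 2 is the shallower sibling of student 1
  expect_lt(length(zoo$student2$blocks), length(zoo$student1$blocks))
  expect_lt(length(zoo$student4$blocks), length(zoo$student3$blocks))
})

test_that("forward_with_taps exposes hint/guide maps and embeddings", {
  withr::local_seed(4)
  teacher <- build_teacher(width_mult = 0.0625)
  x <- array(rnorm(128 * 128 * 1 * 2), c(128, 128, 1, 2))
  r <- forward_with_taps(teacher, x)
  expect_length(r$logits, 2)
  expect_true(all(is.finite(r$logits)))
  # hint at the third pool: spatial side 128 / 2^3 = 16
  expect_equal(dim(r$taps$hint)[1:2], c(16, 16))
  expect_equal(nrow(r$embedding), ecodistill:::tap_shape(teacher, "fc2_relu"))
  # eval-mode determinism
  r2 <- forward_with_taps(teacher, x)
  expect_identical(r$logits, r2$logits)
  expect_error(forward_with_taps(teacher, x, taps = "nope"),
               class = "ecodistill_invalid_argument")
  for (v in 1:4) {
    s <- build_student(v, width_mult = if (v <= 2) 0.25 else 1)
    rs <- forward_with_taps(s, x[, , , 1, drop = FALSE])
    expect_length(rs$logits, 1)
    expect_true(is.finite(rs$logits))
    expect_equal(dim(rs$taps$guide)[1:2], c(16, 16))
  }
})

test_that("profile reports the table fields with the stated identities", {
  s4 <- build_student(4)
  prof <- profile_model(s4, n_trials = 3)
  expect_equal(prof$mults_table, prof$flops_table / 2)
  expect_equal(prof$params, count_parameters(s4))
  expect_equal(prof$memory_mib, prof$params * 4 / 2^20)
  expect_gt(prof$avg_inference_s, 0)
  prof2 <- profile_model(s4, n_trials = 3)
  expect_equal(prof2$params, prof$params)
  expect_equal(prof2$macs, prof$macs)
  # table truncation convention: whole MiB at >= 10, two decimals below
  expect_equal(ecodistill:::memory_table_mib(59568769), 227)
  expect_equal(ecodistill:::memory_table_mib(502793), 1.91)
  expect_equal(ecodistill:::memory_table_mib(52253), 0.19)
})

test_that("checkpoints round-trip parameters and buffers", {
  withr::local_seed(5)
  m <- build_student(4, seed = 3)
  x <- array(rnorm(128 * 128), c(128, 128, 1, 1))
  # perturb running stats so buffers are non-trivial
  fw <- ecodistill:::model_forward(m, x, training = TRUE)
  m <- fw$model
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path, build_student(4, seed = 99))
  y1 <- ecodistill:::model_logits(m, x)
  y2 <- ecodistill:::model_logits(m2, x)
  expect_identical(y1, y2)
})
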