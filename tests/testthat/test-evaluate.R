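# Evaluation harness: metric closed forms, oracle cross-checks, bootstrap and
# Mann-Whitney behaviour, playback reports, method comparison.

test_that("f1_score matches closed forms", {
  expect_equal(f1_score(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1.0)
  # TP=8, FP=2, FN=2 -> 2*8 / (2*8 + 2 + 2) = 0.8
  labels <- c(rep(1, 10), rep(0, 10))
  preds <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  expect_equal(f1_score(labels, preds), 0.8)
  expect_equal(f1_score(c(1, 1, 0), c(0, 0, 0)), 0)
})

test_that("auc_score implements the rank formulation with tie handling", {
  expect_equal(auc_score(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(auc_score(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  # enumerate the 4 positive-negative pairs: wins 3, losses 1 -> 0.75
  expect_equal(auc_score(c(0, 0, 1, 1), c(0.1, 0.8, 0.4, 0.9)), 0.75)
  expect_error(auc_score(c(1, 1), c(0.2, 0.3)), class = "ecodistill_invalid_argument")
  # order invariance
  withr::local_seed(1)
  labels <- rbinom(50, 1, 0.5); labels[1:2] <- c(0, 1)
  scores <- runif(50)
  perm <- sample(50)
  expect_equal(auc_score(labels, scores), auc_score(labels[perm], scores[perm]))
})

test_that("auc equals the normalized U statistic on tie-free data", {
  withr::local_seed(2)
  labels <- c(rep(1, 12), rep(0, 15))
  scores <- rnorm(27)
  u <- mann_whitney_u(scores[labels == 1], scores[labels == 0])
  expect_equal(auc_score(labels, scores), u$U / (12 * 15))
})

test_that("mann_whitney_u: exact enumeration, identities, oracle cross-check", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)          # 2 of the C(6,3) = 20 labelings are as extreme
  expect_equal(r$method, "exact")
  # identical samples -> p = 1 under the exact method
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1.0)
  # swap identity: U_a + U_b = n_a * n_b, same p
  a <- c(0.3, 1.2, 2.2, 5); b <- c(0.9, 1.4, 3.3)
  ra <- mann_whitney_u(a, b); rb <- mann_whitney_u(b, a)
  expect_equal(ra$U + rb$U, length(a) * length(b))
  expect_equal(ra$p, rb$p)
  # independent oracle: stats::wilcox.test exact p on tie-free samples
  wt <- stats::wilcox.test(a, b, exact = TRUE)
  expect_equal(ra$p, wt$p.value, tolerance = 1e-12)
  expect_equal(ra$U, unname(wt$statistic))
  # large-sample normal path against wilcox.test's corrected approximation
  withr::local_seed(3)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  rn <- mann_whitney_u(x, y)
  wn <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(rn$method, "normal")
  expect_equal(rn$p, wn$p.value, tolerance = 1e-10)
  expect_error(mann_whitney_u(numeric(0), 1), class = "ecodistill_invalid_argument")
})

test_that("bootstrap_median_ci: degenerate and ordering properties", {
  ci <- bootstrap_median_ci(rep(3.5, 10), B = 200, seed = 1)
  expect_equal(unname(ci), c(3.5, 3.5))
  withr::local_seed(4)
  v <- rnorm(25)
  ci2 <- bootstrap_median_ci(v, B = 500, seed = 2)
  expect_lte(ci2[["lower"]], median(v))
  expect_gte(ci2[["upper"]], median(v))
  # deterministic given the seed
  expect_equal(bootstrap_median_ci(v, B = 500, seed = 2), ci2)
  expect_error(bootstrap_median_ci(numeric(0)), class = "ecodistill_invalid_argument")
})

test_that("playback_report: schema, perfect classifier, decay with distance", {
  withr::local_seed(5)
  n <- 160
  rec <- data.frame(label = rep(c(0, 1), n / 2),
                    distance_m = rep(c(1, 5, 10, 20), each = n / 4))
  perfect <- ifelse(rec$label == 1, 0.9, 0.1)
  rep1 <- playback_report(rec, perfect)
  expect_equal(nrow(rep1), 5)
  expect_equal(rep1$distance_m, c("1", "5", "10", "20", "overall"))
  expect_true(all(rep1$f1 == 1))
  # label-correlated score minus distance-proportional noise: F1 non-increasing
  noisy <- pmin(1, pmax(0, 0.5 + (rec$label - 0.5) * (1 - rec$distance_m / 22) +
                          rnorm(n, 0, 0.05)))
  rep2 <- playback_report(rec, noisy)
  f1s <- rep2$f1[1:4]
  expect_true(all(diff(f1s) <= 1e-9))
  expect_error(playback_report(rec[rec$distance_m != 10, ],
                               perfect[rec$distance_m != 10]),
               class = "ecodistill_invalid_argument")
})

test_that("compare_methods summarizes runs and pairwise tests", {
  runs <- list(
    soft = data.frame(auc = c(0.97, 0.98, 0.975), f1 = c(0.95, 0.96, 0.955)),
    feat = data.frame(auc = c(0.97, 0.98, 0.975), f1 = c(0.95, 0.96, 0.955)),
    rel  = data.frame(auc = c(0.96, 0.99, 0.97), f1 = c(0.94, 0.97, 0.95)))
  rep <- compare_methods(runs, B = 200, seed = 3)
  expect_equal(nrow(rep$pairwise), 2 * choose(3, 2))
  expect_true(all(rep$pairwise$p >= 0 & rep$pairwise$p <= 1))
  # identical score lists -> exact p = 1
  p_sf <- rep$pairwise$p[rep$pairwise$method_a == "soft" &
                           rep$pairwise$method_b == "feat" &
                           rep$pairwise$metric == "auc"]
  expect_equal(p_sf, 1.0)
  # medians equal a one-line oracle
  med <- rep$summary$median[rep$summary$metric == "auc"]
  expect_equal(med, vapply(runs, function(df) median(df$auc), numeric(1)),
               ignore_attr = TRUE)
  expect_true(all(rep$summary$ci_lower <= rep$summary$median + 1e-12))
  expect_true(all(rep$summary$ci_upper >= rep$summary$median - 1e-12))
  expect_error(compare_methods(runs["soft"]), class = "ecodistill_invalid_argument")
  expect_error(compare_methods(list(a = runs$soft[1, ], b = runs$feat)),
               class = "ecodistill_invalid_argument")
})

test_that("U test type-I error is calibrated near the nominal level", {
  # reduced-size version of the full null calibration (acceptance suite runs
  # 1000 replicates); 400 replicates keep this unit test quick
  withr::local_seed(6)
  rejections <- mean(replicate(400, {
    mann_whitney_u(rnorm(10), rnorm(10))$p < 0.05
  }))
  expect_gte(rejections, 0.02)
  expect_lte(rejections, 0.08)
})
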