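## Evaluation harness: F1 and rank-based AUC, percentile-bootstrap confidence
## intervals of medians, Mann-Whitney U comparisons between distillation
## methods, and distance-stratified playback reports.

#' Predict sigmoid scores for one split of a feature archive
#'
#' @param model a `vad_model`.
#' @param archive a `feature_archive`.
#' @param split `"train"`, `"val"`, or `"test"`.
#' @param batch_size forward batch size (scores are batch-size independent).
#' @return List with `scores` (in (0,1), manifest order within the split) and
#'   `labels`.
#' @export
predict_scores <- function(model, archive, split = "test", batch_size = 32) {
  part <- archive_split(archive, split)
  logits <- model_logits(model, part$features, batch_size)
  list(scores = sigmoid(logits), labels = part$labels)
}

#' F1 score
#'
#' Harmonic mean of precision and recall, `2PR/(P + R)`; defined as 0 when
#' `P + R = 0` (e.g. no positive predictions with positives present).
#'
#' @param labels 0/1 ground truth.
#' @param predictions 0/1 predictions (binarize scores with a threshold first).
#' @return Scalar in `[0, 1]`.
#' @export
f1_score <- function(labels, predictions) {
  if (length(labels) != length(predictions)) abort_invalid("f1_score: length mismatch")
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == 0 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' AUC (rank / Mann-Whitney formulation)
#'
#' Probability that a random positive scores above a random negative, with
#' ties counted 1/2: computed from the rank sum of the positive class.
#'
#' @param labels 0/1 ground truth with both classes present.
#' @param scores numeric scores.
#' @return Scalar in `[0, 1]`.
#' @export
auc_score <- function(labels, scores) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort_invalid("auc_score: need both classes present")
  r <- rank(scores)               # average ranks handle ties at 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval of the median
#'
#' @param values numeric sample (non-empty).
#' @param B bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return Named numeric `c(lower, upper)`.
#' @export
bootstrap_median_ci <- function(values, B = 1000, level = 0.95, seed = 0) {
  if (length(values) == 0) abort_invalid("bootstrap_median_ci: empty input")
  meds <- with_seed(derive_seed(seed, "bootstrap"), {
    n <- length(values)
    draws <- matrix(values[sample.int(n, n * B, replace = TRUE)], nrow = B)
    matrixStats::rowMedians(draws)
  })
  q <- quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Mann-Whitney U test (two-sided)
#'
#' The U statistic of the first sample with a two-sided p-value: exact by full
#' enumeration of all `choose(n_a + n_b, n_a)` labelings when both samples
#' have at most 8 observations (ties handled by the permutation distribution
#' itself), and a tie-corrected normal approximation with continuity
#' correction otherwise.
#'
#' @param a,b numeric samples (non-empty).
#' @return List with `U` (statistic for `a`), `p`, and `method`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort_invalid("mann_whitney_u: empty sample")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (na <= 8 && nb <= 8) {
    combs <- utils::combn(na + nb, na)
    dev_obs <- abs(U - mu)
    u_all <- apply(combs, 2, function(idx) sum(r[idx])) - na * (na + 1) / 2
    p <- mean(abs(u_all - mu) >= dev_obs - 1e-12)
    method <- "exact"
  } else {
    nn <- na + nb
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- na * nb / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}

#' Distance-stratified playback report
#'
#' Mean F1 per playback distance plus the overall mean across distances
#' (playback reporting uses means; the method-comparison table uses medians).
#'
#' @param records playback manifest data.frame with `label` and `distance_m`.
#' @param scores numeric scores aligned with `records` rows.
#' @param threshold binarization threshold (default 0.5).
#' @param distances required distance strata.
#' @return data.frame with columns `distance_m` (`"overall"` for the final
#'   row), `n`, `f1`.
#' @export
playback_report <- function(records, scores, threshold = 0.5,
                            distances = c(1, 5, 10, 20)) {
  if (nrow(records) != length(scores)) abort_invalid("playback_report: length mismatch")
  missing <- setdiff(distances, unique(records$distance_m))
  if (length(missing)) {
    abort_invalid("playback_report: missing distance stratum: ",
                  paste(missing, collapse = ", "))
  }
  preds <- as.integer(scores >= threshold)
  rows <- lapply(distances, function(d) {
    sel <- records$distance_m == d
    data.frame(distance_m = as.character(d), n = sum(sel),
               f1 = f1_score(records$label[sel], preds[sel]))
  })
  per <- do.call(rbind, rows)
  rbind(per, data.frame(distance_m = "overall", n = nrow(records),
                        f1 = mean(per$f1)))
}

#' Compare distillation methods across repeated runs
#'
#' Per-method medians with percentile-bootstrap confidence intervals and all
#' pairwise Mann-Whitney U comparisons, computed for each metric column.
#'
#' @param runs named list (one entry per method) of data.frames with metric
#'   columns (e.g. `auc`, `f1`), one row per repeated run (>= 2 runs each).
#' @param metrics metric columns to analyse.
#' @param B,level,seed bootstrap settings.
#' @return A `comparison_report`: list with `summary` (method x metric medians
#'   and CIs) and `pairwise` (p-values per metric and method pair).
#' @export
compare_methods <- function(runs, metrics = c("auc", "f1"), B = 1000,
                            level = 0.95, seed = 0) {
  if (length(runs) < 2) abort_invalid("compare_methods: need >= 2 methods")
  if (any(vapply(runs, nrow, integer(1)) < 2)) {
    abort_invalid("compare_methods: need >= 2 runs per method")
  }
  methods <- names(runs)
  summary_rows <- list()
  pairwise_rows <- list()
  for (metric in metrics) {
    vals <- lapply(runs, function(df) df[[metric]])
    for (m in methods) {
      ci <- bootstrap_median_ci(vals[[m]], B = B, level = level,
                                seed = derive_seed(seed, paste0(metric, m)))
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        metric = metric, method = m, n_runs = length(vals[[m]]),
        median = median(vals[[m]]), ci_lower = ci[["lower"]],
        ci_upper = ci[["upper"]])
    }
    prs <- utils::combn(methods, 2)
    for (k in seq_len(ncol(prs))) {
      mw <- mann_whitney_u(vals[[prs[1, k]]], vals[[prs[2, k]]])
      pairwise_rows[[length(pairwise_rows) + 1]] <- data.frame(
        metric = metric, method_a = prs[1, k], method_b = prs[2, k],
        U = mw$U, p = mw$p, test = mw$method)
    }
  }
  structure(list(summary = do.call(rbind, summary_rows),
                 pairwise = do.call(rbind, pairwise_rows)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Method comparison (median [bootstrap CI]):\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s %-14s %.4f [%.4f-%.4f] (n=%d)\n", s$metric[i], s$method[i],
                s$median[i], s$ci_lower[i], s$ci_upper[i], s$n_runs[i]))
  }
  cat("Pairwise Mann-Whitney U:\n")
  p <- x$pairwise
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-4s %s vs %s: U=%g, p=%.4f (%s)\n", p$metric[i], p$method_a[i],
                p$method_b[i], p$U[i], p$p[i], p$test[i]))
  }
  invisible(x)
}

#' Evaluate a model on one split
#'
#' @param model a `vad_model`.
#' @param archive a `feature_archive`.
#' @param split split tag.
#' @param threshold binarization threshold for F1.
#' @return List with `f1`, `auc`, `threshold`, `n`.
#' @export
evaluate_model <- function(model, archive, split = "test", threshold = 0.5) {
  pr <- predict_scores(model, archive, split)
  list(f1 = f1_score(pr$labels, as.integer(pr$scores >= threshold)),
       auc = auc_score(pr$labels, pr$scores),
       threshold = threshold, n = length(pr$labels))
}
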