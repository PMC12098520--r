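# Metrics reported per fold and aggregated across leave-one-subject-out
# folds: confusion matrix, per-class precision/recall/F1, accuracy, macro-F1,
# Cohen's kappa and percentile-bootstrap confidence intervals.

#' Confusion matrix
#'
#' @param truth Integer labels in `0..K-1` (rows).
#' @param pred Integer labels in `0..K-1` (columns).
#' @param K Number of classes (default 5).
#' @return K x K integer count matrix; entry `(i, j)` counts samples with
#'   true class `i - 1` predicted as `j - 1`.
#' @export
confusion_matrix <- function(truth, pred, K = 5L) {
  if (length(truth) == 0) stop("empty label vectors")
  if (length(truth) != length(pred)) stop("label vectors differ in length")
  if (any(truth < 0 | truth >= K | pred < 0 | pred >= K))
    stop("labels out of range 0..", K - 1)
  cm <- matrix(0L, K, K)
  for (i in seq_along(truth))
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  cm
}

#' Per-class precision, recall and F1
#'
#' `precision_k = cm[k,k] / colsum_k`, `recall_k = cm[k,k] / rowsum_k`,
#' `F1 = 2PR/(P+R)`. Zero denominators yield 0 and are flagged in the
#' `degenerate` column rather than propagating NaN into the macro average.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return Data frame with one row per class: `precision`, `recall`, `f1`,
#'   `degenerate`.
#' @export
per_class_prf <- function(cm) {
  K <- nrow(cm)
  res <- data.frame(class = seq_len(K) - 1L, precision = 0, recall = 0,
                    f1 = 0, degenerate = FALSE)
  for (k in seq_len(K)) {
    tp <- cm[k, k]; colk <- sum(cm[, k]); rowk <- sum(cm[k, ])
    p <- if (colk > 0) tp / colk else 0
    r <- if (rowk > 0) tp / rowk else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    res$precision[k] <- p; res$recall[k] <- r; res$f1[k] <- f
    res$degenerate[k] <- colk == 0 || rowk == 0 || p + r == 0
  }
  res
}

#' F1 from precision and recall
#' @param precision,recall Scalars or vectors.
#' @return `2 * P * R / (P + R)` (0 where `P + R = 0`).
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Macro-averaged F1
#' @param f1s Exactly five per-class F1 values.
#' @return Their unweighted mean.
#' @export
macro_f1 <- function(f1s) {
  if (length(f1s) != 5) stop("expected exactly 5 per-class F1 values")
  mean(f1s)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' `p_o = trace/total` and `p_e = sum_k rowsum_k * colsum_k / total^2`.
#' Returns 1 in the degenerate all-agreement case `p_e = p_o = 1`.
#'
#' @param cm Confusion matrix.
#' @return Scalar in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - pe) < 1e-15) return(if (po >= 1 - 1e-15) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Overall accuracy
#' @param cm Confusion matrix.
#' @return `trace / total`.
#' @export
accuracy <- function(cm) sum(diag(cm)) / sum(cm)

#' Percentile bootstrap confidence interval
#'
#' Resamples (truth, prediction) pairs with replacement `B` times,
#' recomputes the metric per replicate, and takes the percentile interval.
#' Replicates where the metric is undefined (errors) are skipped and counted.
#'
#' @param truth,pred Label vectors.
#' @param metric Function of `(truth, pred)` returning a scalar; default
#'   accuracy.
#' @param B Number of bootstrap replicates (>= 100).
#' @param level Confidence level in (0, 1).
#' @param seed RNG seed (deterministic interval).
#' @return List with `lower`, `upper`, `level`, `B`, `seed`, `point`,
#'   `skipped`.
#' @export
bootstrap_ci <- function(truth, pred,
                         metric = function(t, p) mean(t == p),
                         B = 1000L, level = 0.95, seed = 1L) {
  stopifnot(B >= 100, level > 0, level < 1,
            length(truth) == length(pred), length(truth) > 0)
  set.seed(seed)
  n <- length(truth)
  vals <- numeric(0); skipped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    v <- tryCatch(metric(truth[idx], pred[idx]), error = function(e) NA_real_)
    if (is.na(v)) skipped <- skipped + 1L else vals <- c(vals, v)
  }
  if (skipped > 0)
    message(skipped, " bootstrap replicates skipped (metric undefined)")
  alpha <- (1 - level) / 2
  qs <- quantile(vals, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(lower = qs[1], upper = qs[2], level = level, B = B, seed = seed,
       point = metric(truth, pred), skipped = skipped)
}

#' Evaluate predictions for one fold
#'
#' @param truth,pred 0-based stage label vectors.
#' @param K Number of classes.
#' @param bootstrap Compute a bootstrap CI for accuracy.
#' @param B,level,seed Bootstrap parameters.
#' @return An `eval_report`: confusion matrix, per-class PRF, `accuracy`,
#'   `macro_f1`, `kappa`, optional `ci`.
#' @export
evaluate_predictions <- function(truth, pred, K = 5L, bootstrap = TRUE,
                                 B = 1000L, level = 0.95, seed = 1L) {
  cm <- confusion_matrix(truth, pred, K)
  prf <- per_class_prf(cm)
  rep <- list(confusion = cm, per_class = prf,
              accuracy = accuracy(cm),
              macro_f1 = mean(prf$f1),
              kappa = cohen_kappa(cm),
              n = length(truth))
  if (bootstrap)
    rep$ci <- bootstrap_ci(truth, pred, B = B, level = level, seed = seed)
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d  acc %.4f  m-F1 %.4f  kappa %.4f\n",
              x$n, x$accuracy, x$macro_f1, x$kappa))
  if (!is.null(x$ci))
    cat(sprintf("  %d%% bootstrap CI for accuracy: (%.3f, %.3f)\n",
                round(100 * x$ci$level), x$ci$lower, x$ci$upper))
  invisible(x)
}

#' Aggregate fold reports
#'
#' Headline metrics are the unweighted means over folds; the per-fold
#' accuracy vector is retained and a pooled confusion matrix (with its own
#' metrics) is reported alongside for transparency.
#'
#' @param reports List of `eval_report`, one per fold.
#' @return List with `mean_accuracy`, `mean_macro_f1`, `mean_kappa`,
#'   `fold_accuracy`, `pooled` (an `eval_report` on the pooled confusion
#'   matrix), `n_folds`.
#' @export
aggregate_folds <- function(reports) {
  if (length(reports) == 0) stop("no fold reports to aggregate")
  K <- unique(vapply(reports, function(r) nrow(r$confusion), integer(1)))
  if (length(K) != 1) stop("inconsistent class counts across folds")
  pooled_cm <- Reduce(`+`, lapply(reports, `[[`, "confusion"))
  prf <- per_class_prf(pooled_cm)
  list(mean_accuracy = mean(vapply(reports, `[[`, numeric(1), "accuracy")),
       mean_macro_f1 = mean(vapply(reports, `[[`, numeric(1), "macro_f1")),
       mean_kappa = mean(vapply(reports, `[[`, numeric(1), "kappa")),
       fold_accuracy = vapply(reports, `[[`, numeric(1), "accuracy"),
       pooled = list(confusion = pooled_cm, per_class = prf,
                     accuracy = accuracy(pooled_cm),
                     macro_f1 = mean(prf$f1),
                     kappa = cohen_kappa(pooled_cm)),
       n_folds = length(reports))
}
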