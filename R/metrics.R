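# Confusion-based metrics, tie-aware ROC/AUC, and the cross-validation
# engines (stratified K-fold and jackknife). CV metrics are pooled: all
# held-out predictions are collected and scored once, so jackknife and
# K-fold share one code path and MCC stays well-defined with tiny folds.

#' Confusion-matrix metrics
#'
#' Computes TP/FP/TN/FN and Acc, Sn (sensitivity), Sp (specificity) and the
#' Matthews correlation coefficient
#' \eqn{MCC = (TP\,TN - FP\,FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.
#' If any factor of the MCC denominator is 0, MCC is defined as 0.
#'
#' @param truth,pred +1/-1 vectors of equal length.
#' @return List with `counts` (TP, FP, TN, FN), `acc`, `sn`, `sp`, `mcc`.
#' @export
compute_metrics <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(truth) != length(pred))
    stop("truth and pred lengths differ", call. = FALSE)
  if (length(truth) == 0L) stop("empty evaluation", call. = FALSE)
  if (!all(c(truth, pred) %in% c(1L, -1L)))
    stop("labels must be +1/-1", call. = FALSE)
  tp <- sum(truth == 1L & pred == 1L)
  fp <- sum(truth == -1L & pred == 1L)
  tn <- sum(truth == -1L & pred == -1L)
  fn <- sum(truth == 1L & pred == -1L)
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
       acc = (tp + tn) / length(truth),
       sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       mcc = mcc)
}

#' ROC curve and AUC from decision scores
#'
#' AUC is the Mann-Whitney rank statistic (ties counted 1/2), which equals
#' the trapezoidal area under the tie-aware ROC. Curve points are emitted at
#' every distinct threshold, from (0,0) to (1,1); a sample is called positive
#' when its score is >= the threshold.
#'
#' @param truth +1/-1 vector; both classes must be present.
#' @param scores Real decision values (larger = more positive).
#' @return A `pse_roc`: list with `points` (data.frame threshold/fpr/tpr) and
#'   `auc`.
#' @export
roc_auc <- function(truth, scores) {
  truth <- as.integer(truth)
  if (length(truth) != length(scores))
    stop("truth and scores lengths differ", call. = FALSE)
  n_pos <- sum(truth == 1L); n_neg <- sum(truth == -1L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)  # average ranks handle ties as 1/2
  auc <- (sum(r[truth == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & truth == 1L), numeric(1)) / n_pos
  fpr <- vapply(thr, function(t) sum(scores >= t & truth == -1L), numeric(1)) / n_neg
  points <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                       tpr = c(0, tpr))
  if (points$fpr[nrow(points)] < 1 || points$tpr[nrow(points)] < 1)
    points <- rbind(points, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  structure(list(points = points, auc = auc), class = "pse_roc")
}

#' @export
print.pse_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param x A `pse_roc`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pse_roc <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "s",
                 xlab = "False positive rate", ylab = "True positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", x$auc))
}

# evaluate code with a temporary, restored RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Stratified fold assignment
#'
#' K-fold assignments are stratified per class (round-robin over a seeded
#' permutation), so per-fold class counts differ by at most 1 from
#' proportionality. `K = "jackknife"` yields leave-one-out folds, one sample
#' per fold in dataset order (no randomness).
#'
#' @param labels +1/-1 vector.
#' @param K Integer number of folds (2..N) or `"jackknife"`.
#' @param seed Integer seed governing the stratified shuffle.
#' @return A `pse_folds`: list with `K`, `fold` (fold id per sample), `seed`.
#' @export
make_folds <- function(labels, K, seed = 1L) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (identical(K, "jackknife") || (is.numeric(K) && K == n)) {
    jack <- identical(K, "jackknife")
    return(structure(list(K = n, fold = seq_len(n), seed = as.integer(seed),
                          jackknife = jack), class = "pse_folds"))
  }
  K <- as.integer(K)
  if (is.na(K) || K < 2L || K > n)
    stop("K must be an integer in 2..N (or \"jackknife\")", call. = FALSE)
  for (cls in c(1L, -1L)) {
    if (sum(labels == cls) < K)
      stop("stratified ", K, "-fold requires >= ", K,
           " members of class ", cls, call. = FALSE)
  }
  fold <- integer(n)
  with_seed(seed, {
    for (cls in c(1L, -1L)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(K), length(idx))
    }
  })
  structure(list(K = K, fold = fold, seed = as.integer(seed),
                 jackknife = FALSE), class = "pse_folds")
}

#' @export
print.pse_folds <- function(x, ...) {
  cat(sprintf("%s assignment over %d samples (seed %d)\n",
              if (x$jackknife) "jackknife" else paste0(x$K, "-fold"),
              length(x$fold), x$seed))
  invisible(x)
}

new_metric_report <- function(truth, pred, scores) {
  m <- compute_metrics(truth, pred)
  roc <- roc_auc(truth, scores)
  structure(c(m, list(auc = roc$auc, roc = roc, scores = scores,
                      pred = pred, truth = truth)),
            class = "pse_metrics")
}

#' @export
print.pse_metrics <- function(x, digits = 4, ...) {
  cat(sprintf("n=%d  TP=%d FP=%d TN=%d FN=%d\n", length(x$truth),
              x$counts["TP"], x$counts["FP"], x$counts["TN"], x$counts["FN"]))
  cat(sprintf("Acc=%.*f  MCC=%.*f  Sn=%.*f  Sp=%.*f  AUC=%.*f\n",
              digits, x$acc, digits, x$mcc, digits, x$sn, digits, x$sp,
              digits, x$auc))
  invisible(x)
}

#' Evaluate labeled predictions into a metric report
#'
#' @param truth +1/-1 vector.
#' @param scores Decision values; predicted label is `sign(score)` with 0
#'   mapped to +1.
#' @return A `pse_metrics` report (confusion counts, Acc/MCC/Sn/Sp, AUC and
#'   the ROC curve).
#' @export
metric_report <- function(truth, scores) {
  new_metric_report(as.integer(truth), ifelse(scores >= 0, 1L, -1L),
                    as.numeric(scores))
}

#' Cross-validate one (feature, SVM) parameter candidate
#'
#' For each fold, an SVM is fitted on the training split's feature rows and
#' scores are computed for the held-out split. All held-out predictions are
#' pooled and scored once. Feature extraction is per-sequence (no
#' dataset-level statistic), so features are extracted once for the whole
#' dataset and reused across folds.
#'
#' @param dataset A `pse_dataset`.
#' @param params A [pse_params()] object.
#' @param svm A [svm_params()] object.
#' @param folds A [make_folds()] assignment built on this dataset's labels.
#' @param index A standardized property index.
#' @param features Optional precomputed [extract_features()] result for
#'   `dataset` (an optimization used by the grid search).
#' @return A `pse_metrics` report over the pooled held-out predictions.
#' @export
cross_validate <- function(dataset, params, svm, folds, index,
                           features = NULL) {
  stopifnot(inherits(folds, "pse_folds"))
  if (length(folds$fold) != length(dataset$labels))
    stop("fold assignment does not match dataset size", call. = FALSE)
  if (is.null(features)) features <- extract_features(dataset, params, index)
  x <- features$x; y <- features$y
  scores <- numeric(length(y))
  for (f in sort(unique(folds$fold))) {
    test <- folds$fold == f
    ytr <- y[!test]
    if (length(unique(ytr)) < 2L)
      stop("training split of fold ", f, " lost a class", call. = FALSE)
    fit <- train_svm(x[!test, , drop = FALSE], ytr, svm)
    scores[test] <- decision_scores(fit, x[test, , drop = FALSE])
  }
  metric_report(y, scores)
}
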