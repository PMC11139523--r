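# Signature-recovery evaluation: Hungarian matching of extracted vs true
# profiles, precision/sensitivity/F1 across cosine thresholds with
# normalized AUC, and exposure-based tumour-type classification.

#' Cosine similarity
#'
#' @param a,b Numeric vectors of equal length (non-zero).
#' @return `sum(a*b) / (||a|| ||b||)`; in \[0, 1\] for non-negative input.
#' @export
cosine_sim <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector",
                               call. = FALSE)
  sum(a * b) / (na * nb)
}

# columns of A vs columns of B -> |A| x |B| cosine matrix
pairwise_cosine <- function(A, B) {
  crossprod(l2_normalize_cols(as.matrix(A)), l2_normalize_cols(as.matrix(B)))
}

#' Match extracted signatures to ground truth
#'
#' Optimal one-to-one matching between the columns of two signature
#' matrices, maximizing the total cosine similarity over
#' `min(k_est, k_true)` pairs (Hungarian / Jonker--Volgenant assignment on
#' `1 - cosine` cost).
#'
#' @param S_est,S_true 96 x k matrices on the canonical channels.
#' @return Object of class `"signature_match"`: data frame `pairs`
#'   (`est`, `true`, `cosine`), plus `unmatched_est`, `unmatched_true`,
#'   `k_est`, `k_true`.
#' @export
match_signatures <- function(S_est, S_true) {
  S_est <- as.matrix(S_est); S_true <- as.matrix(S_true)
  if (ncol(S_est) < 1 || ncol(S_true) < 1)
    stop("empty signature matrix", call. = FALSE)
  if (nrow(S_est) != nrow(S_true)) stop("channel mismatch", call. = FALSE)
  cs <- pairwise_cosine(S_est, S_true) # k_est x k_true
  if (ncol(S_est) <= ncol(S_true)) {
    a <- .cpp_lap(1 - cs)
    pairs <- data.frame(est = seq_len(ncol(S_est)), true = a)
  } else {
    a <- .cpp_lap(1 - t(cs))
    pairs <- data.frame(est = a, true = seq_len(ncol(S_true)))
  }
  pairs$cosine <- cs[cbind(pairs$est, pairs$true)]
  pairs <- pairs[order(-pairs$cosine), ]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unmatched_est = setdiff(seq_len(ncol(S_est)), pairs$est),
                 unmatched_true = setdiff(seq_len(ncol(S_true)), pairs$true),
                 k_est = ncol(S_est), k_true = ncol(S_true)),
            class = "signature_match")
}

#' @export
print.signature_match <- function(x, ...) {
  cat(sprintf("signature match: %d estimated vs %d true (%d pairs)\n",
              x$k_est, x$k_true, nrow(x$pairs)))
  print(x$pairs, digits = 3)
  invisible(x)
}

#' Confusion counts at a cosine threshold
#'
#' A matched pair with cosine similarity at or above the threshold is a
#' true positive; every remaining true signature (unmatched or matched
#' below threshold) is a false negative, and every remaining estimated
#' signature a false positive, so `TP + FN = k_true` and `TP + FP = k_est`.
#'
#' @param match A [match_signatures()] result.
#' @param thr Cosine threshold in \[0, 1\].
#' @return Named integer vector `c(TP, FP, FN)`.
#' @export
confusion_at_threshold <- function(match, thr) {
  stopifnot(inherits(match, "signature_match"), thr >= 0, thr <= 1)
  tp <- sum(match$pairs$cosine >= thr - 1e-9) # guard against float round-off
  c(TP = tp, FP = match$k_est - tp, FN = match$k_true - tp)
}

#' Precision/sensitivity/F1 recovery curve
#'
#' Evaluates signature recovery over a grid of cosine thresholds (default
#' 0.8 to 1 in steps of 0.01): precision `TP/(TP+FP)`, sensitivity
#' `TP/(TP+FN)`, and their harmonic mean F1 (0 when both vanish). Each
#' metric is summarized by its normalized AUC: the trapezoidal area under
#' metric-vs-threshold divided by the grid width, so perfect recovery at
#' every threshold gives 1.
#'
#' @param S_est,S_true Signature matrices.
#' @param thresholds Increasing grid of at least 2 thresholds in \[0, 1\].
#' @return Object of class `"recovery_curve"`: data frame `table` with
#'   per-threshold counts and metrics, and named vector `auc`.
#' @export
recovery_curve <- function(S_est, S_true, thresholds = seq(0.8, 1, by = 0.01)) {
  stopifnot(length(thresholds) >= 2, !is.unsorted(thresholds))
  m <- match_signatures(S_est, S_true)
  rows <- t(vapply(thresholds, function(th) confusion_at_threshold(m, th),
                   c(TP = 0, FP = 0, FN = 0)))
  tab <- data.frame(threshold = thresholds, rows)
  tab$precision <- ifelse(tab$TP + tab$FP > 0, tab$TP / (tab$TP + tab$FP), 0)
  tab$sensitivity <- ifelse(tab$TP + tab$FN > 0, tab$TP / (tab$TP + tab$FN), 0)
  tab$f1 <- ifelse(tab$precision + tab$sensitivity > 0,
                   2 * tab$precision * tab$sensitivity /
                     (tab$precision + tab$sensitivity), 0)
  width <- max(thresholds) - min(thresholds)
  trap <- function(y) sum(diff(thresholds) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  auc <- c(precision = trap(tab$precision) / width,
           sensitivity = trap(tab$sensitivity) / width,
           f1 = trap(tab$f1) / width)
  structure(list(table = tab, auc = auc, match = m),
            class = "recovery_curve")
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat("signature recovery across cosine thresholds ",
      sprintf("[%.2f, %.2f]\n", min(x$table$threshold), max(x$table$threshold)),
      sep = "")
  cat(sprintf("normalized AUC: precision %.3f, sensitivity %.3f, F1 %.3f\n",
              x$auc["precision"], x$auc["sensitivity"], x$auc["f1"]))
  invisible(x)
}

# multiclass Matthews correlation from a confusion matrix (Rk statistic)
mcc_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  s <- sum(cm); c0 <- sum(diag(cm))
  tk <- rowSums(cm) # true class totals
  pk <- colSums(cm) # predicted class totals
  num <- c0 * s - sum(tk * pk)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (den == 0) return(0)
  num / den
}

kappa_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  s <- sum(cm)
  po <- sum(diag(cm)) / s
  pe <- sum(rowSums(cm) * colSums(cm)) / s^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

balanced_accuracy_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  recall <- diag(cm) / pmax(rowSums(cm), 1)
  mean(recall)
}

# deterministic stratified fold assignment
stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Tumour-type classification from signature exposures
#'
#' Quantifies how discriminative a set of exposures is: classes with fewer
#' than `min_class_size` samples are dropped, and a balanced random forest
#' (each tree trained on an equal-size stratified bootstrap of the classes)
#' is evaluated by stratified k-fold cross-validation. Reports the
#' multiclass Matthews correlation coefficient, Cohen's kappa and balanced
#' accuracy per fold.
#'
#' @param Z Samples x k exposure matrix.
#' @param labels Class label per sample (character or factor).
#' @param min_class_size Classes smaller than this are dropped (default 10).
#' @param folds Number of cross-validation folds (default 5).
#' @param trees Trees per forest (default 500).
#' @param seed Integer seed for fold assignment and forests.
#' @return Object of class `"exposure_classification"`: `per_fold` data
#'   frame, `mean`, `sd`, `dropped` (class sizes of the removed classes).
#' @export
classify_exposures <- function(Z, labels, min_class_size = 10, folds = 5,
                               trees = 500, seed = 1) {
  Z <- as.matrix(Z)
  labels <- as.character(labels)
  stopifnot(nrow(Z) == length(labels))
  sizes <- table(labels)
  dropped <- sizes[sizes < min_class_size]
  keep <- labels %in% names(sizes[sizes >= min_class_size])
  Z <- Z[keep, , drop = FALSE]
  y <- factor(labels[keep])
  if (nlevels(y) < 2)
    stop("fewer than 2 classes remain after the size filter", call. = FALSE)
  if (min(table(y)) < folds)
    stop("smallest retained class has fewer samples than folds", call. = FALSE)
  with_seed(seed, {
    fold <- stratified_folds(y, folds)
    per_fold <- data.frame(fold = seq_len(folds), mcc = NA_real_,
                           kappa = NA_real_, balanced_accuracy = NA_real_)
    for (f in seq_len(folds)) {
      tr <- fold != f
      ytr <- droplevels(y[tr])
      nmin <- min(table(ytr))
      rf <- randomForest::randomForest(
        x = Z[tr, , drop = FALSE], y = ytr, ntree = trees,
        strata = ytr, sampsize = rep(nmin, nlevels(ytr)))
      pred <- stats::predict(rf, Z[!tr, , drop = FALSE])
      cm <- table(true = y[!tr], pred = factor(pred, levels = levels(y)))
      per_fold$mcc[f] <- mcc_from_confusion(cm)
      per_fold$kappa[f] <- kappa_from_confusion(cm)
      per_fold$balanced_accuracy[f] <- balanced_accuracy_from_confusion(cm)
    }
    structure(list(per_fold = per_fold,
                   mean = colMeans(per_fold[, -1]),
                   sd = apply(per_fold[, -1], 2, stats::sd),
                   dropped = as.list(dropped),
                   folds = folds),
              class = "exposure_classification")
  })
}

#' @export
print.exposure_classification <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated classification from exposures\n", x$folds))
  for (metric in names(x$mean))
    cat(sprintf("  %-18s %.2f (%.2f)\n", metric, x$mean[metric], x$sd[metric]))
  if (length(x$dropped) > 0)
    cat("dropped classes:",
        paste(sprintf("%s (n=%d)", names(x$dropped), unlist(x$dropped)),
              collapse = ", "), "\n")
  invisible(x)
}
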