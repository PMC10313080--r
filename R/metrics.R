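#' Binary classification metrics
#'
#' Accuracy, precision, recall and F1 from binary labels and predictions:
#' Acc = (TP+TN)/(TP+TN+FP+FN), Pre = TP/(TP+FP), Recall = TP/(TP+FN),
#' F1 = 2 P R / (P + R). Zero-denominator cases (e.g. no predicted
#' positives) are defined as 0 with a logged warning, since the ratio is
#' otherwise undefined.
#'
#' @param labels binary vector of ground-truth labels.
#' @param predictions binary vector of predicted labels.
#' @return list(acc, pre, recall, f1).
#' @export
binary_metrics <- function(labels, predictions) {
  if (!length(labels)) stop("empty input")
  stopifnot(length(labels) == length(predictions))
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  stopifnot(all(labels %in% 0:1), all(predictions %in% 0:1))
  tp <- sum(labels == 1 & predictions == 1)
  tn <- sum(labels == 0 & predictions == 0)
  fp <- sum(labels == 0 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  ratio0 <- function(num, den, what) {
    if (den == 0) { grn_log(what, " undefined (0 denominator); reported as 0"); return(0) }
    num / den
  }
  pre <- ratio0(tp, tp + fp, "precision")
  rec <- ratio0(tp, tp + fn, "recall")
  list(acc = (tp + tn) / length(labels),
       pre = pre, recall = rec,
       f1 = if (pre + rec == 0) 0 else 2 * pre * rec / (pre + rec))
}

#' Multilabel (example-based) metrics
#'
#' Hamming loss is the fraction of wrong labels over all (sample, class)
#' slots. CP/CR/CF1 are the example-based intersection ratios: per sample e,
#' CP_e = |y_e intersect yhat_e| / |yhat_e|, CR_e divides by |y_e|, and CF1_e
#' is their harmonic mean; each is averaged over samples. Samples with an
#' empty predicted (or true) label set contribute 0 to the corresponding
#' ratio by convention. A strict per-class (column-wise macro) variant is
#' available with `per_class = TRUE`.
#'
#' @param Y binary matrix (samples x classes) of true labels.
#' @param Yhat binary matrix of predicted labels, same shape.
#' @param per_class compute column-wise macro precision/recall/F1 instead of
#'   the example-based ratios.
#' @return list(hl, cp, cr, cf1).
#' @export
multilabel_metrics <- function(Y, Yhat, per_class = FALSE) {
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  if (!all(dim(Y) == dim(Yhat))) stop("shape mismatch between Y and Yhat")
  storage.mode(Y) <- "integer"; storage.mode(Yhat) <- "integer"
  hl <- mean(Y != Yhat)
  if (per_class) {
    prs <- lapply(seq_len(ncol(Y)), function(j) binary_metrics(Y[, j], Yhat[, j]))
    cp <- mean(vapply(prs, `[[`, 0, "pre"))
    cr <- mean(vapply(prs, `[[`, 0, "recall"))
    cf1 <- mean(vapply(prs, `[[`, 0, "f1"))
  } else {
    inter <- rowSums(Y & Yhat)
    np <- rowSums(Yhat); nt <- rowSums(Y)
    cp_e <- ifelse(np == 0, 0, inter / pmax(np, 1))
    cr_e <- ifelse(nt == 0, 0, inter / pmax(nt, 1))
    cf1_e <- ifelse(cp_e + cr_e == 0, 0, 2 * cp_e * cr_e / (cp_e + cr_e))
    if (any(np == 0)) grn_log(sum(np == 0), " sample(s) with empty predicted label set; CP term 0")
    cp <- mean(cp_e); cr <- mean(cr_e); cf1 <- mean(cf1_e)
  }
  list(hl = hl, cp = cp, cr = cr, cf1 = cf1)
}

#' ROC curve and AUC
#'
#' AUC via the rank-sum (Mann-Whitney) statistic with midpoint handling of
#' tied scores, which equals the trapezoidal area under the ROC curve swept
#' over all score thresholds. Curve points (FPR, TPR) at every distinct
#' threshold are returned for plotting/export.
#'
#' @param labels binary labels (both classes must be present).
#' @param scores real-valued scores, higher = more positive.
#' @return list(auc, fpr, tpr).
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: both classes must be present")
  r <- rank(scores)  # midpoint ranks under ties
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # curve: sweep thresholds from +Inf downward over distinct scores
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  tp <- cumsum(l); fp <- cumsum(1 - l)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  list(auc = auc,
       fpr = c(0, fp[keep] / n0),
       tpr = c(0, tp[keep] / n1))
}

#' Aggregate per-fold metric reports
#'
#' @param per_fold list of named numeric lists (one per fold).
#' @return list(per_fold, mean) where mean averages each metric over folds.
#' @export
aggregate_folds <- function(per_fold) {
  nm <- names(per_fold[[1]])
  mean_m <- lapply(setNames(nm, nm), function(m)
    mean(vapply(per_fold, function(f) as.numeric(f[[m]]), 0)))
  list(per_fold = per_fold, mean = mean_m)
}
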