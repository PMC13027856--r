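# Training losses (focal / cross-entropy), Mixup, classification metrics
# and ROC/AUC.

#' Focal loss from logits
#'
#' `FL = -alpha_t (1 - p_t)^gamma log(p_t)` averaged over the batch, where
#' `p_t` is the softmax probability of the true class, computed from the
#' logits in log-sum-exp form so `p_t -> 0` never produces `log(0)`.
#' With `gamma = 0` and `alpha_t = 1` the loss reduces exactly to
#' cross-entropy. Soft (e.g. Mixup) targets are supported: each class
#' contributes with its target weight.
#'
#' @param logits numeric matrix `n x 2` (or vector of length 2).
#' @param targets integer class labels in `{1, 2}`, or an `n x 2` matrix of
#'   soft target rows summing to 1.
#' @param alpha_t class-balance weight (default 0.25).
#' @param gamma focusing exponent (default 2, >= 0).
#' @return list with `value` (mean loss) and `grad` (`n x 2` gradient with
#'   respect to the logits).
#' @export
focal_loss <- function(logits, targets, alpha_t = 0.25, gamma = 2) {
  stopifnot(gamma >= 0, alpha_t > 0)
  if (is.null(dim(logits))) logits <- matrix(logits, 1)
  n <- nrow(logits)
  y <- if (is.matrix(targets)) targets
       else { m <- matrix(0, n, ncol(logits)); m[cbind(seq_len(n), targets)] <- 1; m }
  lse <- apply(logits, 1, logsumexp)
  logp <- logits - lse
  p <- exp(logp)
  loss <- sum(y * alpha_t * (1 - p)^gamma * (-logp)) / n
  # d/dz_j = q_j - p_j * sum(q), q_c = y_c alpha p_c (gamma (1-p)^(g-1) log p - (1-p)^g / p)
  om <- pmax(1 - p, 1e-12)
  q <- if (gamma == 0) -y * alpha_t  # exact cross-entropy limit
       else y * alpha_t * (gamma * om^(gamma - 1) * logp * p - om^gamma)
  grad <- (q - p * rowSums(q)) / n
  list(value = loss, grad = grad)
}

#' Cross-entropy loss from logits (soft targets allowed)
#' @inheritParams focal_loss
#' @return list with `value` and `grad`.
#' @export
cross_entropy_loss <- function(logits, targets) focal_loss(logits, targets,
                                                           alpha_t = 1, gamma = 0)

#' Mixup batch augmentation
#'
#' Convex combination `x~ = lambda x_i + (1 - lambda) x_perm(i)` of the
#' batch with a seeded permutation, applied identically to the one-hot
#' labels, which therefore stay on the probability simplex.
#'
#' @param batch_x list of equal-shape numeric arrays.
#' @param batch_y `n x 2` one-hot (or soft) label matrix.
#' @param lambda mixing weight in `[0, 1]` (draw it from
#'   `rbeta(1, a, a)`, `a = 0.2`, per batch).
#' @param perm permutation of `seq_len(n)`; defaults to the identity for
#'   `n = 1` and must be supplied (seeded) otherwise.
#' @return list with `x` (mixed list) and `y` (mixed label matrix).
#' @export
mixup <- function(batch_x, batch_y, lambda, perm = NULL) {
  stopifnot(lambda >= 0, lambda <= 1)
  n <- length(batch_x)
  if (n == 1) return(list(x = batch_x, y = batch_y))
  if (is.null(perm)) stop("supply a seeded permutation for n > 1")
  x <- lapply(seq_len(n), function(i)
    lambda * batch_x[[i]] + (1 - lambda) * batch_x[[perm[i]]])
  y <- lambda * batch_y + (1 - lambda) * batch_y[perm, , drop = FALSE]
  list(x = x, y = y)
}

#' Classification metrics from a confusion table
#'
#' Accuracy, precision, recall (sensitivity), specificity and F1 from the
#' TP/FP/FN/TN counts. Ratios with a zero denominator are reported as
#' `NaN` and flagged in `undefined` rather than coerced to 0.
#'
#' @param tp,fp,fn,tn non-negative confusion counts, or pass `pred` and
#'   `truth` factors/labels with `positive` naming the positive class.
#' @param pred,truth optional predicted and true labels.
#' @param positive positive-class label (default `"ASD"`).
#' @return list of class `metrics_report`.
#' @export
compute_metrics <- function(tp = NULL, fp = NULL, fn = NULL, tn = NULL,
                            pred = NULL, truth = NULL, positive = "ASD") {
  if (!is.null(pred)) {
    pp <- pred == positive; tt <- truth == positive
    tp <- sum(pp & tt); fp <- sum(pp & !tt)
    fn <- sum(!pp & tt); tn <- sum(!pp & !tt)
  }
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn > 0)
  ratio <- function(num, den) if (den == 0) NaN else num / den
  acc <- (tp + tn) / (tp + fp + fn + tn)
  prec <- ratio(tp, tp + fp)
  rec <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  f1 <- if (is.nan(prec) || is.nan(rec) || prec + rec == 0) NaN
        else 2 * prec * rec / (prec + rec)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = acc, precision = prec, recall = rec,
                 specificity = spec, f1 = f1,
                 undefined = c(precision = is.nan(prec), recall = is.nan(rec),
                               specificity = is.nan(spec), f1 = is.nan(f1))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d FN=%d TN=%d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("accuracy %.4f | precision %.4f | recall %.4f | specificity %.4f | F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$specificity, x$f1))
  if (any(x$undefined))
    cat("undefined (zero denominator):",
        paste(names(which(x$undefined)), collapse = ", "), "\n")
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores, records
#' (FPR, TPR) points, and integrates by the trapezoid rule — equivalent to
#' the Mann-Whitney pair statistic, with tied score pairs contributing
#' one half.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical/0-1 vector, `TRUE` = positive; both classes must
#'   be present.
#' @return list of class `roc_curve` with `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  uniq <- !duplicated(s)
  cum_tp <- cumsum(l); cum_fp <- cumsum(!l)
  last_of_tie <- c(uniq[-1], TRUE)
  tpr <- c(0, cum_tp[last_of_tie] / np)
  fpr <- c(0, cum_fp[last_of_tie] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, s[last_of_tie]), auc = auc),
            class = "roc_curve")
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
                 ylab = "True positive rate (sensitivity)",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
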