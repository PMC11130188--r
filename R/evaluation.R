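# Classifier evaluation: confusion-matrix statistics, exact binomial
# machinery (Clopper-Pearson interval, accuracy-vs-NIR test), Cohen's
# kappa, F1, and ROC/AUC. Conventions follow the standard caret-style
# definitions: pathogenic is the positive class, NIR is the larger
# reference-class proportion, and metrics with zero denominators are
# reported as NA rather than 0.

.as_binary <- function(x, what) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    ok <- x %in% c("benign", "pathogenic")
    if (!all(ok)) stop(what, " must be 'benign'/'pathogenic' or 0/1", call. = FALSE)
    return(as.integer(x == "pathogenic"))
  }
  x <- as.integer(x)
  if (!all(x %in% c(0L, 1L))) stop(what, " must be binary (0/1)", call. = FALSE)
  x
}

#' Confusion matrix counts
#'
#' Counts with pathogenic as the positive class: `tp` pathogenic
#' predicted pathogenic, `tn` benign predicted benign.
#'
#' @param truth True labels (0/1 or `"benign"`/`"pathogenic"`).
#' @param predicted Predicted labels, same encoding and length.
#' @return A list with integer elements `tp`, `fp`, `fn`, `tn`.
#' @export
confusionCounts <- function(truth, predicted) {
  t <- .as_binary(truth, "truth")
  p <- .as_binary(predicted, "predicted")
  if (length(t) != length(p)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  list(tp = sum(p == 1L & t == 1L),
       fp = sum(p == 1L & t == 0L),
       fn = sum(p == 0L & t == 1L),
       tn = sum(p == 0L & t == 0L))
}

#' Complete panel of confusion-matrix metrics
#'
#' From the four counts, computes sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, accuracy `(TP+TN)/n`, balanced accuracy, precision/PPV
#' `TP/(TP+FP)`, NPV `TN/(TN+FN)`, the no-information rate (larger
#' reference-class proportion), Cohen's kappa from the marginal-based
#' expected agreement, the F1 score, the exact 95% Clopper-Pearson
#' interval for accuracy and the one-sided exact binomial p-value for
#' accuracy exceeding the NIR. Ratios with zero denominators are `NA`.
#'
#' @param cm A list with counts `tp`, `fp`, `fn`, `tn` (as from
#'   [confusionCounts()]), or four counts given separately.
#' @param tp,fp,fn,tn Counts (alternative to `cm`).
#' @param level Confidence level for the accuracy interval.
#' @return A list of class `confusionStats` holding the counts and every
#'   derived metric.
#' @export
#' @examples
#' m <- classificationMetrics(tp = 42, fp = 4, fn = 3, tn = 49)
#' round(c(m$accuracy, m$sensitivity, m$specificity, m$kappa), 2)
classificationMetrics <- function(cm = NULL, tp = NULL, fp = NULL, fn = NULL,
                                  tn = NULL, level = 0.95) {
  if (!is.null(cm)) {
    tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  }
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  n <- tp + fp + fn + tn
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  acc <- (tp + tn) / n
  ppv <- ratio(tp, tp + fp)
  npv <- ratio(tn, tn + fn)
  nir <- max(tp + fn, tn + fp) / n
  p_o <- acc
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else NA_real_
  f1 <- if (!is.na(ppv) && !is.na(sens) && (ppv + sens) > 0) {
    2 * ppv * sens / (ppv + sens)
  } else NA_real_
  ci <- clopperPearson(tp + tn, n, level = level)
  p_nir <- nirBinomialTest(list(tp = tp, fp = fp, fn = fn, tn = tn))
  structure(list(
    tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
    tn = as.integer(tn), n = as.integer(n),
    accuracy = acc,
    accuracy_ci_lower = unname(ci[1]), accuracy_ci_upper = unname(ci[2]),
    balanced_accuracy = if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_,
    no_information_rate = nir,
    p_acc_gt_nir = p_nir,
    sensitivity = sens,
    specificity = spec,
    ppv = ppv,
    npv = npv,
    kappa = kappa,
    f1 = f1), class = "confusionStats")
}

#' @export
print.confusionStats <- function(x, digits = 2, ...) {
  cat(sprintf("Confusion matrix (n = %d): TP %d, FP %d, FN %d, TN %d\n",
              x$n, x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  Accuracy (%d%% CI)  %.2f (%.2f-%.2f)\n", 95,
              x$accuracy, x$accuracy_ci_lower, x$accuracy_ci_upper))
  for (f in c("balanced_accuracy", "no_information_rate", "sensitivity",
              "specificity", "ppv", "npv", "kappa", "f1")) {
    cat(sprintf("  %-20s %s\n", f, format(round(x[[f]], digits), nsmall = digits)))
  }
  cat(sprintf("  P(acc > NIR)         %.3g\n", x$p_acc_gt_nir))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Interval from beta distribution quantiles; the lower bound is 0 when
#' there are no successes and the upper bound 1 when all trials succeed.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level in (0, 1).
#' @return Numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' round(clopperPearson(91, 98), 2) # 0.86 0.97
clopperPearson <- function(successes, n, level = 0.95) {
  if (length(level) != 1 || !is.finite(level) || level <= 0 || level >= 1) {
    stop("level must be in (0, 1)", call. = FALSE)
  }
  if (n < 1 || successes < 0 || successes > n) {
    stop("need 0 <= successes <= n and n >= 1", call. = FALSE)
  }
  a <- 1 - level
  lower <- if (successes == 0) 0 else stats::qbeta(a / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else stats::qbeta(1 - a / 2, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}

#' One-sided exact binomial test of accuracy against the NIR
#'
#' P-value for observing at least `tp + tn` correct predictions out of
#' `n` under the null that accuracy equals the no-information rate.
#'
#' @param cm List with counts `tp`, `fp`, `fn`, `tn`.
#' @return The one-sided p-value.
#' @export
nirBinomialTest <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  n <- tp + fp + fn + tn
  nir <- max(tp + fn, tn + fp) / n
  stats::binom.test(tp + tn, n, p = nir, alternative = "greater")$p.value
}

#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores in descending
#' order (predicting pathogenic when `score >= threshold`), grouping
#' tied scores, and anchors the curve at (0, 0) and (1, 1).
#'
#' @param truth True labels (0/1 or `"benign"`/`"pathogenic"`), both
#'   classes present.
#' @param scores Numeric pathogenicity scores, higher = more pathogenic.
#' @return A data.frame of class `rocCurve` with columns `threshold`,
#'   `tpr`, `fpr`, ordered from (0, 0) to (1, 1).
#' @export
rocPoints <- function(truth, scores) {
  t <- .as_binary(truth, "truth")
  if (length(t) != length(scores)) {
    stop("truth and scores must have equal length", call. = FALSE)
  }
  n_pos <- sum(t == 1L); n_neg <- sum(t == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires both classes present", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(s) sum(t == 1L & scores >= s) / n_pos, numeric(1))
  fpr <- vapply(thr, function(s) sum(t == 0L & scores >= s) / n_neg, numeric(1))
  out <- data.frame(threshold = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr))
  if (out$tpr[nrow(out)] != 1 || out$fpr[nrow(out)] != 1) {
    out <- rbind(out, data.frame(threshold = -Inf, tpr = 1, fpr = 1))
  }
  class(out) <- c("rocCurve", "data.frame")
  out
}

#' Area under the ROC curve (trapezoidal rule)
#'
#' Trapezoidal integration of the threshold-sweep curve; with the
#' tie-grouped sweep of [rocPoints()] this equals the Mann-Whitney
#' concordance probability with half credit for tied scores.
#'
#' @param curve A `rocCurve` from [rocPoints()].
#' @return AUC in \[0, 1\].
#' @export
aucTrapezoid <- function(curve) {
  stopifnot(inherits(curve, "rocCurve") || all(c("tpr", "fpr") %in% names(curve)))
  fpr <- curve$fpr; tpr <- curve$tpr
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
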