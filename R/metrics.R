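#' Two-class confusion counts
#'
#' Standard 2x2 counts for -1/+1 labels. By convention the positive class
#' (`+1`) is the imagined finger movement: `TP` counts positives predicted
#' positive, `TN` negatives predicted negative, `FP` negatives predicted
#' positive, `FN` positives predicted negative.
#'
#' @param truth True labels in -1/+1.
#' @param predicted Predicted labels in -1/+1, same length.
#' @param positive The label treated as positive (default `1`).
#' @return A tibble with columns `tp`, `tn`, `fp`, `fn`, `n`.
#' @examples
#' confusion_counts(c(1, 1, -1), c(1, -1, -1))  # tp 1, fn 1, tn 1, fp 0
#' @export
confusion_counts <- function(truth, predicted, positive = 1) {
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have the same length", call. = FALSE)
  }
  if (!all(truth %in% c(-1, 1)) || !all(predicted %in% c(-1, 1))) {
    stop("labels must take values -1 and +1 only", call. = FALSE)
  }
  pos_t <- truth == positive
  pos_p <- predicted == positive
  tibble::tibble(
    tp = sum(pos_t & pos_p), tn = sum(!pos_t & !pos_p),
    fp = sum(!pos_t & pos_p), fn = sum(pos_t & !pos_p),
    n = length(truth)
  )
}

#' Chance-corrected accuracy (kappa)
#'
#' `kappa = (acc - rand) / (1 - rand)`, where `rand` is the accuracy of
#' random classification — 0.5 for a balanced two-class task. Kappa is 0 at
#' chance, 1 at perfect accuracy, and affine in accuracy with slope
#' `1/(1 - rand)`.
#'
#' @param acc Classification accuracy as a proportion in `[0, 1]`.
#' @param rand Chance accuracy as a proportion in `[0, 1)`; default 0.5.
#' @return Kappa in `[-1, 1]` (for `rand = 0.5`).
#' @examples
#' kappa_statistic(0.99)  # 0.98
#' kappa_statistic(0.89)  # 0.78
#' @export
kappa_statistic <- function(acc, rand = 0.5) {
  if (any(acc < 0) || any(acc > 1)) stop("`acc` must lie in [0, 1]", call. = FALSE)
  if (any(rand < 0) || any(rand >= 1)) stop("`rand` must lie in [0, 1)", call. = FALSE)
  (acc - rand) / (1 - rand)
}

#' Sensitivity, specificity, precision and F-score from confusion counts
#'
#' Rates are reported in percent: `sensitivity = TP/(TP+FN) x 100` (recall),
#' `specificity = TN/(TN+FP) x 100`, `precision = TP/(TP+FP) x 100`, and
#' the F-score is the harmonic mean of precision and recall,
#' `2 x precision x recall / (precision + recall)` (already in percent when
#' its inputs are). A rate whose denominator is zero is returned as `NA`
#' with a warning rather than silently as 0.
#'
#' @param counts A one-row tibble/list with `tp`, `tn`, `fp`, `fn` (e.g.
#'   from [confusion_counts()]).
#' @return A tibble with `sensitivity`, `specificity`, `precision`,
#'   `f_score`, all in percent.
#' @examples
#' classification_rates(list(tp = 49, tn = 50, fp = 0, fn = 1))
#' @export
classification_rates <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  rate <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined: zero denominator", what), call. = FALSE)
      return(NA_real_)
    }
    num / den * 100
  }
  sens <- rate(tp, tp + fn, "sensitivity")
  spec <- rate(tn, tn + fp, "specificity")
  prec <- rate(tp, tp + fp, "precision")
  f <- f_score(prec, sens)
  tibble::tibble(sensitivity = sens, specificity = spec, precision = prec, f_score = f)
}

#' F-score from precision and recall
#'
#' @param precision,recall Rates in percent.
#' @return Harmonic mean `2 p r / (p + r)`, in percent; `NA` (with a
#'   warning) when both are zero or either is undefined.
#' @examples
#' f_score(100, 98)  # 98.9899
#' @export
f_score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision + recall == 0) {
    warning("F-score undefined: precision + recall = 0", call. = FALSE)
    return(NA_real_)
  }
  2 * precision * recall / (precision + recall)
}

#' Full classifier evaluation report
#'
#' Confusion counts plus the whole metric suite for one two-class
#' evaluation: accuracy and kappa as proportions, sensitivity/specificity/
#' precision/F-score in percent.
#'
#' @inheritParams confusion_counts
#' @param rand Chance accuracy for kappa (0.5 for two balanced classes).
#' @return An object of class `eval_report` (a named list); see
#'   [tidy.eval_report()] and [glance.eval_report()].
#' @examples
#' truth <- rep(c(-1, 1), 50)
#' pred <- truth; pred[1] <- 1
#' evaluate_classification(truth, pred)
#' @export
evaluate_classification <- function(truth, predicted, positive = 1, rand = 0.5) {
  cts <- confusion_counts(truth, predicted, positive)
  acc <- (cts$tp + cts$tn) / cts$n
  rates <- classification_rates(cts)
  structure(
    c(as.list(cts),
      list(accuracy = acc, kappa = kappa_statistic(acc, rand), rand = rand),
      as.list(rates)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d  (TP %d, TN %d, FP %d, FN %d)\n",
              x$n, x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("  accuracy %.4f | kappa %.4f | F-score %.2f%% | sens %.2f%% | spec %.2f%% | prec %.2f%%\n",
              x$accuracy, x$kappa, x$f_score, x$sensitivity, x$specificity, x$precision))
  invisible(x)
}

#' Long-format metrics of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A tibble with `metric` and `value` rows for every count and rate.
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(
    metric = c("tp", "tn", "fp", "fn", "n", "accuracy", "kappa",
               "sensitivity", "specificity", "precision", "f_score"),
    value = c(x$tp, x$tn, x$fp, x$fn, x$n, x$accuracy, x$kappa,
              x$sensitivity, x$specificity, x$precision, x$f_score)
  )
}

#' One-row summary of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A one-row tibble: accuracy, kappa, f_score, sensitivity,
#'   specificity, precision.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, kappa = x$kappa, f_score = x$f_score,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 precision = x$precision)
}
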