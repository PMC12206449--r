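#' Confusion matrix from labels
#'
#' Builds a true-by-predicted confusion matrix over a fixed class
#' vocabulary. Predictions outside the vocabulary (e.g. `UNKNOWN` from the
#' open-set layer) get their own columns and count as errors for every
#' class metric.
#'
#' @param truth,predicted Character vectors.
#' @param class_names Ordered class vocabulary (defaults to classes seen in
#'   `truth`).
#' @return Integer matrix, rows = true classes, columns = predicted classes
#'   (+ any extra predicted labels).
#' @export
confusion_matrix <- function(truth, predicted,
                             class_names = sort(unique(truth))) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  extra <- setdiff(unique(predicted), class_names)
  cols <- c(class_names, extra)
  cm <- table(factor(truth, levels = class_names),
              factor(predicted, levels = cols))
  m <- matrix(as.integer(cm), nrow(cm), ncol(cm),
              dimnames = list(class_names, cols))
  m
}

#' Classification metrics from a confusion matrix
#'
#' Computes per-class one-vs-rest metrics by collapsing the confusion
#' matrix to a 2x2 table per class (TP = diagonal entry, FN = rest of the
#' row, FP = rest of the column, TN = remainder) and support-weighted
#' aggregates: weighted MCC, weighted F1, precision and recall, plus
#' overall accuracy (trace over total). A zero denominator defines MCC (and
#' F1/precision/recall) as 0 for that class. The multiclass MCC
#' generalization (a single coefficient over the full matrix) is reported
#' alongside; the support-weighted one-vs-rest mean is the headline
#' "weighted MCC". Extra predicted-only columns (such as `UNKNOWN`) count
#' as false predictions and never as true positives.
#'
#' @param cm Confusion matrix (true x predicted), e.g. from
#'   [confusion_matrix()].
#' @return A `metrics_report` with per-class tibble and weighted
#'   aggregates; use [generics::tidy()] / [generics::glance()] for tibble
#'   views.
#' @export
compute_metrics <- function(cm) {
  if (!is.matrix(cm) || is.null(rownames(cm))) {
    abort_mt("cm must be a confusion matrix with class rownames.", "metrics_error")
  }
  total <- sum(cm)
  if (total == 0) abort_mt("Empty confusion matrix.", "metrics_error")
  classes <- rownames(cm)
  storage.mode(cm) <- "double" # avoid integer overflow in the MCC products
  per <- lapply(classes, function(cl) {
    tp <- if (cl %in% colnames(cm)) cm[cl, cl] else 0
    fn <- sum(cm[cl, ]) - tp
    fp <- if (cl %in% colnames(cm)) sum(cm[, cl]) - tp else 0
    tn <- total - tp - fn - fp
    den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    tibble::tibble(class = cl, support = tp + fn, tp = tp, fp = fp, fn = fn,
                   tn = tn, mcc = mcc, f1 = f1, precision = prec, recall = rec)
  })
  per <- dplyr::bind_rows(per)
  wsum <- function(v) sum(per$support * v) / sum(per$support)
  known_cols <- intersect(colnames(cm), classes)
  acc <- sum(vapply(known_cols, function(cl) cm[cl, cl], numeric(1))) / total
  structure(
    list(per_class = per,
         weighted_mcc = wsum(per$mcc), weighted_f1 = wsum(per$f1),
         precision = wsum(per$precision), recall = wsum(per$recall),
         accuracy = acc, multiclass_mcc = multiclass_mcc(cm),
         confusion = cm),
    class = "metrics_report"
  )
}

# Gorodkin's R_K multiclass correlation over the full matrix (square part
# of the vocabulary plus any extra predicted columns as pure error mass).
multiclass_mcc <- function(cm) {
  classes <- rownames(cm)
  cols <- colnames(cm)
  full <- matrix(0, length(union(classes, cols)), length(union(classes, cols)),
                 dimnames = list(union(classes, cols), union(classes, cols)))
  full[classes, cols] <- cm
  n <- sum(full)
  tr <- sum(diag(full))
  rows <- rowSums(full)
  colsums <- colSums(full)
  num <- tr * n - sum(rows * colsums)
  den <- sqrt(n^2 - sum(rows^2)) * sqrt(n^2 - sum(colsums^2))
  if (den == 0) 0 else num / den
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> weighted MCC %.3f | weighted F1 %.3f | accuracy %.3f | precision %.3f | recall %.3f\n",
    x$weighted_mcc, x$weighted_f1, x$accuracy, x$precision, x$recall
  ))
  invisible(x)
}

#' Broom-style accessors
#'
#' `tidy()` returns the per-class (or per-epoch / per-probe) breakdown of a
#' result object as a tibble; `glance()` a one-row summary.
#'
#' @param x A package result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_methods
NULL

#' @rdname tidy_methods
#' @export
tidy.metrics_report <- function(x, ...) {
  x$per_class
}

#' @rdname tidy_methods
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    weighted_mcc = x$weighted_mcc, weighted_f1 = x$weighted_f1,
    accuracy = x$accuracy, precision = x$precision, recall = x$recall,
    multiclass_mcc = x$multiclass_mcc, n = sum(x$confusion)
  )
}
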