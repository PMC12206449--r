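#' Stratified k-fold cross-validation
#'
#' Splits samples into `k` stratified folds (per-class fold sizes differ by
#' at most one), trains on `k - 1` folds — from scratch, or by fine-tuning
#' a pretrained source-domain model when one is supplied — and evaluates on
#' the held-out fold. Reports per-fold metrics and the pooled confusion
#' matrix across folds.
#'
#' @param x Fused input tensor `(samples, probes, d)`.
#' @param labels Class labels.
#' @param cfg [network_config()] used for each fold's training.
#' @param k Number of folds (>= 2).
#' @param seed Fold-assignment seed (fixed seed, fixed folds).
#' @param pretrained Optional pretrained `trained_model`; folds then
#'   fine-tune it with `cfg$freeze_blocks` stages frozen.
#' @return A `cv_result`: `pooled` [compute_metrics()] report, `folds` list
#'   of per-fold reports, `assignments` tibble, `predictions` tibble.
#' @export
cross_validate <- function(x, labels, cfg, k = 5, seed = 1, pretrained = NULL) {
  if (k < 2) abort_mt("k must be at least 2.", "cv_error")
  x <- as_input_tensor(x)
  labels <- as.character(labels)
  n <- dim(x)[1]
  folds <- stratified_folds(labels, k, seed)
  class_names <- sort(unique(labels))
  preds <- character(n)
  fold_reports <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train_idx <- setdiff(seq_len(n), test_idx)
    fold_cfg <- cfg
    fold_cfg$seed <- derive_seed(cfg$seed, sprintf("fold%d", f))
    model <- if (is.null(pretrained)) {
      fold_cfg$num_classes <- length(class_names)
      fold_cfg$input_shape <- dim(x)[2:3]
      m <- build_network(fold_cfg, class_names)
      train_network(m, x[train_idx, , , , drop = FALSE], labels[train_idx], fold_cfg)
    } else {
      fine_tune(pretrained, x[train_idx, , , , drop = FALSE], labels[train_idx],
                fold_cfg)
    }
    ps <- predict_scores(model, x[test_idx, , , , drop = FALSE])
    preds[test_idx] <- ps$predicted
    fold_reports[[f]] <- compute_metrics(
      confusion_matrix(labels[test_idx], ps$predicted, class_names)
    )
  }
  pooled <- compute_metrics(confusion_matrix(labels, preds, class_names))
  structure(
    list(pooled = pooled, folds = fold_reports,
         assignments = tibble::tibble(sample = seq_len(n), fold = folds,
                                      truth = labels, predicted = preds),
         k = k, seed = seed),
    class = "cv_result"
  )
}

# Per-class round-robin assignment after a seeded shuffle: fold sizes per
# class differ by at most 1, folds partition the samples.
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  folds <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold stratified CV (seed %d)\n", x$k, x$seed))
  print(x$pooled)
  invisible(x)
}

#' @rdname tidy_methods
#' @export
tidy.cv_result <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$folds), function(f) {
    dplyr::mutate(glance(x$folds[[f]]), fold = f, .before = 1)
  }))
}

#' @rdname tidy_methods
#' @export
glance.cv_result <- function(x, ...) {
  glance(x$pooled)
}

#' Leave-one-class-out unknown-masking protocol
#'
#' Masks one class entirely, trains on the remaining classes (fine-tuning
#' when a pretrained model is given), calibrates the open-set layer, and
#' then asks the model to classify the masked samples. The returned
#' detection accuracy is the fraction of masked samples flagged as
#' UNKNOWN — how reliably a never-seen class is recognized as novel. The
#' open-set calibration is refit within each masking run.
#'
#' By default a stratified `calibration_fraction` of the retained samples
#' is held out from network training and used only to fit the open-set
#' calibration: distances of in-sample (memorized) training points to the
#' class MAVs underestimate the distances fresh samples exhibit, which at
#' small cohort sizes makes every new sample — novel or not — look
#' extreme. Held-out calibration restores a realistic distance scale. Set
#' `calibration_fraction = 0` to calibrate on the training samples
#' themselves.
#'
#' @param x Fused input tensor.
#' @param labels Class labels.
#' @param class_to_mask The class withheld from training.
#' @param cfg [network_config()] for the run.
#' @param tail_size,distance,activation Open-set settings (see
#'   [fit_openmax()]).
#' @param calibration_fraction Stratified fraction of retained samples held
#'   out for calibration (default 0.25).
#' @param pretrained Optional pretrained model to fine-tune.
#' @return A `masking_result`: `detection_accuracy`, the masked class, the
#'   per-sample open-set predictions, and the fitted calibration.
#' @export
unknown_masking_protocol <- function(x, labels, class_to_mask, cfg,
                                     tail_size = 20,
                                     distance = "euclidean",
                                     activation = "softmax",
                                     calibration_fraction = 0.25,
                                     pretrained = NULL) {
  x <- as_input_tensor(x)
  labels <- as.character(labels)
  if (!class_to_mask %in% labels) {
    abort_mt(sprintf("Class '%s' not present in the cohort.", class_to_mask),
             "masking_error")
  }
  keep <- labels != class_to_mask
  if (length(unique(labels[keep])) < 2) {
    abort_mt("At least two classes must remain after masking.", "masking_error")
  }
  xk <- x[keep, , , , drop = FALSE]
  yk <- labels[keep]
  if (calibration_fraction > 0) {
    cal_idx <- stratified_split(yk, calibration_fraction,
                                derive_seed(cfg$seed, "calsplit"))
    tr_idx <- setdiff(seq_along(yk), cal_idx)
  } else {
    cal_idx <- tr_idx <- seq_along(yk)
  }
  x_tr <- xk[tr_idx, , , , drop = FALSE]
  y_tr <- yk[tr_idx]
  model <- if (is.null(pretrained)) {
    cfg$num_classes <- length(unique(y_tr))
    cfg$input_shape <- dim(x)[2:3]
    m <- build_network(cfg, sort(unique(y_tr)))
    train_network(m, x_tr, y_tr, cfg)
  } else {
    fine_tune(pretrained, x_tr, y_tr, cfg)
  }
  cal <- fit_openmax(model, xk[cal_idx, , , , drop = FALSE], yk[cal_idx],
                     tail_size = tail_size,
                     distance = distance, activation = activation)
  xm <- x[!keep, , , , drop = FALSE]
  ps <- predict_scores(model, xm)
  av <- if (activation == "softmax") ps$softmax else ps$penultimate
  open_preds <- vapply(seq_len(nrow(ps$softmax)), function(i) {
    classify_open(openmax_rescore(cal, ps$softmax[i, ], av[i, ]))
  }, character(1))
  structure(
    list(detection_accuracy = mean(open_preds == "UNKNOWN"),
         class_masked = class_to_mask,
         predictions = tibble::tibble(sample = which(!keep), open_label = open_preds),
         calibration = cal, model = model),
    class = "masking_result"
  )
}

#' @export
print.masking_result <- function(x, ...) {
  cat(sprintf("<masking_result> class '%s' masked: %.1f%% of its samples flagged UNKNOWN\n",
              x$class_masked, 100 * x$detection_accuracy))
  invisible(x)
}
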