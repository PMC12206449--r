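#' Multi-class cross-entropy loss
#'
#' Mean over the batch of the negative log softmax probability of the true
#' class. With `class_weights` (one nonnegative weight per class, e.g. the
#' inverse-frequency weights from [inverse_frequency_weights()]), each
#' sample's term is multiplied by its class weight; weights are normalized
#' to mean 1 over classes so the loss scale is comparable with and without
#' weighting.
#'
#' @param logits Numeric matrix, samples x classes (a single vector is
#'   treated as one sample).
#' @param label Integer class indices in `1..C` (or a factor).
#' @param class_weights Optional numeric vector of length `C`.
#' @return Scalar loss (nonnegative).
#' @examples
#' cross_entropy(matrix(c(0, 0), 1), 1)  # log(2) for a uniform 2-class softmax
#' @export
cross_entropy <- function(logits, label, class_weights = NULL) {
  ce_loss_grad(rbind(logits), as.integer(label), class_weights)$loss
}

#' Inverse-frequency class weights
#'
#' The weight of class `c` is `N_total / N_c`, normalized so the mean
#' weight over classes is 1. Classes of sizes 90 and 10 therefore get
#' weights in ratio 1:9.
#'
#' @param labels Character or factor vector of class labels.
#' @param class_names Ordered class vocabulary.
#' @return Named numeric vector of weights.
#' @export
inverse_frequency_weights <- function(labels, class_names = sort(unique(labels))) {
  n <- length(labels)
  counts <- table(factor(labels, levels = class_names))
  if (any(counts == 0)) {
    abort_mt("Every class in the vocabulary needs at least one sample.",
             "class_weight_error")
  }
  w <- n / as.numeric(counts)
  w <- w / mean(w)
  stats::setNames(w, class_names)
}

# Loss + gradient in one pass. labels are 1-based class indices.
ce_loss_grad <- function(logits, labels, class_weights = NULL) {
  n <- nrow(logits)
  C <- ncol(logits)
  if (C < 2) abort_mt("Need at least 2 classes.", "loss_error")
  if (any(labels < 1 | labels > C)) {
    abort_mt("Labels outside 1..C.", "loss_error")
  }
  mx <- apply(logits, 1, max)
  z <- exp(logits - mx)
  sm <- z / rowSums(z)
  idx <- cbind(seq_len(n), labels)
  nll <- -log(pmax(sm[idx], 1e-300))
  w <- if (is.null(class_weights)) rep(1, n) else as.numeric(class_weights)[labels]
  loss <- mean(w * nll)
  dlogits <- sm
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits * (w / n)
  list(loss = loss, dlogits = dlogits, softmax = sm)
}

adam_init <- function(paths) {
  list(m = stats::setNames(vector("list", length(paths)), paths),
       v = stats::setNames(vector("list", length(paths)), paths), t = 0L)
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (path in names(grads)) {
    g <- grads[[path]]
    m <- state$m[[path]]
    v <- state$v[[path]]
    if (is.null(m)) {
      m <- g * 0
      v <- g * 0
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state$m[[path]] <- m
    state$v[[path]] <- v
    upd <- lr * (m / bc1) / (sqrt(v / bc2) + eps)
    model <- model_set_param(model, path, model_get_param(model, path) - upd)
  }
  list(model = model, state = state)
}

# Prepare an input tensor: accept (N, H, W) or (N, H, W, 1).
as_input_tensor <- function(x) {
  d <- dim(x)
  if (length(d) == 3) dim(x) <- c(d, 1L)
  if (length(dim(x)) != 4 || dim(x)[4] != 1) {
    abort_mt("Input must be a (samples, probes, d) array (single channel).",
             "shape_error")
  }
  x
}

stratified_split <- function(labels, fraction, seed) {
  with_seed(seed, {
    val <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_val <- if (length(idx) >= 2) max(1L, round(fraction * length(idx))) else 0L
      if (n_val > 0) val <- c(val, sample(idx, n_val))
    }
    sort(val)
  })
}

#' Train the network
#'
#' Minimizes multi-class cross-entropy with Adam at the configured learning
#' rate and batch size. A stratified `val_fraction` of the data is held out
#' for early stopping: training stops once the validation loss has failed
#' to improve for `patience` consecutive epochs (or at `max_epochs`), and
#' the parameters from the best validation epoch are restored. Fully
#' reproducible for a fixed config seed under single-threaded execution.
#'
#' @param model An untrained or pretrained `trained_model` (from
#'   [build_network()]).
#' @param x Fused input tensor, `(samples, probes, d)` array (see
#'   [fuse_cohort()]); must be missing-free.
#' @param labels Character vector of class labels (must match the model's
#'   vocabulary).
#' @param cfg Optional [network_config()] override (defaults to the
#'   model's).
#' @return The trained model; `$training_log` is a tibble with per-epoch
#'   train/validation losses.
#' @export
train_network <- function(model, x, labels, cfg = NULL) {
  stopifnot(inherits(model, "trained_model"))
  cfg <- cfg %||% model$cfg
  x <- as_input_tensor(x)
  if (anyNA(x)) abort_mt("Training input contains missing values.", "shape_error")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    abort_mt("Training requires at least two classes.", "training_error")
  }
  if (!all(labels %in% model$class_names)) {
    abort_mt("Labels outside the model's class vocabulary.", "training_error")
  }
  y <- match(labels, model$class_names)
  n <- dim(x)[1]
  cw <- NULL
  if (cfg$class_weighting) {
    cw <- inverse_frequency_weights(labels, model$class_names)
  }
  val_idx <- stratified_split(labels, cfg$val_fraction, derive_seed(cfg$seed, "valsplit"))
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(val_idx) == 0) val_idx <- train_idx # degenerate tiny cohorts
  xv <- x[val_idx, , , , drop = FALSE]
  yv <- y[val_idx]
  opt <- adam_init(character(0))
  best_loss <- Inf
  best_snap <- NULL
  wait <- 0L
  log <- vector("list", cfg$max_epochs)
  shuffle_seed <- derive_seed(cfg$seed, "shuffle")
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed(shuffle_seed + epoch, sample(train_idx))
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      bidx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      xb <- x[bidx, , , , drop = FALSE]
      fw <- model_forward(model, xb, train = TRUE, need_cache = TRUE)
      model <- fw$model
      lg <- ce_loss_grad(fw$logits, y[bidx], cw)
      bw <- model_backward(model, fw$caches, lg$dlogits)
      st <- adam_step(model, bw$grads, opt, cfg$learning_rate)
      model <- st$model
      opt <- st$state
      ep_loss <- ep_loss + lg$loss
      nb <- nb + 1L
    }
    fv <- model_forward(model, xv, train = FALSE)
    vl <- ce_loss_grad(fv$logits, yv, cw)$loss
    log[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = ep_loss / nb,
                                   val_loss = vl)
    if (vl < best_loss - 1e-8) {
      best_loss <- vl
      best_snap <- model_snapshot(model)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= max(cfg$patience, 1L)) break
    }
  }
  if (!is.null(best_snap)) model <- model_restore(model, best_snap)
  model$training_log <- dplyr::bind_rows(log[!vapply(log, is.null, logical(1))])
  model$trained <- TRUE
  model$cfg <- cfg
  model
}

#' Two-phase transfer learning: fine-tune a pretrained network
#'
#' Re-initializes the classification head for the target label vocabulary,
#' freezes the first `freeze_blocks` stages (the stem is frozen together
#' with stage 1; `freeze_blocks = 4` trains only the head, 0 trains
#' everything), and trains on the target data with the same optimizer and
#' loss settings as pretraining. Frozen stages keep bit-identical
#' parameters and batch-norm statistics; their batch-norm layers run in
#' inference mode during fine-tuning.
#'
#' @param pretrained A trained `trained_model` (source domain).
#' @param x Target-domain fused tensor (same probes-x-d shape as
#'   pretraining).
#' @param labels Target-domain class labels (define the new vocabulary).
#' @param cfg [network_config()] for fine-tuning; `freeze_blocks` is taken
#'   from here (default 2). `num_classes` is overridden by the target
#'   vocabulary.
#' @return The fine-tuned model.
#' @export
fine_tune <- function(pretrained, x, labels, cfg = NULL) {
  stopifnot(inherits(pretrained, "trained_model"))
  cfg <- cfg %||% pretrained$cfg
  x <- as_input_tensor(x)
  if (!identical(dim(x)[2:3], as.integer(pretrained$cfg$input_shape))) {
    abort_mt("Target input shape must match the pretrained input shape.",
             "shape_error")
  }
  class_names <- sort(unique(as.character(labels)))
  cfg$num_classes <- length(class_names)
  cfg$input_shape <- pretrained$cfg$input_shape
  model <- pretrained
  model$cfg <- cfg
  model$class_names <- class_names
  # fresh head for the target vocabulary
  model$modules[["head.fc"]] <- with_seed(derive_seed(cfg$seed, "head"),
                                          new_dense(model$feature_dim, cfg$num_classes))
  # freeze stem + first freeze_blocks stages
  for (nm in names(model$modules)) {
    st <- module_stage(nm)
    frozen <- (st >= 1 && st <= cfg$freeze_blocks) || (st == 0 && cfg$freeze_blocks >= 1)
    model$modules[[nm]]$frozen <- frozen
  }
  model$frozen_active <- TRUE
  model <- train_network(model, x, labels, cfg)
  model$frozen_active <- FALSE
  for (nm in names(model$modules)) model$modules[[nm]]$frozen <- NULL
  model$fine_tuned <- TRUE
  model
}

#' Predict class scores
#'
#' Runs the network in inference mode and returns per-sample softmax score
#' vectors (each summing to 1) together with the activation vectors the
#' open-set layer consumes: the softmax vector itself (the default
#' activation-vector choice) and the penultimate pooled features.
#'
#' @param model A trained `trained_model`.
#' @param x Fused input tensor.
#' @return List with `softmax` (n x C matrix, columns named by class),
#'   `logits`, `penultimate` (n x feature matrix), and `predicted`
#'   (character vector of argmax labels).
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "trained_model"))
  x <- as_input_tensor(x)
  fw <- model_forward(model, x, train = FALSE)
  logits <- fw$logits
  mx <- apply(logits, 1, max)
  z <- exp(logits - mx)
  sm <- z / rowSums(z)
  colnames(sm) <- model$class_names
  colnames(logits) <- model$class_names
  list(softmax = sm, logits = logits, penultimate = fw$pooled,
       predicted = model$class_names[max.col(sm, ties.method = "first")])
}

#' @rdname tidy_methods
#' @export
tidy.trained_model <- function(x, ...) {
  x$training_log
}

#' @rdname tidy_methods
#' @export
glance.trained_model <- function(x, ...) {
  log <- x$training_log
  tibble::tibble(
    epochs = nrow(log),
    final_train_loss = if (nrow(log)) log$train_loss[nrow(log)] else NA_real_,
    best_val_loss = if (nrow(log)) min(log$val_loss) else NA_real_,
    num_classes = x$cfg$num_classes,
    fine_tuned = isTRUE(x$fine_tuned),
    freeze_blocks = x$cfg$freeze_blocks,
    seed = x$cfg$seed
  )
}
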