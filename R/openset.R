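## Open-set layer: per-class Weibull calibration of activation-vector
## distances and redistribution of softmax mass to an "unknown" class.

# Deterministic maximum-likelihood fit of a 2-parameter Weibull (location
# fixed at 0) by profiling the shape: the MLE shape k solves
#   sum(x^k log x) / sum(x^k) - 1/k - mean(log x) = 0,
# then scale = mean(x^k)^(1/k). Degenerate tails (all distances ~0 or all
# equal) fall back to a step-like fit with a floored scale.
weibull_tail_fit <- function(x, scale_floor = 1e-8) {
  x <- pmax(x, 1e-12)
  if (max(x) < 1e-10 || stats::sd(x) < 1e-12) {
    # zero-distance or constant tail: near-degenerate step CDF at max(x)
    return(list(shape = 1000, scale = max(max(x), scale_floor)))
  }
  mx <- max(x)
  xs <- x / mx # scale-invariant shape; keeps x^k finite for large k
  mlx <- mean(log(xs))
  g <- function(k) {
    xk <- xs^k
    sum(xk * log(xs)) / sum(xk) - 1 / k - mlx
  }
  lo <- 1e-3
  hi <- 1e3
  # g is increasing in k; bracket defensively
  if (g(lo) > 0) {
    k <- lo
  } else if (g(hi) < 0) {
    k <- hi
  } else {
    k <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  }
  list(shape = k, scale = max(mx * mean(xs^k)^(1 / k), scale_floor))
}

activation_distance <- function(av, mav, distance = c("euclidean", "cosine")) {
  distance <- match.arg(distance)
  if (distance == "euclidean") {
    sqrt(sum((av - mav)^2))
  } else {
    den <- sqrt(sum(av^2)) * sqrt(sum(mav^2))
    if (den == 0) return(1)
    1 - sum(av * mav) / den
  }
}

#' Calibrate the open-set (OpenMax) layer
#'
#' For each known class, computes the mean activation vector (MAV) over
#' correctly-classified training samples and fits a Weibull distribution
#' (location 0, maximum likelihood) to the `tail_size` largest distances
#' between those samples' activation vectors and the MAV. The fitted tail
#' CDF later converts a query's distance into a per-class confidence
#' (Eqs. of the open-set rescoring in [openmax_rescore()]).
#'
#' The activation vector is the softmax output by default — distances are
#' computed after softmax — with the penultimate pooled features available
#' as an alternative.
#'
#' @param model A trained `trained_model`.
#' @param x Training fused tensor.
#' @param labels Training labels.
#' @param tail_size Tail length for the Weibull fit (shrinks with a warning
#'   when a class has fewer correctly-classified samples).
#' @param distance `"euclidean"` (default) or `"cosine"`.
#' @param activation `"softmax"` (default) or `"penultimate"`.
#' @return An `openmax_calibration`: per-class MAVs, Weibull (shape, scale),
#'   and settings.
#' @export
fit_openmax <- function(model, x, labels, tail_size = 20,
                        distance = c("euclidean", "cosine"),
                        activation = c("softmax", "penultimate")) {
  distance <- match.arg(distance)
  activation <- match.arg(activation)
  labels <- as.character(labels)
  ps <- predict_scores(model, x)
  av <- if (activation == "softmax") ps$softmax else ps$penultimate
  classes <- model$class_names
  mavs <- list()
  weibull <- list()
  for (cl in classes) {
    idx <- which(labels == cl & ps$predicted == cl)
    if (length(idx) == 0) {
      abort_mt(sprintf(
        "Class '%s' has no correctly-classified training sample; cannot calibrate.",
        cl
      ), "calibration_error")
    }
    avc <- av[idx, , drop = FALSE]
    mav <- colMeans(avc)
    dists <- apply(avc, 1, activation_distance, mav = mav, distance = distance)
    ts <- tail_size
    if (length(dists) < ts) {
      warning(sprintf("Class '%s': tail shrunk to %d available distances.",
                      cl, length(dists)))
      ts <- length(dists)
    }
    tail <- sort(dists, decreasing = TRUE)[seq_len(ts)]
    mavs[[cl]] <- mav
    weibull[[cl]] <- weibull_tail_fit(tail)
  }
  structure(
    list(mavs = mavs, weibull = weibull, class_names = classes,
         tail_size = tail_size, distance = distance, activation = activation),
    class = "openmax_calibration"
  )
}

#' @export
print.openmax_calibration <- function(x, ...) {
  cat(sprintf("<openmax_calibration> %d classes, %s distance on %s activations, tail %d\n",
              length(x$class_names), x$distance, x$activation, x$tail_size))
  invisible(x)
}

#' @rdname tidy_methods
#' @export
tidy.openmax_calibration <- function(x, ...) {
  tibble::tibble(
    class = x$class_names,
    weibull_shape = vapply(x$weibull, `[[`, numeric(1), "shape")[x$class_names],
    weibull_scale = vapply(x$weibull, `[[`, numeric(1), "scale")[x$class_names]
  )
}

#' Open-set rescoring of softmax outputs
#'
#' Converts the query's distance to each class MAV into a confidence
#' `w_j = 1 - WeibullCDF_j(distance_j)`, scales each softmax score by its
#' confidence (`score_j' = score_j * w_j`), and collects the discounted
#' mass into an unknown-class score
#' (`score_unknown = sum_j score_j * (1 - w_j)`). Mass is conserved: the
#' adjusted known scores plus the unknown score sum to the input score
#' mass.
#'
#' @param cal An `openmax_calibration` from [fit_openmax()].
#' @param softmax_scores Per-class scores summing to 1 (named or in
#'   calibration class order).
#' @param activation_vector The sample's activation vector (same kind as
#'   the calibration's).
#' @return An `openmax_scores` list: `scores` (adjusted known scores),
#'   `unknown`, `confidence` (the `w_j`), `distances`.
#' @export
openmax_rescore <- function(cal, softmax_scores, activation_vector) {
  stopifnot(inherits(cal, "openmax_calibration"))
  C <- length(cal$class_names)
  if (length(softmax_scores) != C) {
    abort_mt("Score vector length must match the calibration's class count.",
             "calibration_error")
  }
  if (!is.null(names(softmax_scores))) {
    softmax_scores <- softmax_scores[cal$class_names]
  }
  d <- vapply(cal$class_names, function(cl) {
    activation_distance(activation_vector, cal$mavs[[cl]], cal$distance)
  }, numeric(1))
  w <- vapply(cal$class_names, function(cl) {
    wb <- cal$weibull[[cl]]
    1 - stats::pweibull(d[[cl]], shape = wb$shape, scale = wb$scale)
  }, numeric(1))
  adjusted <- softmax_scores * w
  unknown <- sum(softmax_scores * (1 - w))
  structure(
    list(scores = stats::setNames(as.numeric(adjusted), cal$class_names),
         unknown = unknown,
         confidence = stats::setNames(as.numeric(w), cal$class_names),
         distances = stats::setNames(as.numeric(d), cal$class_names)),
    class = "openmax_scores"
  )
}

#' Open-set classification decision
#'
#' Argmax over the adjusted known-class scores and the unknown score. Ties
#' never produce UNKNOWN: when the unknown score equals the best known
#' score the known class wins, and among tied known classes the one with
#' the lowest index in the calibration order is returned.
#'
#' @param scores An `openmax_scores` from [openmax_rescore()].
#' @param unknown_label Label returned for the unknown class.
#' @return A single class label or `unknown_label`.
#' @export
classify_open <- function(scores, unknown_label = "UNKNOWN") {
  stopifnot(inherits(scores, "openmax_scores"))
  best_known <- which.max(scores$scores) # first max -> lowest index on ties
  if (scores$unknown > scores$scores[best_known]) {
    unknown_label
  } else {
    names(scores$scores)[best_known]
  }
}

#' Serialize / restore an open-set calibration as JSON
#'
#' @param cal An `openmax_calibration`.
#' @param path JSON file path.
#' @return `write_openmax_calibration()` returns `path` invisibly;
#'   `read_openmax_calibration()` the restored calibration.
#' @export
write_openmax_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "openmax_calibration"))
  payload <- list(
    class_names = cal$class_names, tail_size = cal$tail_size,
    distance = cal$distance, activation = cal$activation,
    mavs = cal$mavs, weibull = cal$weibull
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_openmax_calibration
#' @export
read_openmax_calibration <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      mavs = lapply(p$mavs, as.numeric)[p$class_names],
      weibull = lapply(p$weibull, function(w) list(shape = w$shape, scale = w$scale))[p$class_names],
      class_names = p$class_names, tail_size = p$tail_size,
      distance = p$distance, activation = p$activation
    ),
    class = "openmax_calibration"
  )
}
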