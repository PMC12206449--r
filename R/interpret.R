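#' Gradient-based probe attribution
#'
#' For each sample, computes the gradient of the target class's logit with
#' respect to the fused input tensor and forms the gradient-times-input
#' attribution (or the plain absolute gradient). The per-probe saliency is
#' the L2 norm of that attribution over the embedding dimension, averaged
#' over samples. With gradient-times-input, probes whose beta value is 0 in
#' every sample receive saliency exactly 0 (their fused rows are zero).
#'
#' Typical use passes the correctly-predicted samples of the target class,
#' so the saliency reflects what drives confident predictions of that
#' class; [attribute_class_probes()] wraps that filtering.
#'
#' @param model A trained `trained_model`.
#' @param x Fused input tensor `(samples, probes, d)`.
#' @param target_class Class whose logit is attributed (must be in the
#'   model vocabulary).
#' @param method `"grad_x_input"` (default) or `"abs_grad"`.
#' @param probe_names Optional probe ids (defaults to `dimnames(x)[[2]]`).
#' @return An `attribution_result`: tibble (`$saliency`) with `probe_id`,
#'   `saliency`, `rank`, plus the target class and sample count.
#' @export
attribute_probes <- function(model, x, target_class,
                             method = c("grad_x_input", "abs_grad"),
                             probe_names = NULL) {
  method <- match.arg(method)
  x <- as_input_tensor(x)
  n <- dim(x)[1]
  if (n < 1) abort_mt("Need at least one sample.", "attribution_error")
  ci <- match(target_class, model$class_names)
  if (is.na(ci)) {
    abort_mt(sprintf("Unknown target class '%s'.", target_class),
             "attribution_error")
  }
  probe_names <- probe_names %||% dimnames(x)[[2]] %||%
    sprintf("probe%04d", seq_len(dim(x)[2]))
  fw <- model_forward(model, x, train = FALSE, need_cache = TRUE)
  dlogits <- matrix(0, n, model$cfg$num_classes)
  dlogits[, ci] <- 1
  bw <- model_backward(model, fw$caches, dlogits, need_input_grad = TRUE)
  grad <- bw$dx # (N, probes, d, 1)
  attr_tensor <- if (method == "grad_x_input") grad * x else abs(grad)
  d <- dim(attr_tensor)
  dim(attr_tensor) <- d[1:3]
  # per-sample per-probe L2 over embedding dim, then mean over samples
  sal_mat <- sqrt(apply(attr_tensor^2, c(1, 2), sum))
  saliency <- colMeans(sal_mat)
  ord <- order(-saliency, probe_names)
  structure(
    list(
      saliency = tibble::tibble(
        probe_id = probe_names[ord], saliency = saliency[ord],
        rank = seq_along(ord)
      ),
      target_class = target_class, n_samples_used = n, method = method
    ),
    class = "attribution_result"
  )
}

#' @rdname attribute_probes
#' @param labels Sample labels; only correctly-predicted samples of
#'   `target_class` are attributed (falling back to all target-class
#'   samples, with a warning, if none is correctly predicted).
#' @export
attribute_class_probes <- function(model, x, labels, target_class,
                                   method = "grad_x_input",
                                   probe_names = NULL) {
  x <- as_input_tensor(x)
  labels <- as.character(labels)
  ps <- predict_scores(model, x)
  idx <- which(labels == target_class & ps$predicted == target_class)
  if (length(idx) == 0) {
    warning(sprintf(
      "No correctly-predicted '%s' sample; attributing all '%s' samples.",
      target_class, target_class
    ))
    idx <- which(labels == target_class)
  }
  if (length(idx) == 0) {
    abort_mt(sprintf("No sample of class '%s'.", target_class),
             "attribution_error")
  }
  attribute_probes(model, x[idx, , , , drop = FALSE], target_class,
                   method = method, probe_names = probe_names)
}

#' Consensus attribution over independently trained models
#'
#' A single network frequently concentrates its decision on a subset of
#' redundant markers — which subset depends on the initialization seed —
#' so single-model saliency rankings are unstable. Consensus attribution
#' trains-agnostically averages the per-probe saliency of several models
#' (each normalized to sum 1, so every model votes with equal weight),
#' the same stabilization logic that makes random-forest importance more
#' reliable than a single tree's.
#'
#' @param models List of trained `trained_model`s (typically identical
#'   configs with different seeds). A list of length one reproduces
#'   single-model attribution up to normalization.
#' @param x Fused input tensor.
#' @param labels Sample labels (correctly-predicted target-class samples
#'   are attributed per model).
#' @param target_class Class whose logit is attributed.
#' @param method,probe_names Passed to [attribute_probes()].
#' @return An `attribution_result` with consensus saliencies (mean of
#'   per-model normalized saliencies).
#' @export
consensus_attribution <- function(models, x, labels, target_class,
                                  method = "grad_x_input",
                                  probe_names = NULL) {
  stopifnot(is.list(models), length(models) >= 1)
  x <- as_input_tensor(x)
  probe_names <- probe_names %||% dimnames(x)[[2]] %||%
    sprintf("probe%04d", seq_len(dim(x)[2]))
  total <- stats::setNames(numeric(length(probe_names)), probe_names)
  n_used <- 0L
  for (model in models) {
    attr <- attribute_class_probes(model, x, labels, target_class,
                                   method = method, probe_names = probe_names)
    v <- stats::setNames(attr$saliency$saliency, attr$saliency$probe_id)
    s <- sum(v)
    if (s > 0) v <- v / s
    total <- total + v[probe_names]
    n_used <- n_used + attr$n_samples_used
  }
  sal <- total / length(models)
  ord <- order(-sal, probe_names)
  structure(
    list(
      saliency = tibble::tibble(probe_id = probe_names[ord],
                                saliency = unname(sal[ord]),
                                rank = seq_along(ord)),
      target_class = target_class, n_samples_used = n_used,
      method = paste0("consensus_", method), n_models = length(models)
    ),
    class = "attribution_result"
  )
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("<attribution_result> class '%s', %d samples, %s\n",
              x$target_class, x$n_samples_used, x$method))
  print(utils::head(x$saliency, 5))
  invisible(x)
}

#' @rdname tidy_methods
#' @export
tidy.attribution_result <- function(x, ...) {
  x$saliency
}

#' Map top-ranked probes to genes
#'
#' Takes the `top_k` highest-saliency probes, expands their semicolon-joined
#' gene annotations from the manifest, and de-duplicates preserving
#' first-occurrence order (so genes hit by the strongest probes come
#' first). Unannotated probes contribute nothing.
#'
#' @param attr An `attribution_result`.
#' @param manifest Probe manifest tibble covering all ranked probes.
#' @param top_k How many top probes to expand (default 100; capped at the
#'   probe count with a warning).
#' @return Character vector of unique gene symbols, ordered by first
#'   occurrence.
#' @export
map_top_probes_to_genes <- function(attr, manifest, top_k = 100) {
  stopifnot(inherits(attr, "attribution_result"))
  validate_manifest(manifest)
  ranked <- attr$saliency$probe_id
  if (!all(ranked %in% manifest$probe_id)) {
    abort_mt("Manifest does not cover all ranked probes.", "manifest_error")
  }
  if (top_k > length(ranked)) {
    warning(sprintf("top_k = %d exceeds probe count %d; using all probes.",
                    top_k, length(ranked)))
    top_k <- length(ranked)
  }
  if (top_k == 0) return(character(0))
  top <- ranked[seq_len(top_k)]
  ann <- manifest$genes[match(top, manifest$probe_id)]
  genes <- unlist(strsplit(ann, ";", fixed = TRUE))
  genes <- trimws(genes)
  genes <- genes[nzchar(genes)]
  out <- unique(genes)
  if (length(out) == 0) warning("None of the top probes carries a gene annotation.")
  out
}

#' Write a saliency table as TSV
#'
#' @param attr An `attribution_result`.
#' @param manifest Optional manifest to append gene annotations.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_saliency_table <- function(attr, path, manifest = NULL) {
  tab <- attr$saliency
  if (!is.null(manifest)) {
    tab <- dplyr::left_join(tab,
                            dplyr::select(manifest, "probe_id", "genes"),
                            by = "probe_id")
  }
  readr::write_tsv(tab, path)
  invisible(path)
}
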