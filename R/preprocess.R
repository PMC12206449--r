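#' Beta value from signal intensities
#'
#' Computes the methylation fraction `beta = M / (M + U + offset)` from
#' methylated (`M`) and unmethylated (`U`) signal intensities. The offset
#' stabilises the ratio against near-zero total intensity; 100 is the common
#' array-platform convention.
#'
#' @param M,U Nonnegative numeric vectors of methylated / unmethylated
#'   intensities (recycled to a common length).
#' @param offset Nonnegative stabilising constant added to the denominator.
#' @return Numeric vector of beta values in `[0, 1]`.
#' @examples
#' compute_beta(300, 100)        # 0.6 with the default offset of 100
#' compute_beta(500, 500, 0)     # 0.5
#' @export
compute_beta <- function(M, U, offset = 100) {
  if (any(M < 0) || any(U < 0) || any(offset < 0)) {
    abort_mt("Intensities and offset must be nonnegative.", "degenerate_input_error")
  }
  denom <- M + U + offset
  if (any(denom == 0)) {
    abort_mt("M + U + offset must be positive (all-zero intensities are degenerate).",
             "degenerate_input_error")
  }
  M / denom
}

#' Detection-P quality control
#'
#' Masks beta values whose detection P-value strictly exceeds `threshold`:
#' such probes are indistinguishable from background in that sample and are
#' set to missing (`NA`). Values at exactly the threshold are retained.
#'
#' @param cohort A [methylation_cohort()].
#' @param pvals Numeric matrix of detection P-values in `[0, 1]`, same
#'   dimnames as `cohort$beta`.
#' @param threshold Strict masking threshold (default 0.01).
#' @return The cohort with failing entries set to `NA`.
#' @export
apply_detection_qc <- function(cohort, pvals, threshold = 0.01) {
  stopifnot(inherits(cohort, "methylation_cohort"))
  if (!is.matrix(pvals) || !identical(dim(pvals), dim(cohort$beta)) ||
      !identical(rownames(pvals), rownames(cohort$beta)) ||
      !identical(colnames(pvals), colnames(cohort$beta))) {
    abort_mt("Detection-P matrix must align with the cohort (same dims and dimnames).",
             "alignment_error")
  }
  if (anyNA(pvals) || min(pvals) < 0 || max(pvals) > 1) {
    abort_mt("Detection P-values must lie in [0, 1] with no missing entries.",
             "alignment_error")
  }
  beta <- cohort$beta
  beta[pvals > threshold] <- NA_real_
  methylation_cohort(beta, labels = cohort$labels, domain_tag = cohort$domain_tag)
}

#' Missingness filters
#'
#' `filter_probes_by_class_missingness()` drops a probe when its missing
#' fraction strictly exceeds `max_frac` in any single class (the per-class
#' view protects minority classes from probes that fail only in them).
#' `filter_samples_by_missingness()` drops samples whose overall missing
#' fraction strictly exceeds `max_frac`. Both keep boundary cases (fractions
#' exactly at the threshold are retained) and preserve the original ordering
#' of what survives.
#'
#' @param cohort A labelled [methylation_cohort()] (labels required for the
#'   probe filter).
#' @param max_frac Strict missingness threshold (probe filter default 0.30,
#'   sample filter default 0.20).
#' @return The filtered cohort.
#' @export
filter_probes_by_class_missingness <- function(cohort, max_frac = 0.30) {
  stopifnot(inherits(cohort, "methylation_cohort"))
  if (is.null(cohort$labels)) {
    abort_mt("Per-class probe filtering requires sample labels.", "precondition_error")
  }
  miss <- is.na(cohort$beta)
  classes <- unique(cohort$labels)
  drop <- rep(FALSE, ncol(miss))
  for (cl in classes) {
    idx <- cohort$labels == cl
    drop <- drop | (colMeans(miss[idx, , drop = FALSE]) > max_frac)
  }
  subset_cohort(cohort, probes = probe_ids(cohort)[!drop])
}

#' @rdname filter_probes_by_class_missingness
#' @export
filter_samples_by_missingness <- function(cohort, max_frac = 0.20) {
  stopifnot(inherits(cohort, "methylation_cohort"))
  frac <- rowMeans(is.na(cohort$beta))
  keep <- frac <= max_frac
  if (!any(keep)) {
    warning("All samples exceed the missingness threshold; returning an empty cohort.")
  }
  subset_cohort(cohort, samples = sample_ids(cohort)[keep])
}

#' Zero-fill residual missing values
#'
#' Replaces every remaining `NA` beta value with 0. Zero-filling is used in
#' place of imputation so that sparse minority classes are not distorted by
#' borrowed values; a zero reads as "no methylation signal detected".
#' Idempotent.
#'
#' @param cohort A [methylation_cohort()].
#' @return The cohort with no missing entries.
#' @export
zero_fill <- function(cohort) {
  stopifnot(inherits(cohort, "methylation_cohort"))
  beta <- cohort$beta
  beta[is.na(beta)] <- 0
  methylation_cohort(beta, labels = cohort$labels, domain_tag = cohort$domain_tag)
}

#' Rank probes by random-forest importance on the source domain
#'
#' Fits a random forest (500 trees, impurity importance) of class labels on
#' the source-domain beta matrix and ranks probes by decreasing importance,
#' breaking ties lexicographically by probe id. Selection uses source-domain
#' data only, so no target labels can leak into the feature set. Missing
#' entries are zero-filled for the forest fit, consistent with the
#' pipeline's zero-filling of model inputs. A variance ranking is available
#' as a lighter-weight fallback.
#'
#' @param source A labelled source-domain [methylation_cohort()].
#' @param k Number of probes to keep (default 10000; capped at the probe
#'   count with a warning).
#' @param seed Integer seed controlling the forest; fixed seed gives a fixed
#'   ranking.
#' @param method `"random_forest"` (default) or `"variance"`.
#' @param num_trees Trees in the forest.
#' @return A `feature_selection` object: tibble of `probe_id`, `importance`,
#'   `rank` (in `$ranking`), plus the `seed` and `method` used.
#' @export
select_top_variable_probes <- function(source, k = 10000, seed = 1,
                                       method = c("random_forest", "variance"),
                                       num_trees = 500) {
  stopifnot(inherits(source, "methylation_cohort"))
  method <- match.arg(method)
  if (is.null(source$labels)) {
    abort_mt("Probe selection requires source-domain labels.", "precondition_error")
  }
  p <- ncol(source$beta)
  if (k > p) {
    warning(sprintf("k = %d exceeds probe count %d; returning all probes.", k, p))
    k <- p
  }
  x <- source$beta
  x[is.na(x)] <- 0
  # canonical sample order so the ranking is invariant to row permutations
  x <- x[order(rownames(x)), , drop = FALSE]
  if (method == "random_forest") {
    y <- factor(source$labels[rownames(x)])
    fit <- with_seed(seed, randomForest::randomForest(
      x = x, y = y, ntree = num_trees, importance = FALSE
    ))
    imp <- randomForest::importance(fit, type = 2)[, 1]
    imp <- imp[colnames(x)]
  } else {
    imp <- apply(x, 2, stats::var)
  }
  ord <- order(-imp, colnames(x))
  ranking <- tibble::tibble(
    probe_id = colnames(x)[ord],
    importance = unname(imp[ord]),
    rank = seq_len(p)
  )
  structure(
    list(ranking = ranking[seq_len(k), ], seed = seed, method = method, k = k),
    class = "feature_selection"
  )
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> top %d probes by %s (seed %d)\n",
              nrow(x$ranking), x$method, x$seed))
  print(utils::head(x$ranking, 5))
  invisible(x)
}

#' Harmonize selected probes against the target cohort
#'
#' Intersects a source-domain feature selection with the target cohort,
#' keeping only selected probes that are present in the target and have an
#' overall missing fraction of at most `max_missing` across target samples.
#' Order follows the selection ranking. Call this before [zero_fill()] on
#' the target, while missingness is still observable.
#'
#' @param selected A `feature_selection` from [select_top_variable_probes()].
#' @param target The target-domain [methylation_cohort()] (not yet
#'   zero-filled).
#' @param max_missing Inclusive missingness cap (default 0.30).
#' @return Character vector of harmonized probe ids, in selection order.
#' @export
harmonize_feature_set <- function(selected, target, max_missing = 0.30) {
  stopifnot(inherits(selected, "feature_selection"),
            inherits(target, "methylation_cohort"))
  frac <- colMeans(is.na(target$beta))
  sel <- selected$ranking$probe_id
  keep <- sel[sel %in% probe_ids(target)]
  keep <- keep[frac[keep] <= max_missing]
  if (length(keep) == 0) {
    abort_mt("No selected probe survives harmonization against the target cohort.",
             "harmonization_error")
  }
  keep
}

#' Full preprocessing cascade
#'
#' Runs the fixed pipeline order on a target cohort: detection-P QC, then
#' the per-class probe filter, then the sample filter, then (optionally)
#' harmonization against a source-domain probe selection, then zero-filling.
#' Returns the model-ready cohort together with a run manifest recording
#' thresholds, seed and surviving counts after every stage, suitable for
#' JSON serialisation.
#'
#' @param cohort Target [methylation_cohort()] with labels.
#' @param pvals Optional detection-P matrix.
#' @param selected Optional `feature_selection` to harmonize against.
#' @param detection_threshold,probe_max_missing,sample_max_missing,harmonize_max_missing
#'   Stage thresholds (defaults 0.01, 0.30, 0.20, 0.30).
#' @return List with `cohort` (zero-filled) and `manifest` (list of stage
#'   counts and settings).
#' @export
preprocess_cohort <- function(cohort, pvals = NULL, selected = NULL,
                              detection_threshold = 0.01,
                              probe_max_missing = 0.30,
                              sample_max_missing = 0.20,
                              harmonize_max_missing = 0.30) {
  stages <- list(input = dim(cohort))
  if (!is.null(pvals)) {
    cohort <- apply_detection_qc(cohort, pvals, detection_threshold)
  }
  stages$after_qc <- dim(cohort)
  cohort <- filter_probes_by_class_missingness(cohort, probe_max_missing)
  stages$after_probe_filter <- dim(cohort)
  cohort <- filter_samples_by_missingness(cohort, sample_max_missing)
  stages$after_sample_filter <- dim(cohort)
  if (!is.null(selected)) {
    keep <- harmonize_feature_set(selected, cohort, harmonize_max_missing)
    cohort <- subset_cohort(cohort, probes = keep)
  }
  stages$after_harmonization <- dim(cohort)
  cohort <- zero_fill(cohort)
  manifest <- list(
    thresholds = list(
      detection = detection_threshold, probe_missing = probe_max_missing,
      sample_missing = sample_max_missing, harmonize_missing = harmonize_max_missing
    ),
    selection_seed = if (!is.null(selected)) selected$seed else NULL,
    stages = lapply(stages, function(d) list(samples = d[1], probes = d[2]))
  )
  list(cohort = cohort, manifest = manifest)
}
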