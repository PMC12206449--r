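#' Methylation cohort container
#'
#' A `methylation_cohort` bundles a samples-by-probes beta-value matrix with
#' optional per-sample class labels and a domain tag. Beta values are
#' methylation fractions in `[0, 1]`; missing measurements (for example,
#' probes failing detection-P quality control) are encoded as `NA` until
#' [zero_fill()] replaces them with 0 for model input.
#'
#' @param beta Numeric matrix, samples in rows (rownames = sample ids),
#'   probes in columns (colnames = probe ids). Entries in `[0, 1]` or `NA`.
#' @param labels Optional character vector of class labels, either named by
#'   sample id or in row order of `beta`. Must cover every sample if given.
#' @param domain_tag `"source"` (bulk methylation) or `"target"` (cfDNA).
#'
#' @return An object of class `methylation_cohort`.
#' @examples
#' beta <- matrix(runif(6), 2, 3,
#'   dimnames = list(c("s1", "s2"), c("p1", "p2", "p3")))
#' methylation_cohort(beta, labels = c(s1 = "A", s2 = "B"))
#' @export
methylation_cohort <- function(beta, labels = NULL, domain_tag = c("target", "source")) {
  domain_tag <- match.arg(domain_tag)
  if (!is.matrix(beta) || !is.numeric(beta)) {
    abort_mt("`beta` must be a numeric matrix (samples x probes).", "cohort_error")
  }
  if ((nrow(beta) > 0 && is.null(rownames(beta))) ||
      (ncol(beta) > 0 && is.null(colnames(beta)))) {
    abort_mt("`beta` needs sample ids as rownames and probe ids as colnames.", "cohort_error")
  }
  if (is.null(rownames(beta))) rownames(beta) <- character(0)
  if (is.null(colnames(beta))) colnames(beta) <- character(0)
  if (anyDuplicated(rownames(beta)) || anyDuplicated(colnames(beta))) {
    abort_mt("Sample ids and probe ids must be unique.", "cohort_error")
  }
  vals <- beta[!is.na(beta)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 1)) {
    abort_mt("Non-missing beta values must lie in [0, 1].", "cohort_error")
  }
  if (!is.null(labels)) {
    if (!is.null(names(labels))) {
      if (!all(rownames(beta) %in% names(labels))) {
        abort_mt("`labels` must cover every sample.", "cohort_error")
      }
      labels <- labels[rownames(beta)]
    } else {
      if (length(labels) != nrow(beta)) {
        abort_mt("Unnamed `labels` must have one entry per sample.", "cohort_error")
      }
      names(labels) <- rownames(beta)
    }
    labels <- as.character(stats::setNames(labels, names(labels)))
    names(labels) <- rownames(beta)
  }
  structure(
    list(beta = beta, labels = labels, domain_tag = domain_tag),
    class = "methylation_cohort"
  )
}

#' @export
print.methylation_cohort <- function(x, ...) {
  miss <- mean(is.na(x$beta))
  cat(sprintf(
    "<methylation_cohort> %d samples x %d probes [%s domain], %.1f%% missing\n",
    nrow(x$beta), ncol(x$beta), x$domain_tag, 100 * miss
  ))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.methylation_cohort <- function(x) dim(x$beta)

#' Sample and probe accessors
#' @param cohort A [methylation_cohort()].
#' @return Character vector of ids.
#' @export
sample_ids <- function(cohort) rownames(cohort$beta)

#' @rdname sample_ids
#' @export
probe_ids <- function(cohort) colnames(cohort$beta)

subset_cohort <- function(cohort, samples = NULL, probes = NULL) {
  beta <- cohort$beta
  if (!is.null(samples)) beta <- beta[samples, , drop = FALSE]
  if (!is.null(probes)) beta <- beta[, probes, drop = FALSE]
  labels <- cohort$labels
  if (!is.null(labels)) labels <- labels[rownames(beta)]
  methylation_cohort(beta, labels = labels, domain_tag = cohort$domain_tag)
}

#' Read and write methylation matrices as delimited text
#'
#' Beta and detection-P matrices use the same layout: one row per sample, a
#' leading `sample_id` column, then one numeric column per probe. Labels are
#' a two-column TSV (`sample_id`, `class`).
#'
#' @param path File path.
#' @param labels_path Optional label TSV to attach.
#' @param domain_tag Domain tag for the resulting cohort.
#' @return [read_beta_matrix()] returns a [methylation_cohort()];
#'   [read_matrix_tsv()] a plain numeric matrix; writers return `path`
#'   invisibly.
#' @export
read_beta_matrix <- function(path, labels_path = NULL, domain_tag = "target") {
  beta <- read_matrix_tsv(path)
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- readr::read_tsv(labels_path, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
    labels <- stats::setNames(lab[[2]], lab[[1]])
  }
  methylation_cohort(beta, labels = labels, domain_tag = domain_tag)
}

#' @rdname read_beta_matrix
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname read_beta_matrix
#' @param m Numeric matrix with dimnames.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "sample_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname read_beta_matrix
#' @param cohort A [methylation_cohort()].
#' @param beta_path,labels_out Output paths (labels written only when present).
#' @export
write_cohort <- function(cohort, beta_path, labels_out = NULL) {
  write_matrix_tsv(cohort$beta, beta_path)
  if (!is.null(labels_out) && !is.null(cohort$labels)) {
    readr::write_tsv(
      tibble::tibble(sample_id = names(cohort$labels), class = unname(cohort$labels)),
      labels_out
    )
  }
  invisible(beta_path)
}
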