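#' Probe manifests
#'
#' A probe manifest maps each CpG probe to its genomic coordinate (1-based
#' position of the interrogated CpG), strand, and gene annotation
#' (semicolon-joined symbols, possibly empty).
#'
#' @param path TSV with columns `probe_id`, `chrom`, `pos`, `strand`,
#'   `genes`.
#' @return A tibble.
#' @export
read_probe_manifest <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols(
    probe_id = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_integer(), strand = readr::col_character(),
    genes = readr::col_character()
  ))
  m$genes[is.na(m$genes)] <- ""
  validate_manifest(m)
  m
}

#' @rdname read_probe_manifest
#' @param manifest Manifest tibble to write.
#' @export
write_probe_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  readr::write_tsv(manifest, path)
  invisible(path)
}

validate_manifest <- function(m) {
  need <- c("probe_id", "chrom", "pos", "strand", "genes")
  if (!all(need %in% names(m))) {
    abort_mt(paste("Manifest needs columns:", paste(need, collapse = ", ")),
             "manifest_error")
  }
  if (anyDuplicated(m$probe_id)) abort_mt("Duplicate probe ids in manifest.", "manifest_error")
  if (any(m$pos < 1)) abort_mt("Manifest positions must be >= 1.", "manifest_error")
  if (!all(m$strand %in% c("+", "-"))) {
    abort_mt("Manifest strand must be '+' or '-'.", "manifest_error")
  }
  invisible(m)
}

#' Extract the flanking-sequence window of a probe
#'
#' Returns the 50-bp (for the default `flank = 25`) genomic window around a
#' probe's CpG site: the 1-based inclusive interval `[pos - flank,
#' pos + flank - 1]`, so the site sits at 0-based offset `flank` and the
#' window covers `flank` bases upstream and `flank` downstream (the site
#' occupying the first downstream position). Minus-strand probes are
#' reverse-complemented. Windows are never padded: one that runs off the
#' chromosome is an error.
#'
#' @param genome A named [Biostrings::DNAStringSet] (names = chromosomes),
#'   e.g. from [Biostrings::readDNAStringSet()].
#' @param chrom,pos,strand Probe coordinates.
#' @param flank Bases on each side (window length is `2 * flank`).
#' @return Uppercase DNA string of length `2 * flank`.
#' @export
extract_probe_window <- function(genome, chrom, pos, strand = "+", flank = 25) {
  if (!chrom %in% names(genome)) {
    abort_mt(sprintf("Chromosome '%s' not found in the reference.", chrom),
             "lookup_error")
  }
  start <- pos - flank
  end <- pos + flank - 1
  chrom_len <- length(genome[[chrom]])
  if (start < 1 || end > chrom_len) {
    abort_mt(sprintf(
      "Window [%d, %d] for position %d runs off chromosome '%s' (length %d).",
      start, end, pos, chrom, chrom_len
    ), "boundary_error")
  }
  seq <- Biostrings::subseq(genome[[chrom]], start = start, end = end)
  if (identical(strand, "-")) seq <- Biostrings::reverseComplement(seq)
  toupper(as.character(seq))
}

#' @rdname extract_probe_window
#' @param manifest Probe manifest tibble; windows are extracted for every
#'   row.
#' @return For [extract_probe_windows()]: named character vector of windows
#'   (a probe sequence set), all the same length.
#' @export
extract_probe_windows <- function(genome, manifest, flank = 25) {
  validate_manifest(manifest)
  out <- vapply(seq_len(nrow(manifest)), function(i) {
    extract_probe_window(genome, manifest$chrom[i], manifest$pos[i],
                         manifest$strand[i], flank)
  }, character(1))
  stats::setNames(out, manifest$probe_id)
}

#' Sequence-embedding providers
#'
#' An embedding provider turns a fixed-length DNA string into a numeric
#' vector of declared dimension `d0`. Two providers ship with the package:
#'
#' * [mock_hash_embedder()] — a deterministic stand-in used throughout the
#'   test suite: it seeds a pseudo-random generator from a stable hash of
#'   the sequence (plus the provider seed) and draws `d0` standard-normal
#'   values, so identical sequences map to identical vectors across
#'   processes and machines, while single-base changes decorrelate the
#'   vector completely.
#' * [precomputed_embedder()] — wraps a probes-x-d0 matrix of externally
#'   computed embeddings (e.g. from a pretrained nucleotide or protein
#'   language model), keyed by sequence.
#'
#' Adapters for real pretrained language models can implement the same
#' two-generic interface ([embedding_dim()] and `embed_one()`).
#'
#' @param d0 Output embedding dimension (>= 1).
#' @param seed Provider seed mixed into the per-sequence hash.
#' @return An embedding provider object.
#' @export
mock_hash_embedder <- function(d0 = 640, seed = 1) {
  stopifnot(d0 >= 1)
  structure(list(d0 = as.integer(d0), seed = as.integer(seed)),
            class = c("mock_hash_embedder", "sequence_embedder"))
}

#' @rdname mock_hash_embedder
#' @param embeddings Numeric matrix with one row per sequence, rownames =
#'   sequences (or probe ids resolved by the caller).
#' @export
precomputed_embedder <- function(embeddings) {
  stopifnot(is.matrix(embeddings), !is.null(rownames(embeddings)))
  structure(list(d0 = ncol(embeddings), table = embeddings),
            class = c("precomputed_embedder", "sequence_embedder"))
}

#' @rdname mock_hash_embedder
#' @param embedder An embedding provider.
#' @export
embedding_dim <- function(embedder) UseMethod("embedding_dim")

#' @export
embedding_dim.sequence_embedder <- function(embedder) embedder$d0

embed_one <- function(embedder, seq) UseMethod("embed_one")

#' @export
embed_one.mock_hash_embedder <- function(embedder, seq) {
  h <- derive_seed(embedder$seed, seq)
  with_seed(h, stats::rnorm(embedder$d0))
}

#' @export
embed_one.precomputed_embedder <- function(embedder, seq) {
  if (!seq %in% rownames(embedder$table)) {
    abort_mt("Sequence not present in the precomputed embedding table.",
             "lookup_error")
  }
  embedder$table[seq, ]
}

#' Embed a probe sequence set
#'
#' Applies an embedding provider to every probe window, preserving probe
#' order: row `i` of the result embeds sequence `i`. Sequences must be over
#' the alphabet `{A, C, G, T, N}` and share one length.
#'
#' @param embedder An embedding provider (see [mock_hash_embedder()]).
#' @param seqs Named character vector of equal-length DNA strings (names =
#'   probe ids), as from [extract_probe_windows()].
#' @return `raw_embedding` object: probes x d0 matrix (`$matrix`) plus the
#'   embedder name.
#' @export
embed_sequences <- function(embedder, seqs) {
  stopifnot(inherits(embedder, "sequence_embedder"))
  if (is.null(names(seqs))) abort_mt("Sequences must be named by probe id.", "validation_error")
  if (length(unique(nchar(seqs))) > 1) {
    abort_mt("All probe sequences must share one length.", "validation_error")
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort_mt(sprintf("Sequences contain characters outside {A,C,G,T,N}: %s",
                     paste(utils::head(names(seqs)[bad], 3), collapse = ", ")),
             "validation_error")
  }
  mat <- t(vapply(seqs, function(s) embed_one(embedder, s),
                  numeric(embedding_dim(embedder))))
  rownames(mat) <- names(seqs)
  structure(
    list(matrix = mat, embedder_name = class(embedder)[1]),
    class = "raw_embedding"
  )
}

#' Reduce raw embeddings to a probe-embedding matrix (PPE)
#'
#' Centers the probes-x-d0 raw embedding matrix and projects it onto its
#' top-`d` principal components (probes are the observations; no scaling).
#' The result is the pretrained probe-embedding (PPE) matrix fused with
#' beta values downstream. Component signs are fixed (largest-magnitude
#' loading positive) so the reduction is deterministic across platforms.
#'
#' @param raw A `raw_embedding` from [embed_sequences()].
#' @param d Reduced dimension (must not exceed the matrix rank).
#' @return `probe_embedding` object: `$matrix` (probes x d scores),
#'   `$rotation` (orthonormal components), `$explained_variance`
#'   (per-dimension fraction, nonincreasing), `$center`.
#' @export
reduce_embeddings <- function(raw, d = 128) {
  stopifnot(inherits(raw, "raw_embedding"))
  x <- raw$matrix
  if (d > min(dim(x))) {
    abort_mt("d must not exceed min(probes, d0).", "rank_error")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  tol <- max(dim(x)) * .Machine$double.eps * pc$sdev[1]
  rank <- sum(pc$sdev > tol)
  if (d > rank) {
    abort_mt(sprintf("d = %d exceeds the matrix rank (%d).", d, rank), "rank_error")
  }
  rot <- pc$rotation[, seq_len(d), drop = FALSE]
  scores <- pc$x[, seq_len(d), drop = FALSE]
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(d)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      matrix = scores, rotation = rot,
      explained_variance = ev[seq_len(d)], center = pc$center,
      embedder_name = raw$embedder_name, d0 = ncol(x), d = d
    ),
    class = "probe_embedding"
  )
}

#' @export
print.probe_embedding <- function(x, ...) {
  cat(sprintf("<probe_embedding> %d probes x %d dims (from d0 = %d, %s); top-5 EV: %s\n",
              nrow(x$matrix), x$d, x$d0, x$embedder_name,
              paste(sprintf("%.3f", utils::head(x$explained_variance, 5)), collapse = " ")))
  invisible(x)
}

#' Fuse beta values with probe embeddings
#'
#' Scales each probe's embedding row by the sample's beta value at that
#' probe: `fused[i, j] = beta[i] * PPE[i, j]`. A fully unmethylated probe
#' (beta 0) therefore contributes a zero row, a fully methylated one the
#' raw embedding row. The operation is linear in beta. `fuse_cohort()`
#' stacks all samples into a `samples x probes x d` array, the model input
#' tensor.
#'
#' @param beta_row Numeric vector of beta values (no missing entries; call
#'   [zero_fill()] first), aligned to PPE rows.
#' @param ppe A `probe_embedding` from [reduce_embeddings()], or a plain
#'   probes x d matrix.
#' @return `fuse()`: probes x d matrix. `fuse_cohort()`: 3-d array.
#' @export
fuse <- function(beta_row, ppe) {
  m <- if (inherits(ppe, "probe_embedding")) ppe$matrix else ppe
  if (length(beta_row) != nrow(m)) {
    abort_mt("beta_row length must equal the PPE row count.", "alignment_error")
  }
  if (anyNA(beta_row)) {
    abort_mt("beta_row contains missing values; zero_fill the cohort first.",
             "alignment_error")
  }
  m * beta_row
}

#' @rdname fuse
#' @param cohort A missing-free [methylation_cohort()] whose probes match
#'   the PPE rows (order enforced by probe id when names are available).
#' @export
fuse_cohort <- function(cohort, ppe) {
  stopifnot(inherits(cohort, "methylation_cohort"))
  m <- if (inherits(ppe, "probe_embedding")) ppe$matrix else ppe
  beta <- cohort$beta
  if (anyNA(beta)) {
    abort_mt("Cohort contains missing values; zero_fill before fusing.",
             "alignment_error")
  }
  if (!is.null(rownames(m))) {
    if (!all(colnames(beta) %in% rownames(m))) {
      abort_mt("PPE does not cover all cohort probes.", "alignment_error")
    }
    m <- m[colnames(beta), , drop = FALSE]
  } else if (nrow(m) != ncol(beta)) {
    abort_mt("PPE row count must equal the cohort probe count.", "alignment_error")
  }
  n <- nrow(beta)
  out <- array(0, dim = c(n, nrow(m), ncol(m)),
               dimnames = list(rownames(beta), colnames(beta), NULL))
  for (i in seq_len(n)) out[i, , ] <- m * beta[i, ]
  out
}
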