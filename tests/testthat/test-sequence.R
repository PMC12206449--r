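make_marker_genome <- function(len = 100, marker_pos = 50) {
  chars <- rep("A", len)
  chars[marker_pos] <- "G"
  g <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(g) <- "chr1"
  g
}

test_that("window extraction follows the [pos-flank, pos+flank-1] convention", {
  g <- Biostrings::DNAStringSet(strrep("A", 100))
  names(g) <- "chr1"
  expect_identical(extract_probe_window(g, "chr1", 50), strrep("A", 50))
  # a marker base at pos lands at 0-based offset 25 of the window
  gm <- make_marker_genome()
  win <- extract_probe_window(gm, "chr1", 50)
  expect_equal(nchar(win), 50)
  expect_identical(substr(win, 26, 26), "G")
  expect_identical(gsub("G", "A", win), strrep("A", 50))
  # minus strand returns the reverse complement (marker becomes C, mirrored)
  win_m <- extract_probe_window(gm, "chr1", 50, strand = "-")
  expect_identical(substr(win_m, 25, 25), "C")
  expect_identical(win_m, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(win))))
  # boundary and lookup errors
  expect_error(extract_probe_window(g, "chr1", 10), class = "boundary_error")
  expect_error(extract_probe_window(g, "chr1", 80), class = "boundary_error")
  expect_error(extract_probe_window(g, "chr2", 50), class = "lookup_error")
})

test_that("window content is invariant to padding beyond the window", {
  gm <- make_marker_genome(100, 50)
  gm_padded <- Biostrings::DNAStringSet(paste0(as.character(gm[[1]]),
                                               strrep("T", 40)))
  names(gm_padded) <- "chr1"
  expect_identical(extract_probe_window(gm, "chr1", 50),
                   extract_probe_window(gm_padded, "chr1", 50))
})

test_that("mock hash embedder is deterministic, seed-sensitive and base-sensitive", {
  emb <- mock_hash_embedder(d0 = 16, seed = 3)
  s <- strrep("ACGT", 13) # any 52-mer; length is the caller's business
  v1 <- methtransfer:::embed_one(emb, s)
  v2 <- methtransfer:::embed_one(emb, s)
  expect_identical(v1, v2)
  expect_length(v1, 16)
  expect_true(all(is.finite(v1)))
  # different provider seed, different vector
  expect_false(identical(v1, methtransfer:::embed_one(mock_hash_embedder(16, 4), s)))
  # single-base changes decorrelate: 100 random 50-mers vs 1-base mutants
  set.seed(21)
  bases <- c("A", "C", "G", "T")
  for (i in 1:100) {
    seq <- paste(sample(bases, 50, TRUE), collapse = "")
    pos <- sample(50, 1)
    old <- substr(seq, pos, pos)
    mut <- seq
    substr(mut, pos, pos) <- sample(setdiff(bases, old), 1)
    expect_false(identical(methtransfer:::embed_one(emb, seq),
                           methtransfer:::embed_one(emb, mut)))
  }
  # d0 = 1 gives scalar embeddings
  expect_length(methtransfer:::embed_one(mock_hash_embedder(1, 1), s), 1)
})

test_that("embed_sequences preserves order, validates alphabet, equivaries", {
  emb <- mock_hash_embedder(d0 = 8, seed = 1)
  seqs <- c(pA = strrep("A", 10), pB = strrep("C", 10), pC = strrep("A", 10))
  raw <- embed_sequences(emb, seqs)
  expect_equal(dim(raw$matrix), c(3, 8))
  expect_identical(raw$matrix["pA", ], raw$matrix["pC", ]) # identical seqs
  perm <- seqs[c(2, 3, 1)]
  raw_p <- embed_sequences(emb, perm)
  expect_identical(raw_p$matrix[names(perm), ], raw$matrix[names(perm), ])
  expect_error(embed_sequences(emb, c(p1 = "ACGTX")), class = "validation_error")
  expect_error(embed_sequences(emb, c(p1 = "ACGT", p2 = "ACGTAC")),
               class = "validation_error")
})

test_that("PCA reduction matches an independent eigendecomposition oracle", {
  set.seed(17)
  for (rep in 1:3) {
    x <- matrix(rnorm(50 * 10), 50, 10)
    rownames(x) <- sprintf("p%02d", 1:50)
    raw <- structure(list(matrix = x, embedder_name = "test"),
                     class = "raw_embedding")
    ppe <- reduce_embeddings(raw, d = 3)
    # oracle: eigendecomposition of the covariance matrix
    xc <- scale(x, center = TRUE, scale = FALSE)
    ev <- eigen(crossprod(xc) / (nrow(x) - 1), symmetric = TRUE)
    recon_ppe <- ppe$matrix %*% t(ppe$rotation)
    recon_oracle <- (xc %*% ev$vectors[, 1:3]) %*% t(ev$vectors[, 1:3])
    expect_equal(norm(xc - recon_ppe, "F"), norm(xc - recon_oracle, "F"),
                 tolerance = 1e-10)
    expect_equal(ppe$explained_variance,
                 (ev$values / sum(ev$values))[1:3], tolerance = 1e-10)
    # components are orthonormal and scores uncorrelated
    expect_equal(crossprod(ppe$rotation), diag(3), tolerance = 1e-8,
                 ignore_attr = TRUE)
    cr <- crossprod(ppe$matrix)
    expect_lt(max(abs(cr[upper.tri(cr)])), 1e-8)
    expect_true(all(diff(ppe$explained_variance) <= 1e-12))
  }
  # full-dimension projection preserves pairwise distances
  set.seed(18)
  x <- matrix(rnorm(20 * 6), 20, 6)
  rownames(x) <- sprintf("p%02d", 1:20)
  raw <- structure(list(matrix = x, embedder_name = "t"), class = "raw_embedding")
  ppe <- reduce_embeddings(raw, d = 6)
  expect_equal(as.matrix(dist(ppe$matrix)), as.matrix(dist(x)), tolerance = 1e-9)
  # rank-1 matrix explains everything in one dimension
  r1 <- structure(list(matrix = outer(1:20, rep(1, 6)) + 0, embedder_name = "t"),
                  class = "raw_embedding")
  rownames(r1$matrix) <- sprintf("p%02d", 1:20)
  red1 <- reduce_embeddings(r1, d = 1)
  expect_equal(red1$explained_variance, 1)
  expect_error(reduce_embeddings(r1, d = 2), class = "rank_error")
})

test_that("fusion is elementwise, linear in beta, and guards alignment", {
  set.seed(5)
  ppe <- matrix(rnorm(12), 4, 3)
  beta <- c(0, 1, 0.5, 0.25)
  fused <- fuse(beta, ppe)
  expect_equal(fused[1, ], c(0, 0, 0))
  expect_equal(fused[2, ], ppe[2, ])
  expect_equal(fused[3, ], 0.5 * ppe[3, ])
  expect_equal(fuse(2 * beta / 2, ppe), fused)
  expect_equal(fuse(0.4 * beta, ppe), 0.4 * fused) # linearity
  expect_error(fuse(c(0.1, 0.2), ppe), class = "alignment_error")
  expect_error(fuse(c(0.1, NA, 0.3, 0.4), ppe), class = "alignment_error")
  # cohort-level fusion aligns by probe id
  b <- matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2,
              dimnames = list(c("s1", "s2"), c("pg2", "pg1")))
  rownames(ppe) <- c("pg1", "pg2", "pg3", "pg4")
  arr <- fuse_cohort(methylation_cohort(b), ppe)
  expect_equal(dim(arr), c(2, 2, 3))
  expect_equal(arr["s1", "pg2", ], 0.2 * ppe["pg2", ])
  expect_equal(arr["s2", "pg1", ], 0.8 * ppe["pg1", ])
})

test_that("manifest round-trips through TSV including multi-gene annotations", {
  m <- tibble::tibble(
    probe_id = c("cg1", "cg2"), chrom = c("chr1", "chr1"),
    pos = c(100L, 200L), strand = c("+", "-"),
    genes = c("GENE1;GENE2", "")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_probe_manifest(m, path)
  m2 <- read_probe_manifest(path)
  expect_equal(m2, m)
  expect_error(methtransfer:::validate_manifest(
    dplyr::mutate(m, strand = c("+", "?"))), class = "manifest_error")
})
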