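# Shared fixtures, built in code at test time.

# Crafted 8-sample x 12-probe cohort with hand-computed missingness.
# Classes: A = s1..s4, B = s5..s8. The detection-P matrix produces exactly
# these post-QC NA entries:
#   s1: p01 p03 p04 p05 p06   s2: p03   s5: p01 p04
# plus a boundary entry (s3, p02) at P = 0.01 exactly, which is retained.
# Hand-derived cascade (defaults 0.01 / 0.30 / 0.20 / 0.30):
#   probe filter: p03 missing 2/4 = 0.5 in class A -> dropped (11 survive)
#   sample filter: s1 missing 4/11 = 0.364 -> dropped; s5 2/11 = 0.182 kept
#   harmonize vs ranking [p12,p10,p99,p08,p06,p04,p02]: p99 absent -> out
#   zero-fill: the one remaining NA (s5, p04) -> 0
make_crafted_cohort <- function() {
  samples <- paste0("s", 1:8)
  probes <- sprintf("p%02d", 1:12)
  beta <- outer(1:8, 1:12, function(i, j) (i + j) / 25)
  dimnames(beta) <- list(samples, probes)
  labels <- stats::setNames(rep(c("A", "B"), each = 4), samples)
  pvals <- matrix(0.001, 8, 12, dimnames = dimnames(beta))
  pvals["s1", c("p01", "p03", "p04", "p05", "p06")] <- c(0.05, 0.02, 0.02, 0.02, 0.02)
  pvals["s2", "p03"] <- 0.02
  pvals["s5", c("p01", "p04")] <- c(0.011, 0.02)
  pvals["s3", "p02"] <- 0.01 # boundary: exactly at threshold, retained
  selection <- structure(
    list(ranking = tibble::tibble(
      probe_id = c("p12", "p10", "p99", "p08", "p06", "p04", "p02"),
      importance = 7:1, rank = 1:7
    ), seed = 1L, method = "crafted", k = 7L),
    class = "feature_selection"
  )
  list(
    cohort = methylation_cohort(beta, labels = labels),
    pvals = pvals,
    selection = selection,
    expected_probes_after_filter = setdiff(probes, "p03"),
    expected_samples_after_filter = paste0("s", 2:8),
    expected_final_probes = c("p12", "p10", "p08", "p06", "p04", "p02")
  )
}

# Small fused dataset for network tests: synthetic cohort -> mock embedder
# -> PCA -> fused tensor. Cached per test file via the options below.
make_fused_toy <- function(spec = synthetic_cohort_spec(seed = 11),
                           d0 = 32, d = 8, embed_seed = 5) {
  gen <- generate_cohort(spec)
  cohort <- zero_fill(gen$cohort)
  toy <- generate_toy_genome_and_manifest(spec$n_probes, chrom_length = 20000,
                                          seed = 3)
  wins <- extract_probe_windows(toy$genome, toy$manifest)
  ppe <- reduce_embeddings(embed_sequences(mock_hash_embedder(d0, embed_seed), wins),
                           d = d)
  list(x = fuse_cohort(cohort, ppe), labels = unname(cohort$labels),
       cohort = cohort, planted = gen$planted, ppe = ppe,
       manifest = toy$manifest, genome = toy$genome)
}

# Tiny network config for fast unit tests.
tiny_cfg <- function(probes = 32, d = 8, num_classes = 2, ...) {
  args <- utils::modifyList(
    list(block_counts = c(1, 1, 1, 1), input_shape = c(probes, d),
         num_classes = num_classes, stem_channels = 4, base_width = 2,
         expansion = 2, learning_rate = 1e-3, batch_size = 8,
         max_epochs = 5, patience = 3, seed = 7),
    list(...)
  )
  do.call(network_config, args)
}

random_tensor <- function(n, probes = 32, d = 8, seed = 1) {
  set.seed(seed)
  array(stats::runif(n * probes * d), c(n, probes, d))
}
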