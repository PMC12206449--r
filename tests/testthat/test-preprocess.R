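test_that("beta computation follows M / (M + U + offset)", {
  expect_equal(compute_beta(0, 0, 100), 0)
  expect_equal(compute_beta(500, 500, 0), 0.5)
  expect_equal(compute_beta(300, 100, 100), 0.6)
  # vectorized
  expect_equal(compute_beta(c(10, 20), c(90, 80), 0), c(0.1, 0.2))
  expect_error(compute_beta(0, 0, 0), class = "degenerate_input_error")
  expect_error(compute_beta(-1, 5), class = "degenerate_input_error")
})

test_that("detection QC masks strictly above the threshold", {
  fx <- make_crafted_cohort()
  qc <- apply_detection_qc(fx$cohort, fx$pvals)
  expect_true(is.na(qc$beta["s1", "p01"]))    # P = 0.05 -> masked
  expect_equal(qc$beta["s3", "p02"], fx$cohort$beta["s3", "p02"]) # P = 0.01 kept
  expect_equal(sum(is.na(qc$beta)), 8)
  # all-pass matrix leaves the cohort unchanged
  clean <- matrix(0, 8, 12, dimnames = dimnames(fx$cohort$beta))
  expect_identical(apply_detection_qc(fx$cohort, clean)$beta, fx$cohort$beta)
  # misaligned matrix is rejected
  expect_error(apply_detection_qc(fx$cohort, clean[, 1:6]), class = "alignment_error")
})

test_that("probe filter drops on strict per-class missingness", {
  fx <- make_crafted_cohort()
  qc <- apply_detection_qc(fx$cohort, fx$pvals)
  filt <- filter_probes_by_class_missingness(qc)
  expect_identical(probe_ids(filt), fx$expected_probes_after_filter)
  # boundary: exactly at the threshold is retained (1/4 missing = 0.25)
  boundary <- filter_probes_by_class_missingness(qc, max_frac = 0.25)
  expect_true(all(c("p01", "p04") %in% probe_ids(boundary)))
  # just below the boundary the same probes are dropped
  stricter <- filter_probes_by_class_missingness(qc, max_frac = 0.24)
  expect_false(any(c("p01", "p04") %in% probe_ids(stricter)))
  # labels are required
  unlab <- methylation_cohort(qc$beta)
  expect_error(filter_probes_by_class_missingness(unlab), class = "precondition_error")
  # fully observed matrix is untouched
  full <- zero_fill(qc)
  expect_identical(probe_ids(filter_probes_by_class_missingness(full)), probe_ids(full))
})

test_that("sample filter drops on strict overall missingness", {
  fx <- make_crafted_cohort()
  qc <- apply_detection_qc(fx$cohort, fx$pvals)
  filt <- filter_samples_by_missingness(filter_probes_by_class_missingness(qc))
  expect_identical(sample_ids(filt), fx$expected_samples_after_filter)
  # boundary: a sample at exactly the threshold is retained
  beta <- matrix(0.5, 2, 5, dimnames = list(c("a", "b"), paste0("p", 1:5)))
  beta["a", 1] <- NA # 1/5 = 0.2 exactly
  co <- methylation_cohort(beta)
  expect_identical(sample_ids(filter_samples_by_missingness(co, 0.20)), c("a", "b"))
  expect_identical(sample_ids(filter_samples_by_missingness(co, 0.19)), "b")
  expect_warning(filter_samples_by_missingness(co, -1), "All samples")
})

test_that("zero-fill replaces all missing values and is idempotent", {
  fx <- make_crafted_cohort()
  qc <- apply_detection_qc(fx$cohort, fx$pvals)
  zf <- zero_fill(qc)
  expect_false(anyNA(zf$beta))
  expect_equal(zf$beta["s1", "p01"], 0)
  kept <- !is.na(qc$beta)
  expect_identical(zf$beta[kept], qc$beta[kept])
  expect_identical(zero_fill(zf)$beta, zf$beta)
})

test_that("harmonization intersects ranking with target missingness", {
  # worked rule: selected {p1,p2,p3}; target has p1 at 0.1 missing, p2 at
  # 0.5 missing, p3 absent -> only p1 survives
  sel <- structure(list(ranking = tibble::tibble(
    probe_id = c("p1", "p2", "p3"), importance = 3:1, rank = 1:3
  ), seed = 1L, method = "crafted", k = 3L), class = "feature_selection")
  beta <- matrix(0.5, 10, 2, dimnames = list(sprintf("t%02d", 1:10), c("p1", "p2")))
  beta[1, "p1"] <- NA
  beta[1:5, "p2"] <- NA
  tgt <- methylation_cohort(beta)
  expect_identical(harmonize_feature_set(sel, tgt), "p1")
  # fully observed target keeps the whole selection, in ranking order
  full <- methylation_cohort(matrix(0.5, 4, 3, dimnames = list(
    paste0("t", 1:4), c("p3", "p1", "p2"))))
  expect_identical(harmonize_feature_set(sel, full), c("p1", "p2", "p3"))
  # max_missing = 0 keeps only fully observed probes
  beta2 <- beta
  beta2[1, "p1"] <- 0.5 # p1 now fully observed, p2 still 50% missing
  expect_identical(harmonize_feature_set(sel, methylation_cohort(beta2), 0), "p1")
  # empty intersection errors
  na_beta <- matrix(NA_real_, 2, 1, dimnames = list(c("a", "b"), "p2"))
  expect_error(harmonize_feature_set(sel, methylation_cohort(na_beta)),
               class = "harmonization_error")
})

test_that("random-forest probe selection is deterministic and finds signal", {
  # one probe separates two classes perfectly among 20 noise probes
  set.seed(99)
  n <- 30
  beta <- matrix(runif(n * 21, 0.3, 0.7), n, 21,
                 dimnames = list(sprintf("s%02d", 1:n), sprintf("p%02d", 1:21)))
  labels <- rep(c("A", "B"), length.out = n)
  beta[, "p11"] <- ifelse(labels == "A", runif(n, 0, 0.2), runif(n, 0.8, 1))[1:n]
  co <- methylation_cohort(beta, labels = labels)
  sel1 <- select_top_variable_probes(co, k = 1, seed = 42, num_trees = 200)
  expect_identical(sel1$ranking$probe_id, "p11")
  sel_all <- select_top_variable_probes(co, k = 21, seed = 42, num_trees = 200)
  sel_all2 <- select_top_variable_probes(co, k = 21, seed = 42, num_trees = 200)
  expect_identical(sel_all$ranking, sel_all2$ranking)  # same seed, same ranking
  expect_equal(nrow(sel_all$ranking), 21)
  expect_true(all(diff(sel_all$ranking$importance) <= 0))
  expect_warning(select_top_variable_probes(co, k = 50, seed = 1, num_trees = 50),
                 "exceeds probe count")
  # sample order does not change the ranking for a fixed seed
  perm <- sample(n)
  co_perm <- methylation_cohort(beta[perm, ], labels = labels[perm])
  sel_perm <- select_top_variable_probes(co_perm, k = 21, seed = 42, num_trees = 200)
  expect_identical(sel_perm$ranking$probe_id, sel_all$ranking$probe_id)
})

test_that("full cascade records stage counts in the run manifest", {
  fx <- make_crafted_cohort()
  res <- preprocess_cohort(fx$cohort, pvals = fx$pvals, selected = fx$selection)
  expect_identical(probe_ids(res$cohort), fx$expected_final_probes)
  expect_identical(sample_ids(res$cohort), fx$expected_samples_after_filter)
  st <- res$manifest$stages
  expect_equal(st$input$probes, 12)
  expect_equal(st$after_probe_filter$probes, 11)
  expect_equal(st$after_sample_filter$samples, 7)
  expect_equal(st$after_harmonization$probes, 6)
  expect_false(anyNA(res$cohort$beta))
})
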