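test_that("forward pass honours the shape contract and seeded init", {
  cfg <- tiny_cfg(probes = 64, d = 16, num_classes = 3)
  m1 <- build_network(cfg)
  x <- random_tensor(5, 64, 16)
  ps <- predict_scores(m1, x)
  expect_equal(dim(ps$softmax), c(5, 3))
  expect_equal(unname(rowSums(ps$softmax)), rep(1, 5), tolerance = 1e-9)
  expect_equal(ncol(ps$penultimate), m1$feature_dim)
  # identical seeds give bit-identical initial parameters
  m2 <- build_network(cfg)
  expect_identical(stage_checksums(m1), stage_checksums(m2))
  expect_identical(m1$modules[["s3.u1.conv2"]]$params$W,
                   m2$modules[["s3.u1.conv2"]]$params$W)
  m3 <- build_network(network_config(
    block_counts = c(1, 1, 1, 1), input_shape = c(64, 16), num_classes = 3,
    stem_channels = 4, base_width = 2, expansion = 2, seed = 8
  ))
  expect_false(identical(m1$modules[["stem.conv"]]$params$W,
                         m3$modules[["stem.conv"]]$params$W))
  # duplicated sample gives identical scores
  xd <- x[c(1, 1, 2), , , drop = FALSE]
  psd <- predict_scores(m1, xd)
  expect_identical(psd$softmax[1, ], psd$softmax[2, ])
  # mismatched input shape is rejected
  expect_error(as_input_tensor_bad <- predict_scores(m1, array(0, c(2, 64, 16, 3))),
               class = "shape_error")
})

test_that("zeroing the residual branch makes identity-skip units the identity", {
  cfg <- tiny_cfg(probes = 32, d = 8, num_classes = 2)
  cfg$block_counts <- c(2, 1, 1, 1) # s1.u2 is an identity-skip unit
  model <- build_network(cfg)
  ns <- asNamespace("methtransfer")
  x <- random_tensor(3, 32, 8)
  dim(x) <- c(dim(x), 1)
  # capture the input of s1.u2 by running a truncated forward by hand:
  # zero its final-conv weights so the residual branch contributes nothing
  model$modules[["s1.u2.conv3"]]$params$W[] <- 0
  model$modules[["s1.u2.bn3"]]$params$beta[] <- 0
  fw <- ns$model_forward(model, x, train = FALSE)
  # compare against a network without that unit entirely
  cfg1 <- cfg
  cfg1$block_counts <- c(1, 1, 1, 1)
  model1 <- build_network(cfg1)
  for (nm in names(model1$modules)) {
    model1$modules[[nm]]$params <- model$modules[[nm]]$params
    model1$modules[[nm]]$state <- model$modules[[nm]]$state
  }
  fw1 <- ns$model_forward(model1, x, train = FALSE)
  expect_equal(fw$logits, fw1$logits, tolerance = 1e-12)
})

test_that("cross-entropy matches closed forms and the stated weighting", {
  expect_equal(cross_entropy(matrix(c(0, 0), 1), 1), log(2), tolerance = 1e-12)
  expect_equal(cross_entropy(matrix(c(1, 1, 1), 1), 2), log(3), tolerance = 1e-12)
  # true-class logit -> +inf drives the loss to 0
  expect_lt(cross_entropy(matrix(c(50, 0), 1), 1), 1e-20)
  expect_error(cross_entropy(matrix(c(0, 0), 1), 3), class = "loss_error")
  # weights for class sizes (90, 10) are in ratio 1:9
  w <- inverse_frequency_weights(rep(c("a", "b"), c(90, 10)))
  expect_equal(unname(w["b"] / w["a"]), 9)
  expect_equal(mean(w), 1)
  # weighted loss scales each sample's term by its class weight
  lg <- asNamespace("methtransfer")$ce_loss_grad(
    matrix(c(0, 0, 0, 0), 2, 2), c(1L, 2L), class_weights = c(1.5, 0.5)
  )
  expect_equal(lg$loss, mean(c(1.5, 0.5) * log(2)), tolerance = 1e-12)
})

test_that("initial loss on random inputs is near ln(C)", {
  for (C in c(2, 4)) {
    cfg <- tiny_cfg(probes = 32, d = 8, num_classes = C)
    model <- build_network(cfg)
    x <- random_tensor(16, 32, 8, seed = C)
    ps <- predict_scores(model, x)
    y <- rep_len(seq_len(C), 16)
    loss <- mean(-log(ps$softmax[cbind(1:16, y)]))
    expect_lt(abs(loss - log(C)) / log(C), 0.1)
  }
})

test_that("training is deterministic, learns separable data, respects patience", {
  fused <- make_fused_toy(synthetic_cohort_spec(
    n_classes = 2, samples_per_class = 10, n_probes = 32,
    n_informative_per_class = 8, effect_size = 0.45, missing_rate = 0,
    beta_concentration = 100, seed = 6
  ), d0 = 16, d = 4)
  cfg <- tiny_cfg(probes = 32, d = 4, num_classes = 2, max_epochs = 70,
                  patience = 70)
  m1 <- train_network(build_network(cfg, c("class1", "class2")),
                      fused$x, fused$labels, cfg)
  # linearly separable two-class fused data trains to low loss
  expect_lt(min(m1$training_log$train_loss), 0.1)
  # same seed twice: identical training log
  m2 <- train_network(build_network(cfg, c("class1", "class2")),
                      fused$x, fused$labels, cfg)
  expect_identical(m1$training_log, m2$training_log)
  # patience 0 stops after the first epoch with no improvement
  cfg0 <- tiny_cfg(probes = 32, d = 4, num_classes = 2, max_epochs = 50,
                   patience = 0, learning_rate = 10) # divergent on purpose
  m0 <- train_network(build_network(cfg0, c("class1", "class2")),
                      fused$x, fused$labels, cfg0)
  first_bad <- which(diff(c(Inf, m0$training_log$val_loss)) >= -1e-8)[1]
  expect_equal(nrow(m0$training_log), first_bad)
  # single-class data is rejected
  expect_error(train_network(build_network(cfg, c("class1", "class2")),
                             fused$x, rep("class1", 20), cfg),
               class = "training_error")
})

test_that("head permutation permutes scores identically", {
  cfg <- tiny_cfg(probes = 32, d = 8, num_classes = 3)
  m <- build_network(cfg, c("a", "b", "c"))
  x <- random_tensor(4, 32, 8)
  perm <- c(3, 1, 2)
  mp <- m
  mp$class_names <- m$class_names[perm]
  mp$modules[["head.fc"]]$params$W <- m$modules[["head.fc"]]$params$W[, perm]
  mp$modules[["head.fc"]]$params$b <- m$modules[["head.fc"]]$params$b[perm]
  ps <- predict_scores(m, x)
  psp <- predict_scores(mp, x)
  expect_equal(unname(psp$softmax), unname(ps$softmax[, perm]), tolerance = 1e-12)
  expect_identical(psp$predicted, ps$predicted)
})

test_that("fine-tuning freezes exactly the requested stages", {
  fused <- make_fused_toy(synthetic_cohort_spec(
    n_classes = 2, samples_per_class = 8, n_probes = 32,
    n_informative_per_class = 6, effect_size = 0.4, missing_rate = 0, seed = 4
  ), d0 = 16, d = 4)
  cfg <- tiny_cfg(probes = 32, d = 4, num_classes = 2, max_epochs = 3,
                  patience = 3)
  pre <- train_network(build_network(cfg, c("class1", "class2")),
                       fused$x, fused$labels, cfg)
  before <- stage_checksums(pre)
  run_ft <- function(fb) {
    cfg_ft <- cfg
    cfg_ft$freeze_blocks <- fb
    cfg_ft$seed <- 99
    stage_checksums(fine_tune(pre, fused$x, fused$labels, cfg_ft))
  }
  cs2 <- run_ft(2)
  expect_identical(cs2[c("stem", "stage1", "stage2")],
                   before[c("stem", "stage1", "stage2")])
  expect_false(cs2[["stage3"]] == before[["stage3"]])
  expect_false(cs2[["stage4"]] == before[["stage4"]])
  expect_false(cs2[["head"]] == before[["head"]])
  cs0 <- run_ft(0)
  expect_true(all(cs0 != before))
  cs4 <- run_ft(4)
  expect_identical(cs4[c("stem", "stage1", "stage2", "stage3", "stage4")],
                   before[c("stem", "stage1", "stage2", "stage3", "stage4")])
  expect_false(cs4[["head"]] == before[["head"]])
})
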