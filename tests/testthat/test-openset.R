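# Build a calibration object directly with hand-set parameters: the
# rescoring algebra is independent of how the calibration was fitted.
hand_calibration <- function(mavs, shapes, scales,
                             distance = "euclidean") {
  classes <- names(mavs)
  structure(
    list(mavs = mavs,
         weibull = stats::setNames(
           lapply(seq_along(classes),
                  function(i) list(shape = shapes[i], scale = scales[i])),
           classes),
         class_names = classes, tail_size = 5, distance = distance,
         activation = "softmax"),
    class = "openmax_calibration"
  )
}

test_that("rescoring conserves score mass for any confidence vector", {
  set.seed(42)
  for (i in 1:1000) {
    C <- sample(2:5, 1)
    s <- stats::runif(C)
    s <- s / sum(s)
    # random weibulls + random query position give arbitrary w in [0,1]
    mavs <- stats::setNames(lapply(1:C, function(j) stats::runif(C)),
                            paste0("k", 1:C))
    cal <- hand_calibration(mavs, shapes = stats::runif(C, 0.5, 5),
                            scales = stats::runif(C, 0.05, 2))
    av <- stats::runif(C)
    os <- openmax_rescore(cal, s, av)
    expect_true(all(os$scores >= 0))
    expect_true(os$unknown >= 0)
    expect_lt(abs(sum(os$scores) + os$unknown - 1), 1e-9)
    expect_true(all(os$confidence >= 0 & os$confidence <= 1))
  }
})

test_that("confidence limits give identity and all-unknown rescoring", {
  mavs <- list(a = c(1, 0), b = c(0, 1))
  # near-degenerate Weibull: CDF ~ 0 below the scale, ~1 above it
  cal <- hand_calibration(mavs, shapes = c(1000, 1000), scales = c(1, 1))
  s <- c(a = 0.7, b = 0.3)
  # query at a point with distance < scale to both MAVs: w = 1, identity
  at_mav <- openmax_rescore(cal, s, c(0.5, 0.5))
  expect_equal(unname(at_mav$scores), c(0.7, 0.3))
  expect_equal(at_mav$unknown, 0)
  # query far beyond both tails: w = 0, all mass to unknown
  far <- openmax_rescore(cal, s, c(50, 50))
  expect_equal(unname(far$scores), c(0, 0))
  expect_equal(far$unknown, 1)
})

test_that("a two-class hand computation matches exactly", {
  # spreadsheet-style: distances d = (0.5, 0.2); weibull shape 2, scale 1 /
  # shape 1, scale 0.5; w_j = exp(-(d/scale)^shape)
  cal <- hand_calibration(list(a = c(1, 0), b = c(0, 1)),
                          shapes = c(2, 1), scales = c(1, 0.5))
  av <- c(1, 0) + c(-0.5, 0) # distance 0.5 to a's MAV
  d_a <- sqrt(sum((av - c(1, 0))^2))
  d_b <- sqrt(sum((av - c(0, 1))^2))
  w_a <- exp(-(d_a / 1)^2)
  w_b <- exp(-(d_b / 0.5)^1)
  s <- c(a = 0.6, b = 0.4)
  os <- openmax_rescore(cal, s, av)
  expect_equal(unname(os$scores), c(0.6 * w_a, 0.4 * w_b), tolerance = 1e-12)
  expect_equal(os$unknown, 0.6 * (1 - w_a) + 0.4 * (1 - w_b), tolerance = 1e-12)
  # the worked three-class example: scores (.7,.2,.1), w (.5,1,1)
  os3 <- structure(list(
    scores = c(a = 0.35, b = 0.2, c = 0.1), unknown = 0.35,
    confidence = c(a = 0.5, b = 1, c = 1), distances = c(a = 1, b = 0, c = 0)
  ), class = "openmax_scores")
  expect_equal(classify_open(os3), "a") # tie with unknown -> known wins
})

test_that("increasing distance to every MAV never decreases the unknown score", {
  cal <- hand_calibration(list(a = c(1, 0), b = c(0, 1)),
                          shapes = c(2, 1.5), scales = c(0.8, 0.6))
  s <- c(a = 0.5, b = 0.5)
  dirs <- c(1, 1) / sqrt(2)
  unknowns <- vapply(seq(0, 3, by = 0.25), function(t) {
    openmax_rescore(cal, s, c(0.5, 0.5) + t * dirs)$unknown
  }, numeric(1))
  expect_true(all(diff(unknowns) >= -1e-12))
})

test_that("open-set decision rule prefers known classes on ties", {
  mk <- function(scores, unknown) {
    structure(list(scores = scores, unknown = unknown,
                   confidence = scores * 0 + 1, distances = scores * 0),
              class = "openmax_scores")
  }
  expect_equal(classify_open(mk(c(a = 0.35, b = 0.3), 0.35)), "a")
  expect_equal(classify_open(mk(c(a = 0.05, b = 0.05), 0.9)), "UNKNOWN")
  expect_equal(classify_open(mk(c(a = 0.4, b = 0.6), 0)), "b")
  expect_equal(classify_open(mk(c(a = 0.3, b = 0.3), 0.2)), "a") # known tie -> lowest index
})

test_that("weibull tail fitting recovers parameters and handles degeneracy", {
  set.seed(9)
  x <- stats::rweibull(4000, shape = 2.5, scale = 0.7)
  fit <- methtransfer:::weibull_tail_fit(x)
  expect_lt(abs(fit$shape - 2.5) / 2.5, 0.1)
  expect_lt(abs(fit$scale - 0.7) / 0.7, 0.05)
  # cross-check against fitdistrplus MLE on the same data
  fd <- fitdistrplus::fitdist(x, "weibull")
  expect_equal(fit$shape, unname(fd$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit$scale, unname(fd$estimate["scale"]), tolerance = 1e-3)
  # degenerate all-zero tail: floored scale, step-like CDF, w ~ 1 at 0
  dg <- methtransfer:::weibull_tail_fit(rep(0, 10))
  expect_gt(dg$shape, 0)
  expect_gte(dg$scale, 1e-8)
  expect_equal(stats::pweibull(0, dg$shape, dg$scale), 0)
})

test_that("fitting on a trained model builds sane per-class calibrations", {
  fused <- make_fused_toy(synthetic_cohort_spec(
    n_classes = 2, samples_per_class = 12, n_probes = 32,
    n_informative_per_class = 6, effect_size = 0.4, missing_rate = 0, seed = 2
  ), d0 = 16, d = 4)
  cfg <- tiny_cfg(probes = 32, d = 4, num_classes = 2, max_epochs = 30,
                  patience = 10)
  model <- build_network(cfg, sort(unique(fused$labels)))
  model <- train_network(model, fused$x, fused$labels, cfg)
  w <- capture_warnings(
    cal <- fit_openmax(model, fused$x, fused$labels, tail_size = 20)
  )
  expect_true(length(w) >= 1 && all(grepl("tail shrunk", w)))
  cal2 <- suppressWarnings(fit_openmax(model, fused$x, fused$labels, tail_size = 20))
  expect_identical(tidy(cal), tidy(cal2)) # deterministic
  expect_named(cal$mavs, c("class1", "class2"))
  # each MAV is closer to its own class's activations than to the other's
  ps <- predict_scores(model, fused$x)
  for (cl in c("class1", "class2")) {
    own <- colMeans(ps$softmax[fused$labels == cl, , drop = FALSE])
    other <- colMeans(ps$softmax[fused$labels != cl, , drop = FALSE])
    d_own <- sqrt(sum((own - cal$mavs[[cl]])^2))
    d_other <- sqrt(sum((other - cal$mavs[[cl]])^2))
    expect_lt(d_own, d_other)
  }
  # JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_openmax_calibration(cal, path)
  cal_rt <- read_openmax_calibration(path)
  expect_equal(tidy(cal_rt), tidy(cal))
  expect_equal(cal_rt$mavs, cal$mavs, ignore_attr = TRUE, tolerance = 1e-12)
})
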