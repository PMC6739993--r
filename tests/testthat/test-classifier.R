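# Segment classifiers: architecture checksum, softmax contracts,
# gradient correctness, training behavior, mask aggregation.

test_that("default U-net reproduces the published parameter total", {
  m <- build_unet()
  expect_identical(count_parameters(m), 607112L)
})

test_that("config violating the layer inventory is rejected", {
  expect_error(unet_config(base_filters = c(32, 64)), "three")
  expect_error(unet_config(input_length = 50), "pooling")
})

test_that("all three networks emit a 2-class simplex on batched input", {
  set.seed(1)
  X <- matrix(rnorm(7 * 60), 7)
  for (m in list(build_unet(seed = 1), build_cnn(seed = 1),
                 build_rnn(seed = 1))) {
    p <- ucpwi:::model_forward(m, X)$probs
    expect_equal(dim(p), c(2L, 7L))
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(colSums(p), rep(1, 7), tolerance = 1e-6)
  }
})

test_that("same seed gives identical initial weights", {
  expect_identical(build_unet(seed = 3)$params, build_unet(seed = 3)$params)
  expect_false(identical(build_unet(seed = 3)$params,
                         build_unet(seed = 4)$params))
})

test_that("backpropagated gradients match finite differences", {
  check_arch <- function(model, n_coord = 5) {
    set.seed(42)
    X <- matrix(rnorm(3 * 60), 3)
    y <- c(0L, 1L, 1L)
    model$cfg$dropout_rate <- 0    # deterministic forward
    fw <- ucpwi:::model_forward(model, X, train = TRUE)
    g <- ucpwi:::model_backward(model, fw$cache,
                                ucpwi:::ce_grad(fw$probs, y))
    loss_of <- function(mm) {
      f <- ucpwi:::model_forward(mm, X, train = TRUE)
      ucpwi:::ce_loss(f$probs, y)
    }
    for (k in seq_len(n_coord)) {
      ln <- sample(names(model$params), 1)
      pn <- sample(names(model$params[[ln]]), 1)
      i <- sample(length(model$params[[ln]][[pn]]), 1)
      eps <- 1e-6
      mp <- model; mp$params[[ln]][[pn]][i] <- mp$params[[ln]][[pn]][i] + eps
      mm <- model; mm$params[[ln]][[pn]][i] <- mm$params[[ln]][[pn]][i] - eps
      fd <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      an <- g[[ln]][[pn]][i]
      expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-8), 1e-4)
    }
  }
  check_arch(build_unet(seed = 2))
  check_arch(build_cnn(seed = 2))
  check_arch(build_rnn(seed = 2))
})

test_that("a single batch can be overfit", {
  co <- fixture_small_corpus()
  idx <- which(co$split == "train")[1:100]
  sub <- structure(list(segments = co$segments[idx, ], labels = co$labels[idx],
                        provenance = co$provenance[idx, ], split = NULL),
                   class = "segment_dataset")
  m0 <- build_unet(seed = 5)
  m0$cfg$dropout_rate <- 0     # capacity check: no regularization
  m <- train_classifier(m0, sub,
                        train_config("fast", epochs = 200, seed = 5))
  acc <- mean(ucpwi:::predict_classes(m, ucpwi:::normalize_segments(
    sub$segments), normalized = TRUE) == sub$labels)
  expect_gte(acc, 0.99)
})

test_that("training on permuted labels stays near chance", {
  co <- fixture_small_corpus()
  idx <- which(co$split == "train")[1:2000]
  set.seed(9)
  sub <- structure(list(segments = co$segments[idx, ],
                        labels = sample(co$labels[idx]),
                        provenance = co$provenance[idx, ], split = NULL),
                   class = "segment_dataset")
  m <- train_classifier(build_unet(seed = 6), sub,
                        train_config("fast", epochs = 2, seed = 6))
  te <- which(co$split == "test")
  acc <- mean(ucpwi:::predict_classes(m, co$segments[te, ]) ==
                co$labels[te])
  # no information: between chance and the majority-class rate
  expect_lt(abs(acc - 0.5), 0.1)
})

test_that("degenerate one-class datasets are rejected", {
  co <- fixture_small_corpus()
  idx <- which(co$labels == 1L)[1:50]
  sub <- structure(list(segments = co$segments[idx, ], labels = co$labels[idx],
                        provenance = co$provenance[idx, ], split = NULL),
                   class = "segment_dataset")
  expect_error(train_classifier(build_unet(seed = 1), sub), "degenerate")
})

test_that("mask aggregation averages overlapping windows correctly", {
  geo <- probe_geometry(n_elements = 2)
  ph <- phantom(tissue = data.frame(x = 0, z = 0.005, reflectivity = 1),
                noise_sigma = 0.02)
  fr <- simulate_plane_wave_rx(ph, geo, drive_pulse(), n_samples = 180,
                               seed = 3)
  m <- build_unet(seed = 1)
  expect_error(predict_mask(m, fr), "train")
  m$trained <- TRUE   # constant-output untrained weights, but callable
  mk <- predict_mask(m, fr, length = 60, step = 5)
  expect_equal(dim(mk$mask), dim(fr$rf))
  expect_true(all(mk$prob >= 0 & mk$prob <= 1))
  # single covering window: constant probability over its span
  mk1 <- predict_mask(m, fr, length = 60, step = 180)
  expect_equal(length(unique(round(mk1$prob[1:60, 1], 12))), 1L)
  # hand-check the mean-over-windows rule at one sample
  ds <- segment_rf(fr, 60, 5)
  pr <- predict_proba(m, ds$segments)
  el1 <- which(ds$provenance$element == 1)
  covering <- el1[ds$provenance$start[el1] <= 70 &
                    ds$provenance$start[el1] + 59 >= 70]
  expect_equal(mk$prob[70, 1], mean(pr[covering]), tolerance = 1e-12)
})
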