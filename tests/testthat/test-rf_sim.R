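# Plane-wave channel-RF simulator: delays, labels, segmentation,
# corpus construction.

test_that("empty phantom with zero noise yields a silent frame", {
  suppressMessages({
    fr <- simulate_plane_wave_rx(phantom(), probe_geometry(),
                                 drive_pulse(), n_samples = 500)
  })
  expect_true(all(fr$rf == 0))
  expect_true(all(fr$truth_mask == 0L))
})

test_that("echo onset matches the analytic two-way travel time", {
  geo <- probe_geometry()
  ph <- phantom(tissue = data.frame(x = 0, z = 0.02, reflectivity = 1))
  fr <- simulate_plane_wave_rx(ph, geo, drive_pulse())
  for (i in c(1L, 64L, 128L)) {
    tau <- (0.02 + sqrt((0 - geo$element_x[i])^2 + 0.02^2)) / geo$c0
    expected <- tau * geo$fs + 1
    line <- fr$rf[, i]
    onset <- which(abs(line) > 1e-3 * max(abs(line)))[1]
    # first nonzero of the gated sine lands within two samples of the
    # analytic onset (the pulse's own first sample is zero)
    expect_lt(abs(onset - expected), 2.5)
    # truth mask covers the echo
    expect_true(all(fr$truth_mask[onset:(onset + 5), i] == 1L))
  }
})

test_that("bubble echoes carry 8 MHz energy that tissue echoes lack", {
  geo <- probe_geometry()
  pt <- phantom(tissue = data.frame(x = 0, z = 0.02, reflectivity = 1))
  pb <- phantom(bubbles = data.frame(x = 0, z = 0.02, amplitude = 1))
  ft <- simulate_plane_wave_rx(pt, geo, drive_pulse())
  fb <- simulate_plane_wave_rx(pb, geo, drive_pulse())
  at8 <- function(x) {
    x <- x / sqrt(sum(x^2))          # equal energy
    ps <- power_spectrum(x, geo$fs, pad_factor = 4)
    max(ps$power[abs(ps$freq - 8e6) < 0.5e6])
  }
  expect_gt(at8(fb$rf[, 64]) / at8(ft$rf[, 64]), 3)
})

test_that("segment counts follow the sliding-window arithmetic", {
  geo <- probe_geometry(n_elements = 4)
  ph <- phantom(tissue = data.frame(x = 0, z = 0.02, reflectivity = 1),
                noise_sigma = 0.01)
  fr <- simulate_plane_wave_rx(ph, geo, drive_pulse(), seed = 1)
  ds5 <- segment_rf(fr, length = 60, step = 5)
  expect_equal(nrow(ds5$segments) / 4, 409)
  ds60 <- segment_rf(fr, length = 60, step = 60)
  expect_equal(nrow(ds60$segments) / 4, 35)
  expect_error(segment_rf(fr, length = 3000), "exceeds")
})

test_that("segment labels follow the majority rule with bubble ties", {
  geo <- probe_geometry(n_elements = 2, fs = 25e6)
  ph <- phantom(tissue = data.frame(x = 0, z = 0.02, reflectivity = 1))
  fr <- simulate_plane_wave_rx(ph, geo, drive_pulse(), n_samples = 800)
  # hand-build masks to exercise the rule
  fr$truth_mask[, 1] <- 1L                      # constant tissue line
  fr$truth_mask[, 2] <- 2L                      # constant bubble line
  ds <- segment_rf(fr, 60, 60)
  expect_true(all(ds$labels[ds$provenance$element == 1] == 0L))
  expect_true(all(ds$labels[ds$provenance$element == 2] == 1L))
  # exact tie goes to bubble
  fr$truth_mask[, 1] <- rep(c(1L, 2L), 400)
  ds <- segment_rf(fr, 60, 60)
  expect_true(all(ds$labels[ds$provenance$element == 1] == 1L))
  # pure background is unlabeled
  fr$truth_mask[] <- 0L
  ds <- segment_rf(fr, 60, 60)
  expect_true(all(is.na(ds$labels)))
  expect_true(all(ds$bg_frac == 1))
})

test_that("training corpus honors balance, split and determinism", {
  co <- fixture_small_corpus()
  expect_equal(nrow(co$segments), 4000)
  expect_equal(mean(co$labels), 0.45, tolerance = 1e-3)
  expect_equal(mean(co$split == "train"), 0.8, tolerance = 1e-3)
  # balance holds within each side of the split
  expect_equal(mean(co$labels[co$split == "train"]), 0.45,
               tolerance = 2e-3)
  expect_equal(mean(co$labels[co$split == "test"]), 0.45,
               tolerance = 2e-3)
  # frame-level disjointness: no frame contributes to both sides
  expect_length(intersect(unique(co$provenance$frame[co$split == "train"]),
                          unique(co$provenance$frame[co$split == "test"])),
                0)
  co2 <- make_training_corpus(n_segments = 4000, n_frames = 6, seed = 301)
  expect_identical(co, co2)
})

test_that("fixed seed reproduces a frame bitwise", {
  geo <- probe_geometry(n_elements = 8)
  ph <- phantom(tissue = data.frame(x = 0, z = 0.01, reflectivity = 1),
                noise_sigma = 0.05)
  f1 <- simulate_plane_wave_rx(ph, geo, drive_pulse(), n_samples = 600,
                               seed = 42)
  f2 <- simulate_plane_wave_rx(ph, geo, drive_pulse(), n_samples = 600,
                               seed = 42)
  expect_identical(f1$rf, f2$rf)
})
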