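# Shelled-bubble dynamics, scattered pressure, and the bubble wavelet.

test_that("constructors validate their physical fields", {
  expect_error(bubble_params(R0 = -1), "strictly positive")
  expect_error(drive_pulse(fs = 10e6), "fs")
  expect_warning(drive_pulse(peak_pressure = 5e5), "mechanical index")
  expect_silent(drive_pulse())
})

test_that("zero drive leaves the bubble at its equilibrium radius", {
  tr <- solve_bubble_dynamics(bubble_params(),
                              drive_pulse(peak_pressure = 0))
  expect_lt(max(abs(tr$R - 1.7e-6)) / 1.7e-6, 1e-9)
  expect_lt(max(abs(tr$Rdot)), 1e-9 * 1.7e-6 * 2.5e7)
})

test_that("driven trajectory carries second-harmonic energy", {
  tr <- solve_bubble_dynamics(bubble_params(), drive_pulse(), fs_out = 1e8)
  x <- tr$R - 1.7e-6
  ps <- power_spectrum(x, 1e8, pad_factor = 16)
  p8 <- max(ps$power[abs(ps$freq - 8e6) < 0.5e6])
  floor_ <- stats::median(ps$power[ps$freq > 14e6 & ps$freq < 20e6])
  expect_gt(p8, 10 * floor_)
})

test_that("solution is stable under tolerance refinement", {
  tr1 <- solve_bubble_dynamics(bubble_params(), drive_pulse())
  tr2 <- solve_bubble_dynamics(bubble_params(), drive_pulse(),
                               rtol = 5e-9, atol = 5e-13)
  expect_lt(abs(max(abs(tr1$R)) - max(abs(tr2$R))) / max(abs(tr1$R)), 1e-3)
})

test_that("scattered pressure is zero at equilibrium and decays as 1/d", {
  tr0 <- solve_bubble_dynamics(bubble_params(),
                               drive_pulse(peak_pressure = 0))
  p0 <- scattered_pressure(tr0, 0.02)
  expect_lt(max(abs(p0)), 1e-4)
  tr <- solve_bubble_dynamics(bubble_params(), drive_pulse())
  p1 <- scattered_pressure(tr, 0.025)
  p2 <- scattered_pressure(tr, 0.05)
  expect_equal(p1, 2 * p2, tolerance = 1e-12)
  expect_error(scattered_pressure(tr, -1), "positive")
})

test_that("harmonic content grows monotonically with drive amplitude", {
  # long drive so the harmonic line resolves above the gate's leakage
  ratio_at <- function(amp) {
    d8 <- drive_pulse(n_cycles = 8, peak_pressure = amp)
    tr <- solve_bubble_dynamics(bubble_params(), d8,
                                t_span = c(0, d8$duration), fs_out = 1e8)
    pp <- scattered_pressure(tr, 0.01)
    i <- tr$t >= 2 / d8$f0
    sp <- power_spectrum(pp[i] - mean(pp[i]), 1e8, pad_factor = 16)
    max(sp$power[abs(sp$freq - 8e6) < 0.5e6]) /
      max(sp$power[abs(sp$freq - 4e6) < 0.5e6])
  }
  r <- vapply(c(5e3, 1e4, 2e4, 4e4), ratio_at, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("mother wavelet is admissible and centered where measured", {
  w <- fixture_wavelet()
  dt <- 1 / w$fs
  expect_lt(abs(sum(w$psi) * dt), 1e-12)
  expect_equal(sum(w$psi^2) * dt, 1, tolerance = 1e-10)
  expect_equal(w$f_center, spectral_peak(w$psi, w$fs, pad_factor = 16),
               tolerance = 1e-6)
  expect_error(build_mother_wavelet(drive = drive_pulse(peak_pressure = 0)),
               "degenerate")
})

test_that("optimal scale places the dilated wavelet at the second harmonic", {
  w <- fixture_wavelet()
  w8 <- w; w8$f_center <- 8e6
  expect_equal(optimal_scale(w8, 4e6), 1.0)
  w4 <- w; w4$f_center <- 4e6
  expect_equal(optimal_scale(w4, 4e6), 0.5)
  s <- optimal_scale(w, 4e6)
  for (fs in c(25e6, 1e8)) {
    psi_s <- ucpwi:::dilate_wavelet(w, s, fs = fs)
    pk <- spectral_peak(psi_s, fs, pad_factor = 16)
    expect_lt(abs(pk - 8e6) / 8e6, 0.05)
  }
})
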