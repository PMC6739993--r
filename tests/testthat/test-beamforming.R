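# Beamforming: subarray covariance, diagonal loading, eigensubspaces,
# DAS/MV/ESBMV closed forms, eigenvalue threshold detection.

test_that("subarray covariance averages the right number of terms", {
  set.seed(1)
  x <- rnorm(128)
  cv <- subarray_covariance(x, 32)
  expect_equal(cv$n_subarrays, 97L)
  expect_equal(dim(cv$R), c(32L, 32L))
  expect_equal(cv$R, t(cv$R))
  # brute-force oracle
  Rb <- matrix(0, 32, 32)
  for (p in 1:97) Rb <- Rb + tcrossprod(x[p:(p + 31)])
  expect_equal(cv$R, Rb / 97, tolerance = 1e-12)
  # all-ones vector gives the rank-1 all-ones matrix
  cv1 <- subarray_covariance(rep(1, 16), 4)
  expect_equal(cv1$R, matrix(1, 4, 4))
  # L = M: single-term outer product
  cvM <- subarray_covariance(x[1:8], 8)
  expect_equal(cvM$R, tcrossprod(x[1:8]), tolerance = 1e-12)
  expect_error(subarray_covariance(x[1:8], 9), "L")
})

test_that("diagonal loading shifts the spectrum by exactly epsilon", {
  cv <- subarray_covariance(rep(1, 4), 2)   # R = all-ones 2x2
  ld <- diagonal_load(cv, delta = 1 / 2)
  expect_equal(ld$epsilon, 1)
  expect_equal(ld$R, matrix(c(2, 1, 1, 2), 2))
  set.seed(2)
  cv <- subarray_covariance(rnorm(24), 8)
  lam <- eigen(cv$R, symmetric = TRUE)$values
  ld <- diagonal_load(cv, 1 / 80)
  lam_l <- eigen(ld$R, symmetric = TRUE)$values
  expect_equal(lam_l, lam + ld$epsilon, tolerance = 1e-10)
  # zero-trace input passes through unchanged
  z <- diagonal_load(subarray_covariance(numeric(8), 4), 1 / 8)
  expect_equal(z$epsilon, 0)
  expect_error(diagonal_load(cv, 0.5), "delta")
})

test_that("eigendecomposition reconstructs and splits the matrix", {
  d2 <- eigendecompose(diag(c(4, 1)), alpha = 0.4)
  expect_equal(d2$eigvals, c(4, 1))
  expect_equal(d2$N, 1L)
  expect_equal(abs(d2$U_S), matrix(c(1, 0), 2, 1))
  dI <- eigendecompose(diag(5), alpha = 0.4)
  expect_equal(dI$N, 5L)
  for (L in c(5L, 32L)) {
    set.seed(L)
    R <- crossprod(matrix(rnorm(L * L), L))
    e <- eigendecompose(R, alpha = 0.4)
    expect_true(all(diff(e$eigvals) <= 1e-12))
    recon <- e$eigvecs %*% diag(e$eigvals) %*% t(e$eigvecs)
    expect_lt(max(abs(recon - R)), 1e-10 * max(abs(R)))
    Us <- e$U_S; Up <- e$eigvecs[, -seq_len(e$N), drop = FALSE]
    split_sum <- Us %*% diag(e$eigvals[seq_len(e$N)], e$N) %*% t(Us) +
      Up %*% diag(e$eigvals[-seq_len(e$N)], L - e$N) %*% t(Up)
    expect_lt(max(abs(split_sum - R)), 1e-10 * max(abs(R)))
  }
  expect_error(eigendecompose(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("MV weight satisfies the distortionless constraint", {
  for (L in c(4L, 16L, 32L)) {
    set.seed(L)
    cv <- diagonal_load(subarray_covariance(rnorm(3 * L), L))
    w <- ucpwi:::mv_weight(cv)
    expect_lt(abs(sum(w) - 1), 1e-10)   # w^H d = 1 with d = ones
  }
})

test_that("hand-solved 2x2 MV case matches the solver", {
  cov <- structure(list(R = matrix(c(2, 1, 1, 2), 2), L = 2L),
                   class = "covariance_estimate")
  w <- ucpwi:::mv_weight(cov, c(1, 1))
  # R^-1 d = (1/3, 1/3); d^H R^-1 d = 2/3; w = (1/2, 1/2)
  expect_equal(w, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(as.numeric(solve(cov$R, c(1, 1)) /
                            drop(crossprod(c(1, 1), solve(cov$R, c(1, 1))))),
               w, tolerance = 1e-12)
})

test_that("identity covariance collapses MV and ESBMV onto DAS", {
  set.seed(6)
  x <- rnorm(12); L <- 4L
  cov <- structure(list(R = diag(L), L = L), class = "covariance_estimate")
  cov <- eigendecompose(cov, alpha = 0.4)
  expect_equal(cov$N, L)                       # full signal subspace
  sub_das <- mean(vapply(1:(12 - L + 1),
                         function(p) mean(x[p:(p + L - 1)]), numeric(1)))
  expect_equal(mv(x, cov), sub_das, tolerance = 1e-12)
  expect_equal(esbmv(x, cov), mv(x, cov), tolerance = 1e-12)
})

test_that("full-space projection leaves the MV output unchanged", {
  set.seed(7)
  x <- rnorm(24); L <- 8L
  cov <- diagonal_load(subarray_covariance(x, L))
  cov <- eigendecompose(cov, alpha = 1e-12)    # everything is signal
  expect_equal(cov$N, L)
  expect_equal(esbmv(x, cov), mv(x, cov), tolerance = 1e-12)
})

test_that("delay law reduces to 2z/c for the element above the pixel", {
  geo <- probe_geometry()
  i <- 40
  x_i <- geo$element_x[i]
  z <- 0.02
  tau <- (z + sqrt((x_i - x_i)^2 + z^2)) / geo$c0
  expect_equal(tau, 2 * z / geo$c0)
})

test_that("delayed samples align coherently on a point scatterer", {
  geo <- probe_geometry()
  ph <- phantom(tissue = data.frame(x = 0.002, z = 0.02, reflectivity = 1))
  fr <- simulate_plane_wave_rx(ph, geo, drive_pulse())
  # at the scatterer, all elements read the same pulse phase: the
  # coherence factor |sum x| / sum |x| of the gathered vector peaks
  zs <- seq(0.0190, 0.0210, by = 0.5 * geo$c0 / geo$fs / 2)
  Xd <- delay_and_gather(fr, 0.002, zs)
  i_best <- which.max(abs(colSums(Xd)))
  cf <- abs(sum(Xd[, i_best])) / sum(abs(Xd[, i_best]))
  expect_gt(cf, 0.7)
  # the coherent depth sits at the scatterer depth, within the pulse's
  # own peak offset (the gated sine peaks ~1.5 samples into the gate)
  expect_lt(abs(zs[i_best] - 0.02), 3 * geo$c0 / geo$fs / 2)
  # silent region gathers (near) nothing
  expect_lt(max(abs(delay_and_gather(fr, 0.01, 0.05))), 1e-12)
})

test_that("threshold flags pixels against the per-line maximum", {
  lam <- cbind(c(10, 1, 1), c(0, 0, 0), c(2, 2, 2))
  det <- threshold_detect(lam, c_frac = 0.15)
  expect_equal(det[, 1], c(1L, 0L, 0L))       # 1.5 threshold
  expect_equal(det[, 2], c(0L, 0L, 0L))       # silent line: none
  expect_equal(det[, 3], c(1L, 1L, 1L))       # uniform line: all
  expect_error(threshold_detect(lam, c_frac = 1.5), "c_frac")
})

test_that("adaptive beamformers sharpen a point target", {
  geo <- probe_geometry()
  ph <- phantom(tissue = data.frame(x = 0, z = 0.02, reflectivity = 1),
                noise_sigma = 1e-3)
  fr <- simulate_plane_wave_rx(ph, geo, drive_pulse(), seed = 9)
  bf <- beamform_frame(fr, z_range = c(0.018, 0.022))
  i0 <- which.min(abs(bf$z - 0.02))
  zone <- (i0 - 3):(i0 + 3)
  prof <- function(m) apply(abs(bf$pixels[[m]][zone, ]), 2, max)
  fwhm <- function(p) sum(p > max(p) / 2)
  expect_lte(fwhm(prof("mv")), fwhm(prof("das")))
  # sidelobe level: worst response outside the mainlobe neighbourhood
  side <- function(p) max(p[abs(seq_along(p) - which.max(p)) > 5]) / max(p)
  expect_lte(side(prof("esbmv")), side(prof("mv")) + 1e-12)
})
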