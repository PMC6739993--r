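# Plane-wave receive beamforming: delay alignment, spatially-averaged
# subarray covariance with diagonal loading, eigendecomposition into
# signal/noise subspaces, and the DAS / minimum-variance (Capon) /
# eigenspace-based MV beamformers, plus the per-pixel maximum-eigenvalue
# map and threshold used to detect microbubble areas.

#' Delayed element samples for one image pixel
#'
#' For a 0-degree plane-wave transmit, element `i` observes a pixel at
#' lateral position `x` and depth `z` at `t = z/c0 + sqrt((x - x_i)^2 +
#' z^2)/c0`.  Samples are read off each element line by linear
#' interpolation; times outside the recording window contribute zeros.
#'
#' @param data a `channel_data` frame.
#' @param x_pix lateral pixel position, m.
#' @param z_pix pixel depth, m (scalar or vector).
#' @return for scalar `z_pix`, a length-M vector; for a vector, an
#'   M x length(z_pix) matrix.
#' @export
delay_and_gather <- function(data, x_pix, z_pix) {
  stopifnot(inherits(data, "channel_data"))
  g <- data$geometry
  n <- nrow(data$rf)
  out <- matrix(0, g$n_elements, length(z_pix))
  for (i in seq_len(g$n_elements)) {
    tau <- (z_pix + sqrt((x_pix - g$element_x[i])^2 + z_pix^2)) / g$c0
    s <- tau * g$fs + 1         # fractional 1-based sample
    j <- floor(s); fr <- s - j
    ok <- j >= 1 & j < n
    v <- numeric(length(z_pix))
    v[ok] <- (1 - fr[ok]) * data$rf[j[ok], i] +
      fr[ok] * data$rf[j[ok] + 1L, i]
    out[i, ] <- v
  }
  if (length(z_pix) == 1L) out[, 1] else out
}

#' Spatially averaged subarray covariance
#'
#' Mean of the outer products of the `M - L + 1` sliding length-`L`
#' subarrays of the delayed element vector; the spatial averaging
#' decorrelates coherent echoes so the adaptive weights are stable.
#'
#' @param x_d delayed element vector (length M).
#' @param L subarray length, `1 <= L <= M`.
#' @return an object of class `covariance_estimate` with the `L x L`
#'   matrix `R`.
#' @export
subarray_covariance <- function(x_d, L) {
  M <- length(x_d)
  L <- as.integer(L)
  if (L < 1L || L > M) stop("subarray length L must satisfy 1 <= L <= M")
  P <- M - L + 1L
  idx <- outer(seq_len(L), 0:(P - 1L), "+")
  X <- matrix(x_d[idx], L, P)
  structure(list(R = tcrossprod(X) / P, L = L, M = M, n_subarrays = P,
                 subarrays = X),
            class = "covariance_estimate")
}

#' Diagonal loading
#'
#' Adds `epsilon = delta * trace(R)` to the diagonal, making the matrix
#' strictly positive definite whenever the signal has any energy.
#'
#' @param cov a [subarray_covariance()] result (or plain matrix).
#' @param delta loading fraction, `0 < delta <= 1/L`.
#' @return the input with `R` replaced by the loaded matrix and
#'   `epsilon` recorded.
#' @export
diagonal_load <- function(cov, delta = NULL) {
  R <- if (inherits(cov, "covariance_estimate")) cov$R else cov
  L <- nrow(R)
  if (is.null(delta)) delta <- 1 / (10 * L)
  if (delta <= 0 || delta > 1 / L)
    stop("delta must lie in (0, 1/L]")
  eps <- delta * sum(diag(R))
  Rt <- R + diag(eps, L)
  if (inherits(cov, "covariance_estimate")) {
    cov$R <- Rt; cov$epsilon <- eps; cov$delta <- delta
    cov
  } else Rt
}

#' Eigendecomposition into signal and noise subspaces
#'
#' Eigenvalues are sorted descending; the signal subspace collects the
#' eigenvectors whose eigenvalues reach `alpha` times the largest.
#'
#' @param cov a [diagonal_load()]ed `covariance_estimate` (or matrix).
#' @param alpha signal-subspace threshold fraction of `lambda_1`.
#' @return the input augmented with `eigvals`, `eigvecs`, `N` (signal
#'   dimension) and `U_S`.
#' @export
eigendecompose <- function(cov, alpha = 0.4) {
  R <- if (inherits(cov, "covariance_estimate")) cov$R else cov
  if (max(abs(R - t(R))) > 1e-8 * max(abs(R), 1e-300))
    stop("covariance matrix must be symmetric")
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  N <- max(1L, sum(e$values >= alpha * e$values[1]))
  out <- if (inherits(cov, "covariance_estimate")) cov else
    structure(list(R = R, L = nrow(R)), class = "covariance_estimate")
  out$eigvals <- e$values
  out$eigvecs <- e$vectors
  out$N <- N
  out$U_S <- e$vectors[, seq_len(N), drop = FALSE]
  out$alpha <- alpha
  out
}

#' Beamformer point outputs
#'
#' `das()` is the plain average of the delayed samples.  `mv()` solves
#' the minimum-variance (Capon) weight `w = R^-1 d / (d^H R^-1 d)` on
#' the loaded subarray covariance and averages `w^H x` over the sliding
#' subarrays; `esbmv()` first projects the MV weight onto the signal
#' subspace `U_S U_S^H w`.
#'
#' @param x_d delayed element vector (length M).
#' @param cov a loaded (and for `esbmv`, eigendecomposed)
#'   `covariance_estimate` computed from `x_d`.
#' @param d steering vector (all-ones for pre-delayed data).
#' @param alpha signal-subspace fraction (used if `cov` lacks
#'   subspaces).
#' @return scalar beamformer output.
#' @export
das <- function(x_d) mean(x_d)

#' @rdname das
#' @export
mv <- function(x_d, cov, d = rep(1, cov$L)) {
  w <- mv_weight(cov, d)
  sub <- subarrays_of(x_d, cov$L)
  mean(crossprod(w, sub))
}

#' @rdname das
#' @export
esbmv <- function(x_d, cov, d = rep(1, cov$L), alpha = 0.4) {
  if (is.null(cov$U_S)) cov <- eigendecompose(cov, alpha)
  w <- cov$U_S %*% crossprod(cov$U_S, mv_weight(cov, d))
  sub <- subarrays_of(x_d, cov$L)
  mean(crossprod(w, sub))
}

subarrays_of <- function(x_d, L) {
  M <- length(x_d)
  P <- M - L + 1L
  idx <- outer(seq_len(L), 0:(P - 1L), "+")
  matrix(x_d[idx], L, P)
}

# MV weight with unity-gain constraint; singular systems fall back to
# uniform (DAS) weights with a warning.
mv_weight <- function(cov, d = rep(1, cov$L)) {
  Ri_d <- tryCatch(solve(cov$R, d), error = function(e) NULL)
  if (is.null(Ri_d) || !all(is.finite(Ri_d)) ||
      abs(sum(d * Ri_d)) < 1e-300) {
    warning("singular covariance: falling back to uniform weights")
    return(d / sum(d * d))
  }
  Ri_d / drop(crossprod(d, Ri_d))
}

#' Beamform a channel-data frame
#'
#' Forms one scan line per element position.  Per pixel: delay-gather
#' the element vector, average subarray covariances, diagonally load,
#' eigendecompose, and evaluate the requested beamformers plus the
#' maximum eigenvalue.
#'
#' @param data a `channel_data` frame.
#' @param methods subset of `c("das", "mv", "esbmv")`.
#' @param L subarray length.
#' @param alpha signal-subspace fraction of the largest eigenvalue.
#' @param delta diagonal-loading fraction (default `1/(10 L)`).
#' @param z_range depth window `c(z0, z1)` in m (default: full frame).
#' @param decimation beamform every k-th depth sample.
#' @return an object of class `beamformed_image`: per-method `pixels`
#'   matrices (depth x lines), `lambda_max`, grid vectors `z`, `x`.
#' @export
beamform_frame <- function(data, methods = c("das", "mv", "esbmv"),
                           L = 32L, alpha = 0.4, delta = NULL,
                           z_range = NULL, decimation = 1L) {
  stopifnot(inherits(data, "channel_data"))
  methods <- match.arg(methods, several.ok = TRUE)
  g <- data$geometry
  L <- as.integer(L)
  if (is.null(delta)) delta <- 1 / (10 * L)
  n <- nrow(data$rf)
  dt_z <- g$c0 / g$fs / 2               # depth per sample (two-way)
  z_all <- (seq_len(n) - 1) * dt_z
  if (is.null(z_range)) z_range <- range(z_all)
  zi <- which(z_all >= z_range[1] & z_all <= z_range[2])
  zi <- zi[seq.int(1L, length(zi), by = decimation)]
  z <- z_all[zi]
  x <- g$element_x
  nl <- length(x); nz <- length(z)
  px <- lapply(methods, function(m) matrix(0, nz, nl))
  names(px) <- methods
  lam <- matrix(0, nz, nl)
  want_adaptive <- any(methods %in% c("mv", "esbmv"))
  d <- rep(1, L)
  for (li in seq_len(nl)) {
    Xd <- delay_and_gather(data, x[li], z)    # M x nz
    if ("das" %in% methods) px$das[, li] <- colMeans(Xd)
    for (k in seq_len(nz)) {
      x_d <- Xd[, k]
      cov <- subarray_covariance(x_d, L)
      if (sum(diag(cov$R)) <= 0) next       # silent pixel
      cov <- diagonal_load(cov, delta)
      cov <- eigendecompose(cov, alpha)
      lam[k, li] <- cov$eigvals[1]
      if (want_adaptive) {
        w_mv <- mv_weight(cov, d)
        sub <- cov$subarrays
        if ("mv" %in% methods)
          px$mv[k, li] <- mean(crossprod(w_mv, sub))
        if ("esbmv" %in% methods) {
          w_e <- cov$U_S %*% crossprod(cov$U_S, w_mv)
          px$esbmv[k, li] <- mean(crossprod(w_e, sub))
        }
      }
    }
  }
  structure(list(pixels = px, lambda_max = lam, z = z, x = x,
                 methods = methods, L = L, alpha = alpha, delta = delta),
            class = "beamformed_image")
}

#' Maximum-eigenvalue map of a frame
#'
#' @inheritParams beamform_frame
#' @return matrix (depth x lines) of the largest subarray-covariance
#'   eigenvalue per pixel.
#' @export
max_eigenvalue_map <- function(data, L = 32L, delta = NULL,
                               z_range = NULL, decimation = 1L) {
  bf <- beamform_frame(data, methods = "das", L = L, delta = delta,
                       z_range = z_range, decimation = decimation)
  bf$lambda_max
}

#' Threshold the maximum-eigenvalue map into a bubble detection mask
#'
#' A pixel is flagged as microbubble when its maximum eigenvalue
#' reaches `c_frac` times the largest maximum eigenvalue on its own
#' scan line.  All-zero lines yield no detections.
#'
#' @param lambda_max matrix (depth x lines).
#' @param c_frac threshold fraction of the per-line maximum.
#' @return integer 0/1 matrix of the same shape.
#' @export
threshold_detect <- function(lambda_max, c_frac = 0.15) {
  stopifnot(is.matrix(lambda_max), c_frac > 0, c_frac < 1)
  det <- matrix(0L, nrow(lambda_max), ncol(lambda_max))
  for (li in seq_len(ncol(lambda_max))) {
    mx <- max(lambda_max[, li])
    if (mx > 0) det[, li] <- (lambda_max[, li] >= c_frac * mx) + 0L
  }
  det
}

#' Envelope detection and log compression of a beamformed image
#'
#' Analytic-signal magnitude along each scan line, normalized to the
#' image maximum and displayed over `[-dynamic_range, 0]` dB.
#' Detection removes signal: the envelope outside `detect_mask` is
#' zero, which the dB display clips to the `-dynamic_range` floor.
#'
#' @param pixels beamformed matrix (depth x lines).
#' @param dynamic_range display range in dB.
#' @param detect_mask optional 0/1 matrix zeroing undetected pixels.
#' @return list with `envelope` (linear) and `display` (dB).
#' @export
compress_image <- function(pixels, dynamic_range = 60, detect_mask = NULL) {
  env <- apply(pixels, 2, envelope_line)
  if (!is.matrix(env)) env <- matrix(env, nrow(pixels), ncol(pixels))
  if (!is.null(detect_mask)) env[detect_mask == 0L] <- 0
  mx <- max(env)
  if (mx == 0)
    return(list(envelope = env,
                display = matrix(-dynamic_range, nrow(env), ncol(env))))
  disp <- 20 * log10(pmax(env / mx, 1e-300))
  disp[disp < -dynamic_range] <- -dynamic_range
  list(envelope = env, display = disp)
}

#' @export
print.beamformed_image <- function(x, ...) {
  cat(sprintf("beamformed image: %d x %d pixels (%s), L = %d\n",
              nrow(x$lambda_max), ncol(x$lambda_max),
              paste(x$methods, collapse = "/"), x$L))
  invisible(x)
}
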