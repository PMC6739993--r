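# Bubble-approximated wavelet transform (BAWT): continuous wavelet
# transform of RF lines against the simulated bubble's scattered
# pressure, used as a matched filter that passes microbubble echoes and
# rejects linear tissue echoes.

#' BAWT configuration
#'
#' @param scale dimensionless dilation factor of the mother wavelet;
#'   choose [optimal_scale()] to center the passband on the second
#'   harmonic.
#' @param normalization `"L2"`: the dilated wavelet is renormalized to
#'   unit energy, the continuous 1/sqrt(scale) convention.
#' @return an object of class `bawt_config`.
#' @export
bawt_config <- function(scale, normalization = "L2") {
  stopifnot(is.numeric(scale), length(scale) == 1, scale > 0,
            identical(normalization, "L2"))
  structure(list(scale = scale, normalization = normalization),
            class = "bawt_config")
}

#' Continuous wavelet transform of one RF line at one scale
#'
#' "Same"-mode correlation of the line with the time-dilated,
#' energy-renormalized bubble wavelet (zero-padded edges).  The
#' coefficient at sample t measures the correlation of the RF around t
#' with the dilated bubble echo; an RF line equal to the dilated wavelet
#' itself yields a peak coefficient of 1.
#'
#' @param x numeric RF line.
#' @param wavelet a [build_mother_wavelet()] result.
#' @param scale dilation factor (> 0).
#' @param fs sampling rate of `x`, Hz; defaults to the wavelet's rate.
#' @return coefficient line, same length as `x`.
#' @export
cwt_line <- function(x, wavelet, scale, fs = wavelet$fs) {
  stopifnot(inherits(wavelet, "bubble_wavelet"), scale > 0)
  psi_s <- dilate_wavelet(wavelet, scale, fs = fs)
  correlate_same(x, psi_s)
}

# "same"-mode correlation via FFT; kernel center aligned at each sample
correlate_same <- function(x, k) {
  n <- length(x); m <- length(k)
  nf <- stats::nextn(n + m - 1L, 2)
  X <- stats::fft(c(x, rep(0, nf - n)))
  K <- stats::fft(c(k, rep(0, nf - m)))
  full <- Re(stats::fft(X * Conj(K), inverse = TRUE)) / nf
  # full[j] = sum_i x[i+j-1] k[i] for j = 1..; shift so the kernel
  # center sits on the output sample
  ctr <- (m + 1L) %/% 2L
  idx <- ((seq_len(n) - ctr) %% nf) + 1L
  full[idx]
}

#' Replace classified RF with wavelet coefficients
#'
#' On each element line, samples the classifier marked as microbubble
#' are replaced by the CWT coefficient at `cfg$scale`; tissue-classified
#' samples are zeroed, suppressing residual tissue before beamforming.
#'
#' @param data a `channel_data` frame.
#' @param mask a [predict_mask()] result (`bubble_mask`), or a 0/1
#'   matrix sized like `data$rf`.
#' @param wavelet a [build_mother_wavelet()] result.
#' @param cfg a [bawt_config()]; default uses the scale placing the
#'   wavelet passband at the second harmonic of `data$f_transmit`.
#' @return a `channel_data` frame with enhanced RF (same geometry).
#' @export
apply_bawt <- function(data, mask, wavelet,
                       cfg = bawt_config(optimal_scale(wavelet,
                                                       data$f_transmit))) {
  stopifnot(inherits(data, "channel_data"),
            inherits(wavelet, "bubble_wavelet"),
            inherits(cfg, "bawt_config"))
  mk <- if (inherits(mask, "bubble_mask")) mask$mask else mask
  if (!all(dim(mk) == dim(data$rf)))
    stop("mask dimensions do not match the RF frame")
  psi_s <- dilate_wavelet(wavelet, cfg$scale, fs = data$geometry$fs)
  out <- data
  rf <- matrix(0, nrow(data$rf), ncol(data$rf))
  for (i in seq_len(ncol(rf))) {
    ci <- correlate_same(data$rf[, i], psi_s)
    rf[, i] <- ci * (mk[, i] == 1L)
  }
  out$rf <- rf
  out$bawt <- cfg
  out
}
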