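# Run an expression with a locally seeded RNG, restoring the caller's
# .Random.seed afterwards.  seed = NULL means "use the current RNG stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Frequency of the power-spectral peak of a sampled waveform
#'
#' Zero-pads to a fine FFT grid so that the peak location is resolved well
#' below one coarse bin.
#'
#' @param x real waveform.
#' @param fs sampling rate in Hz.
#' @param pad_factor zero-padding factor (FFT length is the next power of
#'   two at least `pad_factor * length(x)`).
#' @return peak frequency in Hz (in `[0, fs/2]`).
#' @export
spectral_peak <- function(x, fs, pad_factor = 8) {
  stopifnot(length(x) > 1, fs > 0)
  n <- 2^ceiling(log2(length(x) * pad_factor))
  X <- stats::fft(c(x, rep(0, n - length(x))))
  half <- 1:(n %/% 2 + 1)
  p <- Mod(X[half])^2
  fs * (which.max(p) - 1) / n
}

# Power spectrum (one-sided) on a padded grid; returns list(freq, power).
power_spectrum <- function(x, fs, pad_factor = 8) {
  n <- 2^ceiling(log2(length(x) * pad_factor))
  X <- stats::fft(c(x, rep(0, n - length(x))))
  half <- 1:(n %/% 2 + 1)
  list(freq = fs * (half - 1) / n, power = Mod(X[half])^2)
}

#' Analytic-signal envelope of a real RF line
#'
#' Magnitude of the analytic signal computed by one-sided spectrum
#' doubling in the frequency domain (the discrete Hilbert construction).
#'
#' @param x real vector (one RF or beamformed line).
#' @return non-negative envelope, same length as `x`.
#' @export
envelope_line <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (all(x == 0)) return(numeric(n))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# interior helper: stop() with the failing stage name, used by run_pipeline
fail_stage <- function(stage, e) {
  stop(sprintf("pipeline stage '%s' failed: %s", stage,
               conditionMessage(e)), call. = FALSE)
}
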