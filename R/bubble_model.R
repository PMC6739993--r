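# Microbubble shell-model dynamics and the bubble-approximated mother
# wavelet.  A SonoVue-like shelled bubble driven by a short plane-wave
# pulse is solved as a second-order radial ODE (Doinikov shell model);
# the far-field scattered pressure of the oscillating bubble is then used
# as a matched mother wavelet for contrast-agent RF enhancement.

#' Physical parameters of the shelled-microbubble model
#'
#' Defaults describe a SonoVue-like phospholipid-shelled bubble in water.
#'
#' @param rho_l liquid density, kg/m^3.
#' @param P0 ambient (atmospheric) pressure, Pa.
#' @param gamma polytropic exponent of the gas core (dimensionless).
#' @param R0 equilibrium bubble radius, m.
#' @param sigma_R0 surface tension at the equilibrium radius, N/m.
#' @param chi shell elasticity modulus, N/m.
#' @param eta_l liquid shear viscosity, Pa s.
#' @param k0,k1 shell viscosity components (kg and kg/s); the k0 term
#'   saturates with the normalized wall velocity `|Rdot/R|` through the
#'   characteristic time constant `alpha_t`.
#' @param alpha_t characteristic time constant of the shear-thinning
#'   shell viscosity, s.
#' @return an object of class `bubble_params`.
#' @export
bubble_params <- function(rho_l = 1000, P0 = 101000, gamma = 1.07,
                          R0 = 1.7e-6, sigma_R0 = 0.072, chi = 0.25,
                          eta_l = 0.002, k0 = 4e-8, k1 = 7e-15,
                          alpha_t = 4e-6) {
  p <- list(rho_l = rho_l, P0 = P0, gamma = gamma, R0 = R0,
            sigma_R0 = sigma_R0, chi = chi, eta_l = eta_l,
            k0 = k0, k1 = k1, alpha_t = alpha_t)
  bad <- names(p)[!vapply(p, function(v) is.numeric(v) && length(v) == 1 &&
                            is.finite(v) && v > 0, logical(1))]
  if (length(bad))
    stop("bubble_params: fields must be strictly positive scalars: ",
         paste(bad, collapse = ", "))
  structure(p, class = "bubble_params")
}

#' Transmit pulse driving the bubble and the array
#'
#' A gated sine of `n_cycles` cycles at `f0`; `envelope = "hann"` applies
#' a raised-cosine taper over the gate.  The mechanical index
#' (peak pressure in MPa over the square root of frequency in MHz) is
#' checked against the low-MI regime contrast imaging requires.
#'
#' @param f0 center frequency, Hz.
#' @param n_cycles number of cycles in the gate.
#' @param peak_pressure peak drive pressure, Pa.
#' @param fs sampling rate, Hz (must be at least `4 * f0`).
#' @param envelope `"rect"` (gated sine, the default) or `"hann"`.
#' @return an object of class `drive_pulse`.
#' @export
drive_pulse <- function(f0 = 4e6, n_cycles = 2, peak_pressure = 50e3,
                        fs = 25e6, envelope = c("rect", "hann")) {
  envelope <- match.arg(envelope)
  stopifnot(f0 > 0, n_cycles >= 1, peak_pressure >= 0, fs >= 4 * f0)
  mi <- (peak_pressure / 1e6) / sqrt(f0 / 1e6)
  if (mi >= 0.1)
    warning(sprintf(
      "mechanical index %.3f >= 0.1: outside the low-MI regime", mi))
  structure(list(f0 = f0, n_cycles = n_cycles,
                 peak_pressure = peak_pressure, fs = fs,
                 envelope = envelope, duration = n_cycles / f0,
                 mechanical_index = mi),
            class = "drive_pulse")
}

#' Evaluate the drive pressure at arbitrary times
#'
#' @param drive a [drive_pulse()].
#' @param t times in seconds (vector).
#' @return drive pressure in Pa, zero outside the gate.
#' @export
drive_waveform <- function(drive, t) {
  inside <- t >= 0 & t <= drive$duration
  p <- numeric(length(t))
  ti <- t[inside]
  env <- if (drive$envelope == "hann")
    0.5 * (1 - cos(2 * pi * ti / drive$duration)) else 1
  p[inside] <- drive$peak_pressure * env * sin(2 * pi * drive$f0 * ti)
  p
}

# ODE right-hand side.  State y = (R, Rdot); returns (Rdot, Rddot).
# The pressure balance at the bubble wall:
#   rho_l (R R'' + 3/2 R'^2) =
#     (P0 + 2 sigma0/R0) (R0/R)^{3 gamma} - 2 sigma0/R
#     - 4 chi (1/R0 - 1/R) - P0 - P_drive(t)
#     - 4 eta_l R'/R - 4 (k0/(1 + alpha_t |R'/R|) + k1 R'/R) R'/R^2
doinikov_rhs <- function(t, y, p, drive) {
  R <- y[1]; Rd <- y[2]
  if (R <= 0) stop("non-physical collapse: R <= 0 at t = ", t)
  rel <- Rd / R
  press <- (p$P0 + 2 * p$sigma_R0 / p$R0) * (p$R0 / R)^(3 * p$gamma) -
    2 * p$sigma_R0 / R -
    4 * p$chi * (1 / p$R0 - 1 / R) -
    p$P0 - drive_waveform(drive, t) -
    4 * p$eta_l * rel -
    4 * (p$k0 / (1 + p$alpha_t * abs(rel)) + p$k1 * rel) * Rd / R^2
  Rdd <- (press / p$rho_l - 1.5 * Rd^2) / R
  c(Rd, Rdd)
}

#' Solve the shelled-bubble radial dynamics
#'
#' Integrates the second-order radial ODE with an adaptive Runge-Kutta
#' scheme (Dormand-Prince 4(5)) from the equilibrium initial condition
#' `R(0) = R0`, `Rdot(0) = 0`.  The radial acceleration is recovered by
#' evaluating the ODE right-hand side on the solution, not by finite
#' differencing.
#'
#' @param params a [bubble_params()].
#' @param drive a [drive_pulse()].
#' @param t_span `c(t0, t1)` in seconds; the default covers the drive
#'   gate plus 2.5 microseconds of ring-down.
#' @param rtol,atol solver tolerances.
#' @param fs_out output sampling rate, Hz; defaults to `drive$fs`.
#' @return an object of class `radial_trajectory` with fields `t`, `R`,
#'   `Rdot`, `Rddot` and the generating `params`/`drive`.
#' @export
solve_bubble_dynamics <- function(params, drive, t_span = NULL,
                                  rtol = 1e-8, atol = 1e-12,
                                  fs_out = NULL) {
  stopifnot(inherits(params, "bubble_params"), inherits(drive, "drive_pulse"))
  if (is.null(fs_out)) fs_out <- drive$fs
  if (is.null(t_span)) t_span <- c(0, drive$duration + 2.5e-6)
  stopifnot(length(t_span) == 2, t_span[2] > t_span[1])
  times <- seq(t_span[1], t_span[2], by = 1 / fs_out)
  # integrate u = log(R/R0), w = Rdot/R0: positivity of R is structural
  # and trial steps of the adaptive scheme can never evaluate at R <= 0
  rhs <- function(t, y, parms) {
    R <- params$R0 * exp(y[1])
    Rd <- params$R0 * y[2]
    dy <- doinikov_rhs(t, c(R, Rd), params, drive)
    list(c(Rd / R, dy[2] / params$R0))
  }
  sol <- deSolve::ode(y = c(0, 0), times = times, func = rhs, parms = NULL,
                      method = "ode45", rtol = rtol, atol = atol)
  diag_ <- attr(sol, "istate")
  if (!is.null(diag_) && diag_[1] < 0)
    stop("bubble ODE solver failed to converge (istate = ", diag_[1], ")")
  R <- params$R0 * exp(sol[, 2])
  Rdot <- params$R0 * sol[, 3]
  if (any(!is.finite(R)))
    stop("bubble ODE solver returned a non-finite radius")
  if (min(R) / params$R0 < 1e-3)
    stop("non-physical collapse: radius fell below R0/1000")
  Rddot <- vapply(seq_along(times), function(i)
    doinikov_rhs(times[i], c(R[i], Rdot[i]), params, drive)[2], numeric(1))
  structure(list(t = times, R = R, Rdot = Rdot, Rddot = Rddot,
                 fs = fs_out, params = params, drive = drive),
            class = "radial_trajectory")
}

#' Far-field pressure scattered by an oscillating bubble
#'
#' `P(d, t) = rho_l (R/d) (2 Rdot^2 + R Rddot)`, the incompressible
#' far-field of a pulsating sphere; amplitude decays exactly as `1/d`.
#'
#' @param traj a [solve_bubble_dynamics()] result.
#' @param d distance from the bubble center to the observation point, m.
#' @param rho_l liquid density, kg/m^3.
#' @return pressure time series (Pa) on `traj$t`.
#' @export
scattered_pressure <- function(traj, d, rho_l = traj$params$rho_l) {
  stopifnot(inherits(traj, "radial_trajectory"))
  if (!is.numeric(d) || length(d) != 1 || d <= 0)
    stop("scattered_pressure: d must be a positive scalar distance")
  rho_l * (traj$R / d) * (2 * traj$Rdot^2 + traj$R * traj$Rddot)
}

#' Build the bubble-approximated mother wavelet
#'
#' Solves the bubble dynamics under `drive`, evaluates the scattered
#' pressure, trims it to the window holding 99.9% of its energy,
#' subtracts the mean (zero-mean admissibility) and normalizes to unit
#' continuous energy (`sum(psi^2) / fs = 1`).  The spectral peak of the
#' result is recorded as the wavelet center frequency.
#'
#' @param params a [bubble_params()].
#' @param drive a [drive_pulse()].
#' @param t_span optional integration window passed on to the solver.
#' @param energy_frac fraction of waveform energy the trimmed support
#'   must retain.
#' @param fs_out sampling rate of the stored wavelet, Hz.  The default
#'   (100 MHz) oversamples the RF rate so that later dilation onto an RF
#'   grid interpolates from a fine source grid.
#' @return an object of class `bubble_wavelet` with fields `psi`, `fs`,
#'   `f_center`, `norm`.
#' @export
build_mother_wavelet <- function(params = bubble_params(),
                                 drive = drive_pulse(),
                                 t_span = NULL, energy_frac = 0.999,
                                 fs_out = 1e8) {
  traj <- solve_bubble_dynamics(params, drive, t_span = t_span,
                                fs_out = fs_out)
  p <- scattered_pressure(traj, d = 0.01)  # distance cancels after norm
  e <- p^2
  if (sum(e) == 0) stop("degenerate wavelet: scattered pressure is zero")
  cum <- cumsum(e) / sum(e)
  i0 <- max(1L, which(cum >= (1 - energy_frac) / 2)[1] - 1L)
  i1 <- which(cum >= 1 - (1 - energy_frac) / 2)[1]
  psi <- p[i0:i1]
  psi <- psi - mean(psi)
  if (sum(psi^2) == 0) stop("degenerate wavelet: zero energy after trim")
  dt <- 1 / traj$fs
  psi <- psi / sqrt(sum(psi^2) * dt)
  structure(list(psi = psi, fs = traj$fs,
                 f_center = spectral_peak(psi, traj$fs, pad_factor = 16),
                 norm = "unit-energy, zero-mean"),
            class = "bubble_wavelet")
}

#' Scale factor placing the dilated wavelet at the second harmonic
#'
#' The dilation `psi(t/s)` moves the spectral peak from `f_center` to
#' `f_center / s`; choosing `s = f_center / (2 f_transmit)` centers the
#' passband on the second harmonic of the transmit frequency, where the
#' microbubble echo energy that tissue lacks is concentrated.
#'
#' @param wavelet a [build_mother_wavelet()] result.
#' @param f_transmit transmit center frequency, Hz.
#' @return the dimensionless scale factor.
#' @export
optimal_scale <- function(wavelet, f_transmit) {
  stopifnot(inherits(wavelet, "bubble_wavelet"), f_transmit > 0)
  wavelet$f_center / (2 * f_transmit)
}

# Dilated wavelet psi(t/s) sampled at rate `fs` (default the wavelet's
# own grid), discrete unit energy (sum of squares 1).  Used by the CWT.
dilate_wavelet <- function(wavelet, scale, fs = wavelet$fs) {
  stopifnot(scale > 0, fs > 0)
  dur <- (length(wavelet$psi) - 1) / wavelet$fs   # mother support, s
  m <- floor(dur * scale * fs) + 1
  if (m < 4)
    stop("scale too small: dilated wavelet has fewer than 4 samples")
  t_new <- (seq_len(m) - 1) / fs                   # dilated time axis
  psi_s <- stats::approx(x = (seq_along(wavelet$psi) - 1) / wavelet$fs,
                         y = wavelet$psi, xout = t_new / scale)$y
  psi_s / sqrt(sum(psi_s^2))
}

#' @export
print.bubble_wavelet <- function(x, ...) {
  cat(sprintf(
    "bubble wavelet: %d samples at %.1f MHz, center frequency %.2f MHz\n",
    length(x$psi), x$fs / 1e6, x$f_center / 1e6))
  invisible(x)
}

#' @export
print.radial_trajectory <- function(x, ...) {
  cat(sprintf(
    "radial trajectory: %d samples over %.2f us, R in [%.3f, %.3f] um\n",
    length(x$t), diff(range(x$t)) * 1e6,
    min(x$R) * 1e6, max(x$R) * 1e6))
  invisible(x)
}
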