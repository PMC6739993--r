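# Synthetic plane-wave channel-RF generator.  A 0-degree plane wave
# insonifies point scatterers; tissue-like scatterers return a delayed
# copy of the transmit pulse (linear echo) while microbubble scatterers
# return the shelled-bubble scattered-pressure waveform (nonlinear, with
# second-harmonic content).  Per-sample ground-truth labels accompany
# the RF so segment classifiers can be trained and scored.

#' Linear-array probe geometry
#'
#' @param n_elements number of array elements.
#' @param pitch element pitch, m.
#' @param fs sampling rate, Hz.
#' @param c0 speed of sound, m/s.
#' @return an object of class `probe_geometry`; `element_x` holds the
#'   lateral element positions centered on the array midpoint.
#' @export
probe_geometry <- function(n_elements = 128, pitch = 0.3e-3,
                           fs = 25e6, c0 = 1540) {
  stopifnot(n_elements >= 2, pitch > 0, fs > 0, c0 > 0)
  structure(list(
    n_elements = as.integer(n_elements), pitch = pitch, fs = fs, c0 = c0,
    element_x = (seq_len(n_elements) - 1 - (n_elements - 1) / 2) * pitch),
    class = "probe_geometry")
}

#' Point-scatterer phantom
#'
#' @param tissue data frame with columns `x`, `z`, `reflectivity`
#'   (positions in m); linear scatterers.
#' @param bubbles data frame with columns `x`, `z`, `amplitude`;
#'   microbubble scatterers.
#' @param noise_sigma standard deviation of additive white noise on the
#'   RF, in the same (unit-peak echo) amplitude units.
#' @return an object of class `phantom`.
#' @export
phantom <- function(tissue = NULL, bubbles = NULL, noise_sigma = 0) {
  chk <- function(df, val, what) {
    if (is.null(df)) return(data.frame(x = numeric(0), z = numeric(0),
                                       v = numeric(0))[, 0])
    stopifnot(is.data.frame(df), all(c("x", "z", val) %in% names(df)))
    if (nrow(df) && any(df$z <= 0))
      stop(what, " scatterer depths must be positive")
    if (nrow(df) && any(!is.finite(df[[val]])))
      stop(what, " scatterer strengths must be finite")
    df
  }
  tissue <- chk(tissue, "reflectivity", "tissue")
  bubbles <- chk(bubbles, "amplitude", "bubble")
  stopifnot(noise_sigma >= 0)
  structure(list(tissue = tissue, bubbles = bubbles,
                 noise_sigma = noise_sigma), class = "phantom")
}

# resolves the bubble_params() constructor without being shadowed by
# same-named function arguments
default_bubble_params <- function() bubble_params()

# cache of bubble echo waveforms keyed by drive/params/fs
.bubble_wave_cache <- new.env(parent = emptyenv())

# Unit-peak bubble echo waveform at sampling rate fs: scattered pressure
# of the driven bubble trimmed to its energetic support.
bubble_echo_waveform <- function(params, drive, fs) {
  key <- paste(c(unlist(params), drive$f0, drive$n_cycles,
                 drive$peak_pressure, drive$envelope, fs), collapse = "|")
  if (!is.null(.bubble_wave_cache[[key]])) return(.bubble_wave_cache[[key]])
  traj <- solve_bubble_dynamics(params, drive, fs_out = fs)
  p <- scattered_pressure(traj, d = 0.01)
  e <- p^2
  if (sum(e) > 0) {
    cum <- cumsum(e) / sum(e)
    i0 <- max(1L, which(cum >= 5e-4)[1] - 1L)
    i1 <- which(cum >= 1 - 5e-4)[1]
    p <- p[i0:i1]
    p <- p / max(abs(p))
  }
  .bubble_wave_cache[[key]] <- p
  p
}

#' Simulate one plane-wave transmit/receive on a point-scatterer phantom
#'
#' A 0-degree plane wave reaches depth `z` after `z/c0`; the echo of a
#' scatterer at `(x, z)` reaches element `i` after a further Euclidean
#' return path.  Tissue scatterers echo the transmit pulse; bubble
#' scatterers echo the shelled-bubble scattered pressure.  Echo
#' amplitude is the scatterer strength divided by the return distance.
#' Fractional delays are applied by linear interpolation.
#'
#' @param phantom a [phantom()].
#' @param geometry a [probe_geometry()].
#' @param drive a [drive_pulse()].
#' @param bubble_params a [bubble_params()].
#' @param n_samples RF samples per line.
#' @param seed optional integer; fixes the noise RNG so frames are
#'   bitwise reproducible.
#' @return an object of class `channel_data`: `rf` (samples x elements),
#'   `truth_mask` (0 background, 1 tissue, 2 bubble), `geometry`,
#'   `f_transmit`, `drive`.
#' @export
simulate_plane_wave_rx <- function(phantom, geometry = probe_geometry(),
                                   drive = drive_pulse(),
                                   bubble_params = NULL,
                                   n_samples = 2100, seed = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(geometry, "probe_geometry"))
  if (is.null(bubble_params)) bubble_params <- default_bubble_params()
  if (nrow(phantom$tissue) + nrow(phantom$bubbles) == 0 &&
      phantom$noise_sigma == 0)
    message("empty phantom with zero noise: returning silent frame")
  fs <- geometry$fs; c0 <- geometry$c0
  m <- geometry$n_elements
  rf <- matrix(0, n_samples, m)
  mask <- matrix(0L, n_samples, m)
  w_tissue <- drive_waveform(drive, (0:ceiling(drive$duration * fs)) / fs)
  if (max(abs(w_tissue)) > 0) w_tissue <- w_tissue / max(abs(w_tissue))
  w_bubble <- if (nrow(phantom$bubbles))
    bubble_echo_waveform(bubble_params, drive, fs) else numeric(0)
  n_trunc <- 0L
  add_echoes <- function(df, strength_col, w, label) {
    lw <- length(w)
    if (lw == 0 || !nrow(df)) return()
    for (s in seq_len(nrow(df))) {
      xs <- df$x[s]; zs <- df$z[s]; a0 <- df[[strength_col]][s]
      ret <- sqrt((xs - geometry$element_x)^2 + zs^2)   # per element
      tau <- (zs + ret) / c0
      amp <- a0 / pmax(ret, 1e-4)
      n0 <- tau * fs                       # fractional onset sample
      j0 <- floor(n0); frac <- n0 - j0
      for (i in seq_len(m)) {
        idx <- (j0[i] + 1L):(j0[i] + lw + 1L)  # 1-based, +1 for frac tail
        keep <- idx <= n_samples
        if (!all(keep)) n_trunc <<- n_trunc + 1L
        wfull <- amp[i] * c((1 - frac[i]) * w, 0) +
          amp[i] * c(0, frac[i] * w)
        rf[idx[keep], i] <<- rf[idx[keep], i] + wfull[keep]
        mask[idx[keep], i] <<- pmax(mask[idx[keep], i], label)
      }
    }
  }
  add_echoes(phantom$tissue, "reflectivity", w_tissue, 1L)
  add_echoes(phantom$bubbles, "amplitude", w_bubble, 2L)
  if (n_trunc > 0)
    warning(n_trunc, " echo(es) extended beyond the time window and were",
            " truncated")
  if (phantom$noise_sigma > 0)
    rf <- rf + with_seed(seed,
      matrix(stats::rnorm(n_samples * m, 0, phantom$noise_sigma),
             n_samples, m))
  structure(list(rf = rf, truth_mask = mask, geometry = geometry,
                 f_transmit = drive$f0, drive = drive,
                 bubble_params = bubble_params),
            class = "channel_data")
}

#' @export
print.channel_data <- function(x, ...) {
  cat(sprintf(
    "channel data: %d samples x %d elements at %.1f MHz (f0 = %.2f MHz)\n",
    nrow(x$rf), ncol(x$rf), x$geometry$fs / 1e6, x$f_transmit / 1e6))
  invisible(x)
}

#' Slice channel RF lines into labeled sliding-window segments
#'
#' Each element line is cut into windows of `length` samples advancing
#' by `step`.  When the frame carries a truth mask, a segment is labeled
#' bubble (1) or tissue (0) by the majority label of its samples, ties
#' going to bubble; segments whose samples are mostly unlabeled
#' background get `NA`.  The background fraction is reported so
#' training-set construction can drop mostly-silent windows.
#'
#' @param data a [simulate_plane_wave_rx()] frame (`channel_data`).
#' @param length segment length in samples.
#' @param step window advance in samples.
#' @param frame_id integer identifier recorded in the provenance table.
#' @return an object of class `segment_dataset`: `segments` (one row per
#'   window), `labels`, `bg_frac`, `provenance` (frame, element, start).
#' @export
segment_rf <- function(data, length = 60L, step = 5L, frame_id = 1L) {
  stopifnot(inherits(data, "channel_data"))
  n <- nrow(data$rf); m <- ncol(data$rf)
  length <- as.integer(length); step <- as.integer(step)
  if (length > n) stop("segment length exceeds the line length")
  starts <- seq.int(1L, n - length + 1L, by = step)
  n_seg <- base::length(starts) * m
  segs <- matrix(0, n_seg, length)
  labels <- rep(NA_integer_, n_seg)
  bg <- numeric(n_seg)
  has_truth <- !is.null(data$truth_mask)
  # gather rows: for element i, rows of all windows
  win <- outer(starts, 0:(length - 1L), "+")   # n_starts x length
  k <- 0L
  for (i in seq_len(m)) {
    rows <- (k + 1L):(k + base::length(starts))
    segs[rows, ] <- data$rf[, i][win]
    if (has_truth) {
      mk <- data$truth_mask[, i][win]
      dim(mk) <- dim(win)
      nb <- rowSums(mk == 2L); nt <- rowSums(mk == 1L)
      bg[rows] <- rowSums(mk == 0L) / length
      lab <- ifelse(nb + nt == 0L, NA_integer_, as.integer(nb >= nt))
      labels[rows] <- lab
    }
    k <- k + base::length(starts)
  }
  structure(list(
    segments = segs, labels = labels, bg_frac = bg,
    provenance = data.frame(
      frame = frame_id,
      element = rep(seq_len(m), each = base::length(starts)),
      start = rep(starts, m)),
    split = NULL),
    class = "segment_dataset")
}

#' @export
print.segment_dataset <- function(x, ...) {
  cat(sprintf("segment dataset: %d segments of length %d",
              nrow(x$segments), ncol(x$segments)))
  if (any(!is.na(x$labels)))
    cat(sprintf("; %.1f%% bubble",
                100 * mean(x$labels[!is.na(x$labels)] == 1L)))
  if (!is.null(x$split))
    cat(sprintf("; split %d train / %d test",
                sum(x$split == "train"), sum(x$split == "test")))
  cat("\n")
  invisible(x)
}

# Corpus phantoms emulate the acquisitions the training data came from:
# whole frames of microbubble solution (bubbles throughout the field,
# as in a beaker) or whole frames of tissue speckle (dense scatterer
# field), with randomized placement and strengths.  Mixed frames are
# what inference sees; training samples are drawn from single-class
# acquisitions.
solution_phantom <- function(geometry, z_max, noise_sigma = 0.01) {
  half_ap <- max(geometry$element_x)
  nb <- sample(120:200, 1)
  phantom(bubbles = data.frame(
    x = stats::runif(nb, -half_ap, half_ap),
    z = stats::runif(nb, 5e-3, z_max),
    amplitude = exp(stats::rnorm(nb, 0, 0.5))),
    noise_sigma = noise_sigma)
}

tissue_phantom <- function(geometry, z_max, noise_sigma = 0.01) {
  half_ap <- max(geometry$element_x)
  nt <- sample(150:250, 1)   # dense field: tissue is speckle, not points
  phantom(tissue = data.frame(
    x = stats::runif(nt, -half_ap, half_ap),
    z = stats::runif(nt, 5e-3, z_max),
    reflectivity = exp(stats::rnorm(nt, 0, 0.5))),
    noise_sigma = noise_sigma)
}

#' Canonical bubble-tube fixture phantom
#'
#' A pork-like superficial tissue layer with a few strong scattering
#' points above a 3 mm microbubble-filled tube band: the configuration
#' used throughout the examples and the end-to-end checks.
#'
#' @param geometry a [probe_geometry()].
#' @param tube_depth center depth of the bubble tube, m.
#' @param tube_diameter tube diameter, m.
#' @param n_tissue,n_bubbles scatterer counts.
#' @param strong_reflectivity reflectivity of the strong tissue points.
#' @param noise_sigma additive white-noise level.
#' @return a [phantom()].
#' @export
tube_phantom <- function(geometry = probe_geometry(),
                         tube_depth = 26e-3, tube_diameter = 3e-3,
                         n_tissue = 60, n_bubbles = 40,
                         strong_reflectivity = 4, noise_sigma = 0.01) {
  half_ap <- max(geometry$element_x)
  tissue <- data.frame(
    x = stats::runif(n_tissue, -half_ap, half_ap),
    z = stats::runif(n_tissue, 8e-3, 18e-3),
    reflectivity = exp(stats::rnorm(n_tissue, 0, 0.4)))
  strong <- data.frame(
    x = c(-6e-3, 0, 7e-3), z = c(10e-3, 14e-3, 12e-3),
    reflectivity = strong_reflectivity)
  bubbles <- data.frame(
    x = stats::runif(n_bubbles, -half_ap * 0.6, half_ap * 0.6),
    z = stats::runif(n_bubbles, tube_depth - tube_diameter / 2,
                     tube_depth + tube_diameter / 2),
    amplitude = exp(stats::rnorm(n_bubbles, 0, 0.3)))
  phantom(rbind(tissue, strong), bubbles, noise_sigma)
}

#' Build a labeled training corpus of RF segments
#'
#' Simulates `n_frames` randomized phantoms (scatterer placement,
#' strengths, drive frequency and amplitude all varied), slices each
#' frame into length-`seg_length` windows, drops mostly-background
#' windows, then balances classes to `class_balance` bubble fraction and
#' splits train/test 80/20 at the frame level so that overlapping
#' windows never straddle the split.
#'
#' @param n_segments total corpus size after balancing.
#' @param class_balance bubble fraction of the corpus.
#' @param n_frames number of simulated frames.
#' @param seed integer RNG seed; the corpus is a deterministic function
#'   of it.
#' @param geometry a [probe_geometry()].
#' @param n_samples RF samples per line.
#' @param seg_length,seg_step segmentation parameters.
#' @param f0_choices,amp_choices drive frequencies (Hz) and peak
#'   pressures (Pa) sampled per frame.
#' @param train_frac fraction of frames assigned to the training split.
#' @return a `segment_dataset` with a `split` column.
#' @export
make_training_corpus <- function(n_segments = 20000, class_balance = 0.45,
                                 n_frames = 16, seed = 1,
                                 geometry = probe_geometry(),
                                 n_samples = 2100,
                                 seg_length = 60L, seg_step = 5L,
                                 f0_choices = c(3.5e6, 4e6, 4.5e6),
                                 amp_choices = c(30e3, 40e3, 50e3),
                                 train_frac = 0.8) {
  with_seed(seed, {
    z_max <- 0.9 * geometry$c0 * (n_samples / geometry$fs) / 2
    sets <- vector("list", n_frames)
    for (fr in seq_len(n_frames)) {
      dr <- drive_pulse(f0 = sample(f0_choices, 1),
                        peak_pressure = sample(amp_choices, 1))
      # alternate single-class acquisitions (bubble solution / tissue),
      # mirroring how the field collects pure training recordings
      ph <- if (fr %% 2L == 1L) solution_phantom(geometry, z_max) else
        tissue_phantom(geometry, z_max)
      frame <- simulate_plane_wave_rx(ph, geometry, dr,
                                      n_samples = n_samples)
      ds <- segment_rf(frame, seg_length, seg_step, frame_id = fr)
      keep <- !is.na(ds$labels) & ds$bg_frac <= 0.5
      sets[[fr]] <- list(segments = ds$segments[keep, , drop = FALSE],
                         labels = ds$labels[keep],
                         provenance = ds$provenance[keep, ])
    }
    if (n_frames < 4L || n_frames %% 2L != 0L)
      stop("n_frames must be an even number >= 4 so both acquisition ",
           "types appear on both sides of the frame-level split")
    # at least one frame of each type held out; 80/20 is enforced on
    # segment counts, the frame split only prevents window leakage
    n_train_frames <- min(n_frames - 2L, round(train_frac * n_frames))
    pick <- function(frames, target_n) {
      segs <- do.call(rbind, lapply(sets[frames], `[[`, "segments"))
      labs <- unlist(lapply(sets[frames], `[[`, "labels"))
      prov <- do.call(rbind, lapply(sets[frames], `[[`, "provenance"))
      nb_target <- round(class_balance * target_n)
      nt_target <- target_n - nb_target
      ib <- which(labs == 1L); it <- which(labs == 0L)
      if (length(ib) < nb_target || length(it) < nt_target)
        stop("corpus generation produced too few segments of one class; ",
             "increase n_frames")
      sel <- c(sample(ib, nb_target), sample(it, nt_target))
      sel <- sample(sel)                      # shuffle class order
      list(segments = segs[sel, , drop = FALSE], labels = labs[sel],
           provenance = prov[sel, ])
    }
    tr <- pick(seq_len(n_train_frames), round(train_frac * n_segments))
    te <- pick((n_train_frames + 1L):n_frames,
               n_segments - round(train_frac * n_segments))
    structure(list(
      segments = rbind(tr$segments, te$segments),
      labels = c(tr$labels, te$labels),
      bg_frac = NULL,
      provenance = rbind(tr$provenance, te$provenance),
      split = rep(c("train", "test"),
                  c(length(tr$labels), length(te$labels)))),
      class = "segment_dataset")
  })
}
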