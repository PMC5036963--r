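#' Synthetic striatum-like plane contours
#'
#' Superellipse-based simple polygons standing in for atlas-delineated
#' striatal contours across coronal planes (13 by default, matching the
#' rat series). Plane size drifts along the rostro-caudal axis; an
#' optional notch produces a non-convex contour that exercises the
#' first-intersection logic of the ray-cast normalization.
#'
#' @param n_planes number of coronal planes.
#' @param a_um,b_um semi-axes of the central plane, um.
#' @param exponent superellipse exponent (2 = ellipse; > 2 boxier).
#' @param n_vertices vertices per contour.
#' @param notch_depth fraction (0-0.9) of the local radius carved out of
#'   the medial side; 0 disables the notch.
#' @param seed optional RNG seed (size drift only).
#' @return list of [plane_contour()] objects.
#' @export
make_contours <- function(n_planes = 13L, a_um = 3000, b_um = 2200,
                          exponent = 2.5, n_vertices = 72L,
                          notch_depth = 0, seed = NULL) {
  if (n_planes < 1L) stop("need at least one plane")
  if (a_um <= 0 || b_um <= 0 || exponent <= 0) stop("degenerate shape parameters")
  if (notch_depth < 0 || notch_depth > 0.9) stop("notch_depth must be in [0, 0.9]")
  if (!is.null(seed)) set.seed(seed)
  scales <- 1 - 0.4 * abs(seq(-1, 1, length.out = n_planes))
  bregma <- seq(2.2, -2.6, length.out = n_planes)
  lapply(seq_len(n_planes), function(p) {
    th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
    r <- 1
    if (notch_depth > 0) {
      # carve a smooth dent around theta = pi (the medial side)
      w <- exp(-((th - pi) / 0.35)^2)
      r <- 1 - notch_depth * w
    }
    x <- scales[p] * a_um * r * sign(cos(th)) * abs(cos(th))^(2 / exponent)
    y <- scales[p] * b_um * r * sign(sin(th)) * abs(sin(th))^(2 / exponent)
    plane_contour(cbind(x, y), plane_id = p, bregma_mm = bregma[p])
  })
}

# Beta draw on [-1, 1] with mean `bias`; concentration sets the spread
rbeta_signed <- function(n, bias, concentration = 4) {
  if (abs(bias) >= 1) stop("|bias| must be < 1")
  a <- concentration * (1 + bias) / 2
  b <- concentration * (1 - bias) / 2
  2 * stats::rbeta(n, a, b) - 1
}

#' Sample neurons with a controlled spatial bias inside a contour
#'
#' Target normalized coordinates are drawn from Beta distributions
#' (affinely mapped to \[-1, 1\]) whose means equal the requested ml/dv
#' biases, then placed inside the polygon by inverting the ray
#' parametrization of [normalize_position()]. The realized mean normalized
#' position therefore matches the target up to sampling error.
#'
#' @param contour a [plane_contour()].
#' @param n number of neurons (> 0).
#' @param ml_bias,dv_bias target mean normalized positions, in (-1, 1).
#' @param seed optional RNG seed.
#' @param concentration Beta concentration (larger = tighter around the
#'   mean).
#' @return data frame with `x`, `y`, `ml_target`, `dv_target`.
#' @export
sample_biased_neurons <- function(contour, n, ml_bias = 0, dv_bias = 0,
                                  seed = NULL, concentration = 4) {
  if (n <= 0) stop("n must be positive")
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(x = numeric(n), y = numeric(n),
                    ml_target = numeric(n), dv_target = numeric(n))
  filled <- 0L
  guard <- 0L
  while (filled < n) {
    guard <- guard + 1L
    if (guard > 50L * n) stop("placement failed; contour too irregular")
    ml <- rbeta_signed(1L, ml_bias, concentration)
    dv <- rbeta_signed(1L, dv_bias, concentration)
    inv <- invert_normalized_position(ml, dv, contour)
    if (!inv$converged) next
    filled <- filled + 1L
    out[filled, ] <- c(inv$x, inv$y, ml, dv)
  }
  out
}

# 1/f ("pink") noise via FFT spectral shaping, unit SD
pink_noise <- function(n) {
  X <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)            # symmetric frequency index
  y <- Re(stats::fft(X / sqrt(f), inverse = TRUE)) / n
  y / stats::sd(y)
}

# monotone exponential waveshaper on [-1, 1]; skew != 0 breaks the
# up/down symmetry of a sinusoid without changing its period
waveshape_skew <- function(s, skew) {
  if (skew == 0) return(s)
  (exp(skew * (s + 1) / 2) - 1) / (exp(skew) - 1) * 2 - 1
}

#' Simulate an ECoG/LFP-like field signal
#'
#' Sum of a ~1 Hz slow oscillation (optionally skewed through a monotone
#' waveshaper, producing the non-uniform phase distributions that motivate
#' the ECDF correction), a spindle-band component, a gamma-band component,
#' and 1/f noise.
#'
#' @param duration_s signal length, s.
#' @param fs sampling rate, Hz (> 200; 1 kHz default, 16600 matches the
#'   acquisition rate of the recordings modeled).
#' @param amplitudes named numeric: `slow`, `spindle`, `gamma`, `noise`.
#' @param f_slow,f_spindle,f_gamma component frequencies, Hz.
#' @param skew slow-wave skew parameter (0 = pure sinusoid).
#' @param seed optional RNG seed.
#' @param channel signal label.
#' @return a [sampled_signal()] with a `truth` attribute.
#' @export
simulate_field <- function(duration_s, fs = 1000,
                           amplitudes = c(slow = 1, spindle = 0.3,
                                          gamma = 0.15, noise = 0.2),
                           f_slow = 1, f_spindle = 9.5, f_gamma = 40,
                           skew = 0, seed = NULL, channel = "ECoG") {
  if (duration_s <= 0) stop("duration must be positive")
  if (fs <= 200) stop("sampling rate must exceed 200 Hz")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  ph0 <- stats::runif(3, 0, 2 * pi)
  slow <- amplitudes[["slow"]] * waveshape_skew(sin(2 * pi * f_slow * t + ph0[1]), skew)
  spin <- amplitudes[["spindle"]] * sin(2 * pi * f_spindle * t + ph0[2]) *
    (0.5 + 0.5 * sin(2 * pi * f_slow * t + ph0[1]))
  gam <- amplitudes[["gamma"]] * sin(2 * pi * f_gamma * t + ph0[3])
  noise <- if (amplitudes[["noise"]] > 0) amplitudes[["noise"]] * pink_noise(n) else 0
  s <- sampled_signal(slow + spin + gam + noise, fs, channel = channel)
  attr(s, "truth") <- list(f_slow = f_slow, f_spindle = f_spindle,
                           f_gamma = f_gamma, amplitudes = amplitudes,
                           skew = skew)
  s
}

#' Simulate a phase-locked spike train
#'
#' Inhomogeneous Poisson process with von Mises phase modulation: the
#' intensity is proportional to `exp(kappa * cos(theta(t) - mu))` where
#' `theta(t)` is the instantaneous phase of the signal in `band`,
#' normalized to a target mean rate. The expected recovered vector length
#' is the Bessel ratio `I1(kappa) / I0(kappa)`.
#'
#' @param s a [sampled_signal()].
#' @param band length-2 Hz band whose phase drives the modulation.
#' @param rate target mean firing rate, spikes/s (> 0).
#' @param kappa von Mises concentration (>= 0; 0 = homogeneous Poisson).
#' @param mu preferred phase, radians (0 = oscillation peak).
#' @param seed optional RNG seed.
#' @param state,identity labels for the resulting [spike_train()].
#' @return a [spike_train()] spanning the signal, with a `truth` attribute.
#' @export
simulate_locked_train <- function(s, band = c(0.67, 1.5), rate = 5, kappa = 1,
                                  mu = 0, seed = NULL, state = "SWA",
                                  identity = NA_character_) {
  if (rate <= 0) stop("rate must be positive")
  if (kappa < 0) stop("kappa must be non-negative")
  if (band[2] >= s$fs / 2) stop("band outside the signal's Nyquist range")
  if (!is.null(seed)) set.seed(seed)
  dur <- length(s$samples) / s$fs
  if (kappa == 0) {
    lam <- rep(rate, length(s$samples))
  } else {
    th <- analytic_phase(s, band[1], band[2])$phase
    lam <- exp(kappa * cos(th - mu))
    lam <- rate * lam / mean(lam)
  }
  lam_max <- max(lam)
  n_cand <- stats::rpois(1L, lam_max * dur)
  # cap candidates at the last sample so every spike has a phase sample
  cand <- sort(stats::runif(n_cand, 0, (length(s$samples) - 1) / s$fs))
  idx <- pmin(pmax(round(cand * s$fs + 1), 1L), length(lam))
  keep <- stats::runif(n_cand) < lam[idx] / lam_max
  times <- unique(s$t0 + cand[keep])
  st <- spike_train(times, epoch = s$t0 + c(0, dur), state = state,
                    identity = identity)
  attr(st, "truth") <- list(rate = rate, kappa = kappa, mu = mu, band = band,
                            expected_R = besselI(kappa, 1) / besselI(kappa, 0))
  st
}

#' Simulate spikes timed relative to iLFP peaks
#'
#' For every retained peak, spike normalized times are drawn from a
#' Gaussian with mean `mu_star` and SD `sigma_star` truncated to
#' \[-1, 1\], then mapped back to real time within the peak.
#'
#' @param peaks data frame from [segment_peaks()] (>= 1 row).
#' @param mu_star target mean normalized firing time, in (-1, 1).
#' @param sigma_star normalized-time SD (> 0).
#' @param spikes_per_peak expected spikes per peak (Poisson count).
#' @param seed optional RNG seed.
#' @param epoch epoch for the resulting train (default spans the peaks).
#' @return a [spike_train()] with a `truth` attribute.
#' @export
simulate_peak_timed_train <- function(peaks, mu_star = -0.3, sigma_star = 0.1,
                                      spikes_per_peak = 5, seed = NULL,
                                      epoch = NULL) {
  if (nrow(peaks) < 1L) stop("no peaks to place spikes in")
  if (abs(mu_star) >= 1 || sigma_star <= 0) stop("invalid timing parameters")
  if (!is.null(seed)) set.seed(seed)
  times <- numeric(0)
  for (r in seq_len(nrow(peaks))) {
    k <- stats::rpois(1L, spikes_per_peak)
    if (k == 0L) next
    z <- stats::rnorm(k, mu_star, sigma_star)
    bad <- z <= -1 | z >= 1
    while (any(bad)) {                       # rejection-truncate to (-1, 1)
      z[bad] <- stats::rnorm(sum(bad), mu_star, sigma_star)
      bad <- z <= -1 | z >= 1
    }
    times <- c(times, peaks$start_s[r] + (z + 1) / 2 * peaks$duration_s[r])
  }
  times <- sort(unique(times))
  if (is.null(epoch)) epoch <- c(min(peaks$start_s), max(peaks$end_s))
  st <- spike_train(times, epoch = epoch, state = "SWA")
  attr(st, "truth") <- list(mu_star = mu_star, sigma_star = sigma_star,
                            spikes_per_peak = spikes_per_peak)
  st
}

#' Simulate Gaussian feature clusters with identity labels
#'
#' `k` spherical Gaussian clusters in `dims` dimensions with unit
#' within-cluster SD and mutual center distances equal to
#' `separation` (centers on a randomly oriented regular simplex). Identity
#' labels agree with the generating cluster at rate
#' `identity_correlation`.
#'
#' @param k number of clusters (>= 1).
#' @param n_per_cluster rows per cluster.
#' @param separation mutual center distance in within-cluster SD units
#'   (>= 0; ignored for k = 1).
#' @param dims number of feature columns.
#' @param seed optional RNG seed.
#' @param identity_correlation probability a row's identity label matches
#'   its cluster.
#' @return list with `features` (matrix), `labels` (true clusters),
#'   `identities` (character).
#' @export
simulate_feature_clusters <- function(k = 3L, n_per_cluster = 20L,
                                      separation = 5, dims = 6L, seed = NULL,
                                      identity_correlation = 1) {
  if (k < 1L) stop("k must be >= 1")
  if (separation < 0) stop("separation must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  centers <- matrix(0, k, dims)
  if (k > 1L) {
    S <- diag(k) - 1 / k
    E <- eigen(S, symmetric = TRUE)
    V <- E$vectors[, seq_len(k - 1L), drop = FALSE] %*%
      diag(sqrt(pmax(E$values[seq_len(k - 1L)], 0)), k - 1L)
    V <- V / sqrt(2) * separation           # rows mutually `separation` apart
    Q <- qr.Q(qr(matrix(stats::rnorm(dims * (k - 1L)), dims, k - 1L)))
    centers <- V %*% t(Q)
  }
  labels <- rep(seq_len(k), each = n_per_cluster)
  X <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(length(labels) * dims), ncol = dims)
  colnames(X) <- paste0("f", seq_len(dims))
  ids <- paste0("type", labels)
  flip <- stats::runif(length(labels)) > identity_correlation
  if (any(flip) && k > 1L) {
    ids[flip] <- paste0("type", vapply(labels[flip], function(l) {
      sample(setdiff(seq_len(k), l), 1L)
    }, integer(1)))
  }
  list(features = X, labels = labels, identities = ids)
}

#' Simulate nucleus top-depths in a tissue slab
#'
#' Homogeneous nuclei at a known volumetric density inside a slab of
#' given thickness over the disector counting frame: per frame, a Poisson
#' number of nucleus tops with depths uniform over the slab. Ground truth
#' for fractionator density recovery.
#'
#' @param density_mm3 true density, cells/mm^3 (> 0).
#' @param slab_um slab thickness, um (> disector depth + guard).
#' @param spec a [disector_spec()].
#' @param n_frames number of independent frames.
#' @param seed optional RNG seed.
#' @return list with `depths` (list of per-frame depth vectors) and
#'   `truth` (the density).
#' @export
simulate_nucleus_stack <- function(density_mm3, slab_um, spec = disector_spec(),
                                   n_frames = 1L, seed = NULL) {
  if (density_mm3 <= 0 || slab_um <= 0) stop("degenerate slab or density")
  if (!is.null(seed)) set.seed(seed)
  vol_mm3 <- spec$frame_width_um * spec$frame_height_um * slab_um * 1e-9
  depths <- lapply(seq_len(n_frames), function(i) {
    n <- stats::rpois(1L, density_mm3 * vol_mm3)
    sort(stats::runif(n, 0, slab_um))
  })
  list(depths = depths, truth = list(density_mm3 = density_mm3,
                                     slab_um = slab_um, n_frames = n_frames))
}

#' Simulate Cavalieri point-grid counts over an ellipsoid
#'
#' Systematic sections through an analytic ellipsoid with a randomly
#' offset square point grid per section; the counts feed
#' [cavalieri_volume()] and the analytic volume `4/3*pi*a*b*c` is the
#' ground truth.
#'
#' @param semi_axes_mm length-3 semi-axes (a, b, c), mm.
#' @param a_p_mm2 area per grid point, mm^2.
#' @param t_mm section spacing, mm.
#' @param seed optional RNG seed.
#' @return list with `P` (counts per section), `a_p_mm2`, `t_mm`,
#'   `truth` (analytic volume, mm^3).
#' @export
simulate_point_grid <- function(semi_axes_mm = c(2, 1.5, 1), a_p_mm2 = 0.01,
                                t_mm = 0.2, seed = NULL) {
  if (any(semi_axes_mm <= 0) || a_p_mm2 <= 0 || t_mm <= 0) {
    stop("positive dimensions required")
  }
  if (!is.null(seed)) set.seed(seed)
  a <- semi_axes_mm[1]; b <- semi_axes_mm[2]; cc <- semi_axes_mm[3]
  gs <- sqrt(a_p_mm2)
  z0 <- stats::runif(1, 0, t_mm)               # random section phase
  zs <- seq(-cc + z0, cc, by = t_mm)
  P <- vapply(zs, function(z) {
    f <- 1 - (z / cc)^2
    if (f <= 0) return(0L)
    ae <- a * sqrt(f); be <- b * sqrt(f)
    ox <- stats::runif(1, 0, gs); oy <- stats::runif(1, 0, gs)
    gx <- seq(-ae - gs + ox, ae, by = gs)
    gy <- seq(-be - gs + oy, be, by = gs)
    sum(outer(gx^2 / ae^2, gy^2 / be^2, "+") < 1)
  }, integer(1))
  list(P = P, a_p_mm2 = a_p_mm2, t_mm = t_mm,
       truth = list(volume_mm3 = 4 / 3 * pi * a * b * cc))
}
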