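#' Spike train within a recording epoch
#'
#' Spike times in seconds, strictly increasing, all inside the epoch. A
#' brain-state label ("SWA" or "activation") and a molecular-identity label
#' travel with the train. Epochs shorter than 60 s are allowed at
#' construction but flagged, since downstream population analyses only
#' include epochs of at least 60 s.
#'
#' @param times numeric vector of spike times (s), strictly increasing.
#' @param epoch length-2 numeric `c(t0, t1)` in seconds.
#' @param state brain-state label.
#' @param identity molecular identity label (e.g. "PV+/Scgn+").
#' @param min_epoch_s inclusion threshold for analysis (default 60 s).
#' @return object of class `spike_train`.
#' @export
spike_train <- function(times, epoch, state = c("SWA", "activation"),
                        identity = NA_character_, min_epoch_s = 60) {
  state <- match.arg(state)
  times <- as.numeric(times)
  if (length(epoch) != 2L || epoch[2] <= epoch[1]) stop("invalid epoch")
  if (is.unsorted(times, strictly = TRUE)) stop("spike times must be strictly increasing")
  if (length(times) && (times[1] < epoch[1] || times[length(times)] > epoch[2])) {
    stop("spike times must lie within the epoch")
  }
  structure(list(times = times, epoch = as.numeric(epoch), state = state,
                 identity = identity,
                 meets_min_epoch = diff(epoch) >= min_epoch_s),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train: %d spikes in [%.2f, %.2f] s (%s, %s)\n",
              length(x$times), x$epoch[1], x$epoch[2], x$state, x$identity))
  invisible(x)
}

isi_of <- function(st) diff(st$times)

#' Mean firing rate
#'
#' Spike count divided by epoch duration, in spikes/s.
#'
#' @param st a [spike_train()].
#' @return firing rate (>= 0).
#' @export
firing_rate <- function(st) {
  dur <- diff(st$epoch)
  if (dur <= 0) stop("zero-length epoch")
  length(st$times) / dur
}

#' Default log-spaced ISI histogram bin edges
#'
#' 100 logarithmically spaced bins from 1 ms to 10 s.
#'
#' @param n_bins number of bins.
#' @param lo,hi range in seconds.
#' @return vector of `n_bins + 1` edges.
#' @export
isi_bin_edges <- function(n_bins = 100L, lo = 1e-3, hi = 10) {
  exp(seq(log(lo), log(hi), length.out = n_bins + 1L))
}

#' Interspike-interval histogram (percent counts)
#'
#' Percent of ISIs per bin over log-spaced edges; ISIs outside the edge
#' range accumulate in the first/last bin so that the histogram always sums
#' to 100 when at least one ISI exists.
#'
#' @param st a [spike_train()] with >= 2 spikes.
#' @param edges bin edges in seconds (default [isi_bin_edges()]).
#' @return object of class `isi_histogram` with `edges` and
#'   `percent` (summing to 100).
#' @export
isi_histogram <- function(st, edges = isi_bin_edges()) {
  isi <- isi_of(st)
  if (length(isi) < 1L) stop("need >= 2 spikes for an ISI histogram")
  clipped <- pmin(pmax(isi, edges[1]), edges[length(edges)])
  cnt <- graphics::hist(clipped, breaks = edges, plot = FALSE,
              include.lowest = TRUE, right = TRUE)$counts
  structure(list(edges = edges, percent = 100 * cnt / sum(cnt),
                 n_isi = length(isi)),
            class = "isi_histogram")
}

#' Spearman correlation between two ISI histograms
#'
#' Firing-pattern similarity of a neuron pair: the Spearman rho between
#' their percent-count ISI histograms over identical bins. Within-group
#' pair correlations are then compared across groups (e.g. by
#' [mann_whitney()] or [kruskal_wallis_dunn()]) to quantify how homogeneous
#' each population's firing pattern is.
#'
#' @param h_a,h_b [isi_histogram()] objects with identical edges.
#' @return Spearman rho.
#' @export
isi_pair_correlation <- function(h_a, h_b) {
  if (length(h_a$edges) != length(h_b$edges) ||
      any(h_a$edges != h_b$edges)) {
    stop("histograms must share identical bin edges")
  }
  spearman_rho(h_a$percent, h_b$percent)
}

#' CV2 and ISI-variability features
#'
#' Local variability `CV2_i = 2|ISI_(i+1) - ISI_i| / (ISI_(i+1) + ISI_i)`
#' plus summary features used for clustering: the CV2 mean, the CV2 ratio
#' (proportion of CV2 values below `lo` over proportion above `hi`,
#' add-one smoothed so regular trains stay finite; the unsmoothed ratio is
#' also reported), and the global ISI coefficient of variation.
#'
#' @param st a [spike_train()] with >= 3 spikes.
#' @param lo,hi CV2 ratio cutoffs (defaults 0.2 and 1.85).
#' @return list with `cv2` (series), `cv2_mean`, `cv2_ratio`,
#'   `cv2_ratio_raw`, `cv_isi`.
#' @export
cv2_features <- function(st, lo = 0.2, hi = 1.85) {
  isi <- isi_of(st)
  if (length(isi) < 2L) stop("need >= 2 ISIs (3 spikes)")
  a <- isi[-length(isi)]; b <- isi[-1L]
  cv2 <- 2 * abs(b - a) / (b + a)
  n_lo <- sum(cv2 < lo); n_hi <- sum(cv2 > hi)
  list(cv2 = cv2,
       cv2_mean = mean(cv2),
       cv2_ratio = (n_lo + 1) / (n_hi + 1),
       cv2_ratio_raw = if (n_hi > 0) n_lo / n_hi else NA_real_,
       cv_isi = stats::sd(isi) / mean(isi))
}

#' Log10 ISI percentile
#'
#' log10 of the linearly interpolated qth percentile of the interspike
#' intervals (q = 10, 50 and 85 are the clustering features).
#'
#' @param st a [spike_train()] with >= 2 spikes.
#' @param q percentile in (0, 100).
#' @return log10 seconds.
#' @export
log_isi_percentile <- function(st, q) {
  isi <- isi_of(st)
  if (length(isi) < 1L) stop("need >= 2 spikes")
  log10(unname(stats::quantile(isi, q / 100, type = 7)))
}

#' Split a mean spike waveform into D1 and D2 segments
#'
#' D1 is the time for the waveform to go from baseline to the peak of its
#' first deflection; D2 the time to return from that peak to baseline.
#' Baseline mean and SD come from the pre-trigger window; departure and
#' return are judged against `k` baseline SDs, with a return requiring
#' `sustain` consecutive samples inside the band. A waveform that never
#' returns has `d2_ms = NA` and is flagged (such cells are excluded from
#' waveform-length comparisons).
#'
#' @param w numeric waveform samples.
#' @param fs sampling rate, Hz.
#' @param n_baseline number of pre-trigger baseline samples.
#' @param k departure threshold in baseline SDs.
#' @param sustain consecutive in-band samples required for a return.
#' @return list with `d1_ms`, `d2_ms`, `total_ms`, `peak_index`, `ok`.
#' @export
waveform_segments <- function(w, fs, n_baseline = max(2L, floor(0.2 * length(w))),
                              k = 3, sustain = 3L) {
  w <- as.numeric(w)
  if (n_baseline < 2L || n_baseline >= length(w)) stop("invalid baseline window")
  mu <- mean(w[seq_len(n_baseline)])
  s <- stats::sd(w[seq_len(n_baseline)])
  thr <- max(k * s, .Machine$double.eps * max(abs(w - mu), 1))
  dev <- abs(w - mu)
  out <- which(dev > thr)
  out <- out[out > n_baseline]
  if (!length(out)) stop("no deflection beyond the baseline band")
  i0 <- out[1L]
  sgn <- sign(w[i0] - mu)
  # first deflection runs until the signal next crosses the baseline mean
  end1 <- i0
  while (end1 < length(w) && sign(w[end1] - mu) == sgn) end1 <- end1 + 1L
  peak <- i0 - 1L + which.max(sgn * (w[i0:end1] - mu))
  # last in-band sample before the departure = baseline departure point
  pre <- which(dev[seq_len(peak)] <= thr)
  t_start <- if (length(pre)) max(pre) else 1L
  d1 <- (peak - t_start) / fs
  # first sustained return to within the baseline band after the peak
  inband <- dev <= thr
  t_ret <- NA_integer_
  if (peak < length(w)) {
    run <- 0L
    for (i in (peak + 1L):length(w)) {
      run <- if (inband[i]) run + 1L else 0L
      if (run >= sustain) { t_ret <- i - sustain + 1L; break }
    }
    if (is.na(t_ret) && run > 0L && inband[length(w)]) {
      t_ret <- length(w) - run + 1L   # in-band run truncated by the record end
    }
  }
  d2 <- if (is.na(t_ret)) NA_real_ else (t_ret - peak) / fs
  list(d1_ms = 1000 * d1, d2_ms = 1000 * d2,
       total_ms = 1000 * (d1 + d2), peak_index = peak, ok = !is.na(t_ret))
}

#' Full electrophysiological feature record for one neuron
#'
#' Convenience wrapper computing the scalar features used downstream:
#' firing rate, log ISI percentiles (10/50/85), CV of ISIs, CV2 mean and
#' CV2 ratio.
#'
#' @param st a [spike_train()] with >= 3 spikes.
#' @return one-row data frame.
#' @export
feature_record <- function(st) {
  cv <- cv2_features(st)
  data.frame(rate = firing_rate(st),
             log_isi_p10 = log_isi_percentile(st, 10),
             log_isi_p50 = log_isi_percentile(st, 50),
             log_isi_p85 = log_isi_percentile(st, 85),
             cv_isi = cv$cv_isi,
             cv2_mean = cv$cv2_mean,
             cv2_ratio = cv$cv2_ratio)
}
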