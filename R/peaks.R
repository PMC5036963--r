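#' Admissible iLFP peak-duration window from the filter passband
#'
#' Trough-to-trough cycles of an oscillation confined to a `[low, high]` Hz
#' passband last between `1/high` and `1/low` seconds; cycles outside the
#' corner periods are artifacts of the segmentation and are discarded. For
#' the 0.4-1.6 Hz slow-oscillation band this gives 0.625-2.5 s.
#'
#' @param low,high passband edges in Hz.
#' @return named numeric `c(min, max)` in seconds.
#' @export
duration_gate <- function(low = 0.4, high = 1.6) {
  if (low <= 0 || high <= low) stop("need 0 < low < high")
  c(min = 1 / high, max = 1 / low)
}

#' Invert and slow-band filter an LFP
#'
#' The striatal LFP polarity is inverted (iLFP) so that peaks correspond to
#' the synchronized depolarized 'up states' of nearby projection neurons,
#' then filtered with a zero-phase 2nd-order Butterworth bandpass at
#' 0.4-1.6 Hz.
#'
#' @param lfp a [sampled_signal()] with `fs >= 10` Hz.
#' @param low,high slow band edges in Hz.
#' @param order Butterworth order.
#' @return filtered iLFP as a [sampled_signal()] with a `band` attribute.
#' @export
invert_and_filter <- function(lfp, low = 0.4, high = 1.6, order = 2L) {
  if (lfp$fs < 10) stop("sampling rate too low for the slow band")
  inv <- sampled_signal(-lfp$samples, lfp$fs, channel = "iLFP", t0 = lfp$t0)
  bandpass_filter(inv, low, high, order = order)
}

#' Segment trough-to-trough iLFP peaks
#'
#' The Hilbert phase of the filtered iLFP is unwrapped and troughs are
#' located as crossings of odd multiples of pi (phase -pi -> pi delimits
#' one peak), not as amplitude minima. Peaks with a duration outside the
#' gate are discarded; incomplete peaks at the record edges never form.
#'
#' @param filtered_ilfp output of [invert_and_filter()].
#' @param gate duration gate in s; defaults to [duration_gate()] evaluated
#'   at the signal's `band` attribute.
#' @return data frame with columns `start_s`, `end_s`, `duration_s` (may
#'   have zero rows).
#' @export
segment_peaks <- function(filtered_ilfp, gate = NULL) {
  if (is.null(gate)) {
    band <- attr(filtered_ilfp, "band")
    if (is.null(band)) stop("no band attribute; pass `gate` explicitly")
    gate <- duration_gate(band[["low"]], band[["high"]])
  }
  band <- attr(filtered_ilfp, "band")
  pad_s <- if (!is.null(band)) 2 / band[["low"]] else 2 * gate[["max"]]
  ph <- Arg(analytic_padded(filtered_ilfp$samples, filtered_ilfp$fs, pad_s))
  up <- ph + cumsum(c(0, ifelse(diff(ph) < -pi, 2 * pi,
                                ifelse(diff(ph) > pi, -2 * pi, 0))))
  fs <- filtered_ilfp$fs; t0 <- filtered_ilfp$t0
  # crossing times of each odd multiple of pi, linearly interpolated
  lev <- seq(from = (floor((min(up) / pi - 1) / 2) * 2 + 1) * pi,
             to = max(up), by = 2 * pi)
  lev <- lev[lev >= min(up) & lev <= max(up)]
  troughs <- numeric(0)
  for (L in lev) {
    i <- which(up[-length(up)] < L & up[-1L] >= L)
    if (length(i)) {
      # phase wobble near the filter transients can re-cross a level; the
      # last up-crossing is the committed trough for that cycle
      i <- max(i[i > 0])
      frac <- (L - up[i]) / (up[i + 1L] - up[i])
      troughs <- c(troughs, t0 + (i - 1 + frac) / fs)
    }
  }
  troughs <- sort(troughs)
  if (length(troughs) < 2L) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0)))
  }
  pk <- data.frame(start_s = troughs[-length(troughs)], end_s = troughs[-1L])
  pk$duration_s <- pk$end_s - pk$start_s
  pk[pk$duration_s >= gate[["min"]] & pk$duration_s <= gate[["max"]], ,
     drop = FALSE]
}

#' Peak-aligned normalized-time firing histogram
#'
#' Each spike falling inside a retained iLFP peak is mapped to normalized
#' time `2 * (t - start) / duration - 1` in \[-1, 1\] (so a spike at 30% of
#' any peak lands in the same bin regardless of the peak's duration) and
#' accumulated over 100 equal right-closed bins; a spike exactly at a
#' trough boundary belongs to the peak beginning there. The mean filtered
#' iLFP amplitude per bin and the median normalized firing time are also
#' returned.
#'
#' @param st a [spike_train()].
#' @param peaks data frame from [segment_peaks()].
#' @param filtered_ilfp optional filtered iLFP for the amplitude profile.
#' @param n_bins number of normalized-time bins (default 100).
#' @return object of class `peak_histogram`: `counts` (length `n_bins`),
#'   `edges`, `median_firing_time` (NA-flagged when no spike falls in a
#'   peak), `amplitude` (or NULL), `n_spikes_in_peaks`, `n_peaks`.
#' @export
normalized_histogram <- function(st, peaks, filtered_ilfp = NULL,
                                 n_bins = 100L) {
  if (nrow(peaks) < 1L) stop("need at least one retained peak")
  norm_t <- numeric(0)
  for (r in seq_len(nrow(peaks))) {
    sel <- st$times >= peaks$start_s[r] & st$times < peaks$end_s[r]
    if (any(sel)) {
      norm_t <- c(norm_t,
                  2 * (st$times[sel] - peaks$start_s[r]) / peaks$duration_s[r] - 1)
    }
  }
  edges <- seq(-1, 1, length.out = n_bins + 1L)
  counts <- if (length(norm_t)) {
    graphics::hist(norm_t, breaks = edges, plot = FALSE, include.lowest = TRUE,
         right = TRUE)$counts
  } else rep(0L, n_bins)
  amp <- NULL
  if (!is.null(filtered_ilfp)) {
    centers <- (edges[-1L] + edges[-length(edges)]) / 2
    fs <- filtered_ilfp$fs; t0 <- filtered_ilfp$t0
    n <- length(filtered_ilfp$samples)
    prof <- matrix(NA_real_, nrow(peaks), n_bins)
    for (r in seq_len(nrow(peaks))) {
      tt <- peaks$start_s[r] + (centers + 1) / 2 * peaks$duration_s[r]
      idx <- pmin(pmax(round((tt - t0) * fs + 1), 1L), n)
      prof[r, ] <- filtered_ilfp$samples[idx]
    }
    amp <- colMeans(prof)
  }
  structure(list(counts = counts, edges = edges,
                 median_firing_time = if (length(norm_t)) stats::median(norm_t) else NA_real_,
                 amplitude = amp,
                 n_spikes_in_peaks = length(norm_t), n_peaks = nrow(peaks)),
            class = "peak_histogram")
}

#' Compare median normalized firing times across neuron groups
#'
#' Kruskal-Wallis ANOVA on ranks with Dunn post-hoc tests over the
#' per-neuron median firing times of two or more populations (e.g. dSPN /
#' iSPN / PV+/Scgn- / PV+/Scgn+).
#'
#' @param groups named list of numeric vectors of median firing times,
#'   each with >= 3 neurons.
#' @return A [test_result()] with Dunn pairwise table.
#' @export
compare_firing_times <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  if (any(vapply(groups, length, 1L) < 3L)) stop("each group needs >= 3 neurons")
  kruskal_wallis_dunn(groups)
}

#' Compare iLFP peak properties across neuron groups
#'
#' Control analysis: the durations (or amplitudes, or peak times) of the
#' iLFP peaks used for each neuron group should not differ between groups;
#' a significant result would mean firing-time differences could reflect
#' biased field recordings rather than biased spiking.
#'
#' @param groups named list of numeric vectors (one property value per
#'   peak or per neuron).
#' @return A [test_result()].
#' @export
compare_peak_properties <- function(groups) {
  kruskal_wallis_dunn(groups)
}
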