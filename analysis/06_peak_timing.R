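#!/usr/bin/env Rscript
# Normalized-time firing analysis around iLFP slow-oscillation peaks:
# four simulated neuron groups fire early or late within the peak
# (dSPN-like early, iSPN-like late; one PV-like group early, the other
# centered), and their median normalized firing times are compared with
# Kruskal-Wallis + Dunn tests, with the peak-duration control comparison.

library(pvscgn)
dir.create("results", showWarnings = FALSE)
set.seed(1006)

lfp <- simulate_field(150, fs = 250, amplitudes = c(slow = 1, spindle = 0.1,
                                                    gamma = 0.05, noise = 0.15),
                      seed = 1006, channel = "LFP")
ilfp <- invert_and_filter(sampled_signal(-lfp$samples, lfp$fs, "LFP"))
peaks <- segment_peaks(ilfp)
cat(sprintf("Retained %d iLFP peaks (durations %.2f-%.2f s).\n",
            nrow(peaks), min(peaks$duration_s), max(peaks$duration_s)))

groups <- list(dSPN = -0.25, iSPN = 0.10, ScgnNeg = -0.35, ScgnPos = 0.00)
med <- lapply(groups, function(mu) {
  replicate(12, normalized_histogram(
    simulate_peak_timed_train(peaks, mu, 0.12, 4), peaks)$median_firing_time)
})

cmp <- compare_firing_times(med)
write.csv(cmp$pairwise, "results/peak_timing_pairwise.csv", row.names = FALSE)
out <- data.frame(group = names(med),
                  median_firing_time = vapply(med, median, numeric(1)))
write.csv(out, "results/peak_timing.csv", row.names = FALSE)
print(out, row.names = FALSE)
cat(sprintf("Kruskal-Wallis across groups: p = %.2g.\n", cmp$p_value))

ctrl <- compare_peak_properties(lapply(groups, function(...) peaks$duration_s))
cat(sprintf("Control (identical peak durations across groups): p = %.2f.\n",
            ctrl$p_value))
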