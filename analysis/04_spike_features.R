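#!/usr/bin/env Rscript
# Spike-train feature extraction and firing-pattern homogeneity. Three
# simulated cell classes: a tonic regular class (cholinergic-like), a
# fast irregular class and a slow irregular class (the two PV-like
# populations). Features: rate, log ISI percentiles, CV of ISIs, CV2
# statistics; homogeneity: Spearman correlations between ISI histograms of
# within-class pairs, compared across classes.

library(pvscgn)
dir.create("results", showWarnings = FALSE)
set.seed(1004)

gamma_train <- function(rate, shape, dur = 300) {
  # gamma-renewal train: shape > 1 regular, shape = 1 Poisson
  isi <- rgamma(ceiling(rate * dur * 1.5) + 10, shape, rate = shape * rate)
  t <- cumsum(isi); t <- t[t < dur]
  spike_train(t, epoch = c(0, dur), state = "activation")
}

classes <- list(
  tonic_regular = function() gamma_train(5, shape = 8),
  fast_irregular = function() gamma_train(14, shape = 1),
  slow_irregular = function() gamma_train(3.7, shape = 1))

feats <- list(); hists <- list()
for (cl in names(classes)) {
  for (i in 1:12) {
    st <- classes[[cl]]()
    feats[[length(feats) + 1]] <- cbind(class = cl, neuron = i,
                                        feature_record(st))
    hists[[paste(cl, i)]] <- isi_histogram(st)
  }
}
feats <- do.call(rbind, feats)
write.csv(feats, "results/spike_features.csv", row.names = FALSE)

med_rate <- tapply(feats$rate, feats$class, median)
cat(sprintf("Median rates: fast %.1f vs slow %.2f spikes/s (Mann-Whitney p = %.2g).\n",
            med_rate[["fast_irregular"]], med_rate[["slow_irregular"]],
            mann_whitney(feats$rate[feats$class == "fast_irregular"],
                         feats$rate[feats$class == "slow_irregular"])$p_value))

pair_rho <- function(cl) {
  ids <- grep(paste0("^", cl, " "), names(hists), value = TRUE)
  pairs <- combn(ids, 2)
  vapply(seq_len(ncol(pairs)), function(j) {
    isi_pair_correlation(hists[[pairs[1, j]]], hists[[pairs[2, j]]])
  }, numeric(1))
}
rho <- lapply(names(classes), pair_rho)
names(rho) <- names(classes)
hom <- kruskal_wallis_dunn(rho)
write.csv(hom$pairwise, "results/isi_homogeneity.csv", row.names = FALSE)
cat(sprintf("ISI-histogram pair correlations (median): %s.\n",
            paste(sprintf("%s %.2f", names(rho), vapply(rho, median, 1)),
                  collapse = ", ")))
cat(sprintf("Homogeneity differs across classes: KW p = %.2g.\n", hom$p_value))
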