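#!/usr/bin/env Rscript
# Build the synthetic anatomical census: 13 coronal plane contours and two
# interneuron populations counted inside them. One population ("ScgnNeg")
# is spatially unbiased; the other ("ScgnPos") drifts from lateral in
# rostral planes to medial in caudal planes, the pattern under study.
# Writes the census tables consumed by 02/03.

library(pvscgn)

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
set.seed(1001)

contours <- make_contours(13, seed = 1001)
ml_gradient <- seq(0.35, -0.35, length.out = 13)  # rostral lateral -> caudal medial

vert_rows <- list(); neuron_rows <- list()
for (p in seq_along(contours)) {
  ct <- contours[[p]]
  vert_rows[[p]] <- data.frame(plane_id = p, order = seq_len(nrow(ct$vertices)),
                               x_um = ct$vertices[, 1], y_um = ct$vertices[, 2])
  neg <- sample_biased_neurons(ct, 120, ml_bias = 0, dv_bias = 0.05)
  pos_n <- round(40 * (0.5 + (p / 13)^2 * 2.5))   # density rises caudally
  pos <- sample_biased_neurons(ct, pos_n, ml_bias = ml_gradient[p], dv_bias = 0)
  neuron_rows[[p]] <- rbind(
    data.frame(plane_id = p, x_um = neg$x, y_um = neg$y, PV = 1, Scgn = 0),
    data.frame(plane_id = p, x_um = pos$x, y_um = pos$y, PV = 1, Scgn = 1))
}
verts <- do.call(rbind, vert_rows)
neurons <- do.call(rbind, neuron_rows)
neurons$id <- seq_len(nrow(neurons))

write.table(verts, "results/data/contours.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
write.table(neurons, "results/data/neurons.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

cat(sprintf("Simulated %d planes; %d PV+/Scgn- and %d PV+/Scgn+ neurons.\n",
            length(contours), sum(neurons$Scgn == 0), sum(neurons$Scgn == 1)))
cat(sprintf("Caudal-most plane has %.1fx the PV+/Scgn+ count of the rostral-most.\n",
            sum(neurons$Scgn == 1 & neurons$plane_id == 13) /
              sum(neurons$Scgn == 1 & neurons$plane_id == 1)))
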