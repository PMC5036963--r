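Package: pvscgn
Title: Quantitative Analysis of Striatal PV+/Scgn Interneuron Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical and signal-processing pipeline for characterizing
    subpopulations of striatal parvalbumin-expressing (PV+) interneurons split
    by secretagogin (Scgn) co-expression. Implements stereological counting
    arithmetic (optical disector, Cavalieri volume estimation, Gundersen
    coefficient of error), contour-normalized spatial-bias statistics for
    neuron distributions across coronal planes, interspike-interval and CV2
    spike-train features, spike-field phase locking across an exponential
    Butterworth filterbank with circular statistics and empirical-CDF phase
    correction, normalized-time firing histograms aligned to slow-oscillation
    peaks in the inverted local field potential, and Ward hierarchical
    clustering with permutation-surrogate selection of the number of
    significant clusters. Ground-truth synthetic-data generators for every
    input allow the whole pipeline to be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
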