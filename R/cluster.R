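#' Electrophysiological parameter sets for clustering
#'
#' Names of the feature columns used for cluster inference in each brain
#' state. The SWA set has 7 parameters (three regularity measures, the
#' normalized iLFP-peak median firing time, and the ECoG slow, spindle and
#' gamma vector lengths); a 6-parameter variant without `cv_isi` is
#' provided as a preset. The activation set has 6 regularity/rate
#' parameters.
#'
#' @param state `"SWA"`, `"SWA6"` or `"activation"`.
#' @return character vector of column names.
#' @export
cluster_parameters <- function(state = c("SWA", "SWA6", "activation")) {
  switch(match.arg(state),
         SWA = c("log_isi_p10", "cv_isi", "cv2_ratio", "ilfp_peak_median",
                 "vec_slow", "vec_spindle", "vec_gamma"),
         SWA6 = c("log_isi_p10", "cv2_ratio", "ilfp_peak_median",
                  "vec_slow", "vec_spindle", "vec_gamma"),
         activation = c("log_isi_p10", "log_isi_p50", "log_isi_p85",
                        "rate", "cv2_ratio", "cv2_mean"))
}

prepare_features <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("feature matrix must be numeric")
  if (anyNA(x)) stop("feature matrix must have no missing values")
  if (nrow(x) < 2L) stop("need at least 2 rows")
  if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0)) stop("constant column after standardization")
    x <- scale(x)
  }
  x
}

#' Ward linkage on squared Euclidean distances
#'
#' Agglomerative clustering minimizing the increase in within-cluster
#' variance at each merge (Ward's method on squared Euclidean distances,
#' `hclust(method = "ward.D")` on `dist()^2`). Columns are z-scored first
#' by default so that mixed-unit features contribute comparably; raw-scale
#' linkage is available behind the flag.
#'
#' @param x numeric matrix or data frame (rows = neurons).
#' @param standardize z-score columns before computing distances.
#' @return an `hclust` object; merge heights are nondecreasing.
#' @export
ward_linkage <- function(x, standardize = TRUE) {
  x <- prepare_features(x, standardize)
  stats::hclust(stats::dist(x)^2, method = "ward.D")
}

# successive differences of the (nondecreasing) Ward merge heights
linkage_gaps <- function(hc) diff(hc$height)

#' Significant cluster number by surrogate resampling of linkage gaps
#'
#' Ward linkage heights are the successive within-cluster distances of the
#' agglomeration; a large difference (gap) between successive heights marks
#' the scale at which genuinely separate clusters are being forced
#' together (Thorndike's criterion). The null distribution of such gaps is
#' obtained from surrogate data sets in which every feature column is
#' independently permuted across rows, destroying between-column structure
#' while keeping every marginal. Each observed gap receives the p-value
#' `(1 + # surrogates with max gap >= observed) / (n_surrogates + 1)` under
#' the default `"max"` null (the distribution of the largest surrogate
#' gap), which controls the family-wise error over the whole gap sequence;
#' `"rank"` compares the k-th largest observed gap to the null of the k-th
#' largest surrogate gap and is anticonservative across the sequence. The
#' gap with the smallest p-value below `alpha` (ties broken toward the
#' larger gap) sets the threshold at the midpoint of its two heights; when
#' no gap is significant the result is zero significant clusters.
#'
#' @param x numeric feature matrix (rows = neurons, >= 4).
#' @param n_surrogates number of column-permutation surrogates (>= 100;
#'   10000 in the full analysis).
#' @param alpha significance level for gap selection.
#' @param seed optional RNG seed for the surrogates.
#' @param standardize z-score columns (applied identically to surrogates).
#' @param null_type `"max"` (default) or `"rank"`.
#' @return object of class `cluster_result`: `hclust`, `heights`, `gaps`,
#'   `gap_p`, `threshold`, `n_clusters`, `labels` (NULL when
#'   `n_clusters == 0`).
#' @export
thorndike_resample <- function(x, n_surrogates = 10000L, alpha = 0.05,
                               seed = NULL, standardize = TRUE,
                               null_type = c("max", "rank")) {
  null_type <- match.arg(null_type)
  if (n_surrogates < 100L) stop("need >= 100 surrogates for stable p-values")
  x <- as.matrix(x)
  if (nrow(x) < 4L) stop("need at least 4 rows")
  if (!is.null(seed)) set.seed(seed)
  hc <- ward_linkage(x, standardize)
  g <- linkage_gaps(hc)
  k <- length(g)
  surr_gaps <- matrix(NA_real_, n_surrogates, k)
  for (s in seq_len(n_surrogates)) {
    xs <- apply(x, 2L, sample)
    surr_gaps[s, ] <- linkage_gaps(ward_linkage(xs, standardize))
  }
  if (null_type == "max") {
    null_max <- apply(surr_gaps, 1L, max)
    gap_p <- vapply(g, function(gi) (1 + sum(null_max >= gi)) /
                      (n_surrogates + 1), numeric(1))
  } else {
    ord_null <- apply(surr_gaps, 1L, sort, decreasing = TRUE)  # k x S
    rk <- rank(-g, ties.method = "first")
    gap_p <- vapply(seq_len(k), function(j) {
      (1 + sum(ord_null[rk[j], ] >= g[j])) / (n_surrogates + 1)
    }, numeric(1))
  }
  sig <- which(gap_p < alpha)
  if (!length(sig)) {
    res <- list(hclust = hc, heights = hc$height, gaps = g, gap_p = gap_p,
                threshold = NA_real_, n_clusters = 0L, labels = NULL,
                alpha = alpha, null_type = null_type)
  } else {
    best <- sig[order(gap_p[sig], -g[sig])][1L]
    threshold <- (hc$height[best] + hc$height[best + 1L]) / 2
    labels <- stats::cutree(hc, h = threshold)
    res <- list(hclust = hc, heights = hc$height, gaps = g, gap_p = gap_p,
                threshold = threshold, n_clusters = length(unique(labels)),
                labels = labels, alpha = alpha, null_type = null_type)
  }
  structure(res, class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d significant clusters (alpha = %g, %s null)\n",
              x$n_clusters, x$alpha, x$null_type))
  if (x$n_clusters > 0L) {
    cat("  threshold =", format(x$threshold),
        " min gap p =", format.pval(min(x$gap_p)), "\n")
  }
  invisible(x)
}

#' Cluster composition by withheld molecular identity
#'
#' Cross-tabulates cluster labels against the molecular identities that
#' were withheld from clustering, and reports the majority identity and
#' its fraction for each cluster.
#'
#' @param labels integer cluster labels.
#' @param identities character identities, aligned with `labels`.
#' @return list with `table` (cluster x identity contingency) and
#'   `majority` (data frame: cluster, identity, fraction, n).
#' @export
cluster_composition <- function(labels, identities) {
  if (length(labels) != length(identities)) stop("length mismatch")
  tab <- table(cluster = labels, identity = identities)
  maj <- do.call(rbind, lapply(rownames(tab), function(cl) {
    row <- tab[cl, ]
    data.frame(cluster = cl, identity = names(row)[which.max(row)],
               fraction = max(row) / sum(row), n = sum(row),
               stringsAsFactors = FALSE)
  }))
  list(table = tab, majority = maj)
}
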