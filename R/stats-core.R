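#' Nonparametric test result container
#'
#' Light-weight container used by every statistical routine in the package.
#' Holds the test statistic, the two-sided p-value, the per-group sample
#' sizes and the name of the method, plus optional extras (odds ratio,
#' pairwise tables, degeneracy flags).
#'
#' @param statistic test statistic (U, V, H, odds ratio, ...).
#' @param p_value two-sided p-value in \[0, 1\].
#' @param n_per_group integer vector of group sizes (all >= 1).
#' @param method character name of the test.
#' @param ... further named fields stored alongside.
#' @return An object of class `pv_test`.
#' @export
test_result <- function(statistic, p_value, n_per_group, method, ...) {
  stopifnot(is.numeric(p_value), length(p_value) == 1L)
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    stop("p_value must lie in [0, 1]")
  }
  if (any(n_per_group < 1L)) stop("all group sizes must be >= 1")
  structure(
    c(list(statistic = unname(statistic), p_value = unname(p_value),
           n_per_group = as.integer(n_per_group), method = method),
      list(...)),
    class = "pv_test")
}

#' @export
print.pv_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  statistic =", format(x$statistic), "  p =", format.pval(x$p_value),
      "  n =", paste(x$n_per_group, collapse = "/"), "\n")
  if (isTRUE(x$degenerate)) cat("  (degenerate input)\n")
  invisible(x)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent samples. The exact null
#' distribution is enumerated when both groups have at most `exact_max`
#' observations and there are no ties; otherwise the normal approximation
#' with tie correction is used.
#'
#' @param x,y numeric vectors, each with at least one value.
#' @param exact_max largest per-group n for which the exact path is taken.
#' @return A [test_result()] with the U statistic.
#' @export
mann_whitney <- function(x, y, exact_max = 8L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must contain at least one value")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- length(x) <= exact_max && length(y) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = !use_exact))
  test_result(statistic = wt$statistic, p_value = wt$p.value,
              n_per_group = c(length(x), length(y)),
              method = "Mann-Whitney U", exact = use_exact)
}

#' Wilcoxon signed-rank test against zero median
#'
#' Two-sided one-sample test of median 0. Exact zeros are dropped before
#' ranking (Wilcoxon's convention); if nothing remains the result is flagged
#' degenerate with p = 1.
#'
#' @param values numeric vector.
#' @return A [test_result()]; `$degenerate` is `TRUE` when all inputs are 0.
#' @export
wilcoxon_signed_vs_zero <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("empty input")
  if (anyNA(values)) stop("missing values are not allowed")
  nonzero <- values[values != 0]
  if (!length(nonzero)) {
    return(test_result(statistic = 0, p_value = 1,
                       n_per_group = length(values),
                       method = "Wilcoxon signed-rank vs 0",
                       degenerate = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(nonzero, mu = 0))
  test_result(statistic = wt$statistic, p_value = wt$p.value,
              n_per_group = length(nonzero),
              method = "Wilcoxon signed-rank vs 0", degenerate = FALSE)
}

#' Kruskal-Wallis ANOVA on ranks with Dunn's post-hoc test
#'
#' Omnibus rank test over k groups followed by Dunn's pairwise z tests with
#' tie correction. Pairwise p-values are reported unadjusted and
#' Benjamini-Hochberg adjusted; significance statements in this package use
#' the unadjusted values.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return A [test_result()] with `$pairwise`, a data frame of Dunn z and p.
#' @export
kruskal_wallis_dunn <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need a list of >= 2 groups")
  if (any(!vapply(groups, length, 1L) >= 2L)) stop("every group needs n >= 2")
  groups <- lapply(groups, as.numeric)
  if (anyNA(unlist(groups))) stop("missing values are not allowed")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  kw <- stats::kruskal.test(groups)

  values <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, 1L))
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)[names(groups)]
  n <- vapply(groups, length, 1L)
  tie_tab <- table(values)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))

  pairs <- utils::combn(names(groups), 2L)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[a]] + 1 / n[[b]]))
    z[j] <- (rbar[[a]] - rbar[[b]]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  pw <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                   z = z, p = p, p_adj = stats::p.adjust(p, method = "BH"),
                   stringsAsFactors = FALSE)
  test_result(statistic = kw$statistic, p_value = kw$p.value,
              n_per_group = n, method = "Kruskal-Wallis + Dunn",
              pairwise = pw)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided exact test using the hypergeometric point-probability rule.
#' The odds ratio is the conditional maximum-likelihood estimate; with a
#' zero cell it may be 0 or Inf, which is flagged rather than an error.
#'
#' @param tab 2x2 matrix of non-negative integer counts, or four counts
#'   `c(a, b, c, d)` filling the table by row.
#' @return A [test_result()] with the odds ratio as statistic.
#' @export
fisher_exact <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2L, 2L, byrow = TRUE)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(tab != round(tab))) stop("counts must be integers")
  if (sum(tab) <= 0) stop("total count must be positive")
  ft <- stats::fisher.test(tab)
  or <- unname(ft$estimate)
  test_result(statistic = or, p_value = ft$p.value,
              n_per_group = rowSums(tab), method = "Fisher exact",
              odds_ratio = or, or_degenerate = !is.finite(or) || or == 0)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment with significance flags at level `alpha`. Flags
#' are monotone in the raw p-values: a p-value is never flagged while a
#' smaller one is not.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return list with `p_adjusted` and logical `significant`.
#' @export
fdr_adjust <- function(p_values, alpha = 0.05) {
  p_values <- as.numeric(p_values)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, significant = adj <= alpha, alpha = alpha)
}

#' Spearman rank correlation
#'
#' Rank correlation with average-rank tie handling. A constant input vector
#' makes the coefficient undefined; `NA` is returned with a warning rather
#' than an error so that callers screening many pairs can drop such cases.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\], or `NA` for constant input.
#' @export
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("constant input: Spearman rho undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Serialize test results to a flat JSON report
#'
#' @param results named list of [test_result()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_test_report <- function(results, path) {
  flat <- lapply(results, function(r) {
    list(test = r$method, statistic = r$statistic, p = r$p_value,
         n = r$n_per_group,
         adjustment = if (!is.null(r$adjustment)) r$adjustment else "none")
  })
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
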