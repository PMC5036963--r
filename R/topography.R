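#' Coronal-plane contour
#'
#' A closed, simple polygon delineating the striatum in one coronal plane,
#' with orientation metadata stating which x direction is lateral and which
#' y direction is dorsal. Coordinates are in um. Hemispheres are assumed to
#' be pre-reflected so that a single lateral direction applies.
#'
#' @param vertices two-column matrix of (x, y) vertices in order; the
#'   polygon is closed implicitly (last vertex joins the first).
#' @param plane_id identifier of the plane.
#' @param bregma_mm rostro-caudal position relative to Bregma, mm.
#' @param lateral_dir +1 if +x is lateral, -1 if -x is lateral.
#' @param dorsal_dir +1 if +y is dorsal, -1 if -y is dorsal.
#' @param check_simple verify that the polygon does not self-intersect.
#' @return object of class `plane_contour`.
#' @export
plane_contour <- function(vertices, plane_id = NA, bregma_mm = NA,
                          lateral_dir = 1L, dorsal_dir = 1L,
                          check_simple = TRUE) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L) {
    stop("vertices must be an n x 2 matrix with n >= 3")
  }
  if (anyNA(vertices)) stop("vertices must be finite")
  if (!lateral_dir %in% c(-1L, 1L) || !dorsal_dir %in% c(-1L, 1L)) {
    stop("direction metadata must be +1 or -1")
  }
  if (check_simple && !is_simple_polygon(vertices)) {
    stop("polygon is self-intersecting")
  }
  structure(list(vertices = unname(vertices), plane_id = plane_id,
                 bregma_mm = bregma_mm, lateral_dir = as.integer(lateral_dir),
                 dorsal_dir = as.integer(dorsal_dir)),
            class = "plane_contour")
}

# brute-force O(m^2) segment-intersection check; contours are small
is_simple_polygon <- function(v) {
  m <- nrow(v)
  seg <- cbind(v, v[c(2:m, 1L), ])
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      # skip adjacent segments (share a vertex)
      if (j == i + 1L || (i == 1L && j == m)) next
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross2(p[1], p[2], p[3], p[4], q[1], q[2])
      d2 <- cross2(p[1], p[2], p[3], p[4], q[3], q[4])
      d3 <- cross2(q[1], q[2], q[3], q[4], p[1], p[2])
      d4 <- cross2(q[1], q[2], q[3], q[4], p[3], p[4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(FALSE)
    }
  }
  TRUE
}

# crossings of the horizontal (axis = "x": vary x at fixed y) or vertical
# line through (x0, y0) with the closed polygon; half-open vertex rule so
# each crossing is counted exactly once
axis_crossings <- function(contour, x0, y0, axis = c("x", "y")) {
  axis <- match.arg(axis)
  v <- contour$vertices
  m <- nrow(v)
  a <- v[, if (axis == "x") 2L else 1L]          # coordinate tested against the line
  b <- v[, if (axis == "x") 1L else 2L]          # coordinate of the crossing
  lvl <- if (axis == "x") y0 else x0
  nxt <- c(2:m, 1L)
  hit <- (a > lvl) != (a[nxt] > lvl)
  i <- which(hit)
  if (!length(i)) return(numeric(0))
  j <- nxt[i]
  sort(b[i] + (lvl - a[i]) * (b[j] - b[i]) / (a[j] - a[i]))
}

#' Test whether points lie strictly inside a contour
#'
#' Even-odd ray casting. Points within `tol` of the boundary are reported
#' as not inside (boundary points are rejected throughout the package).
#'
#' @param contour a [plane_contour()].
#' @param x,y point coordinates (vectorized).
#' @param tol boundary tolerance in contour units.
#' @return logical vector.
#' @export
point_in_contour <- function(contour, x, y, tol = 1e-9) {
  vapply(seq_along(x), function(k) {
    cr <- axis_crossings(contour, x[k], y[k], "x")
    if (any(abs(cr - x[k]) <= tol)) return(FALSE)
    sum(cr < x[k]) %% 2L == 1L
  }, logical(1))
}

#' Contour-normalized position of a neuron
#'
#' Horizontal and vertical rays are cast from the neuron to the contour;
#' the first crossing on each side defines the medial/lateral (or
#' ventral/dorsal) border for that neuron. Each axis value is the position
#' within that chord mapped linearly to \[-1, 1\]: 0 means equidistant from
#' the two borders, +1 on the lateral (dorsal) border, -1 on the medial
#' (ventral) border, following the contour's direction metadata.
#'
#' @param x,y neuron position in um (vectorized).
#' @param contour a [plane_contour()].
#' @return data frame with columns `ml` and `dv` in (-1, 1).
#' @export
normalize_position <- function(x, y, contour) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  inside <- point_in_contour(contour, x, y)
  if (!all(inside)) {
    stop("neuron(s) outside (or on) the contour: ",
         paste(which(!inside), collapse = ", "))
  }
  ml <- dv <- numeric(length(x))
  for (k in seq_along(x)) {
    cx <- axis_crossings(contour, x[k], y[k], "x")
    lo <- cx[cx < x[k]]; hi <- cx[cx > x[k]]
    if (!length(lo) || !length(hi)) stop("degenerate horizontal ray at point ", k)
    x_neg <- max(lo); x_pos <- min(hi)             # first crossings each way
    mlk <- 2 * (x[k] - x_neg) / (x_pos - x_neg) - 1
    ml[k] <- mlk * contour$lateral_dir

    cy <- axis_crossings(contour, x[k], y[k], "y")
    lo <- cy[cy < y[k]]; hi <- cy[cy > y[k]]
    if (!length(lo) || !length(hi)) stop("degenerate vertical ray at point ", k)
    y_neg <- max(lo); y_pos <- min(hi)
    dvk <- 2 * (y[k] - y_neg) / (y_pos - y_neg) - 1
    dv[k] <- dvk * contour$dorsal_dir
  }
  data.frame(ml = ml, dv = dv)
}

#' Map a target normalized coordinate back to plane coordinates
#'
#' Inverse of the per-axis ray parametrization used by
#' [normalize_position()], solved by coordinate-wise fixed-point iteration
#' (the horizontal chord depends on y and vice versa). Used by the
#' synthetic-data generator and by round-trip tests.
#'
#' @param ml,dv target normalized coordinates in (-1, 1).
#' @param contour a [plane_contour()].
#' @param max_iter,tol iteration controls.
#' @return list with `x`, `y` and logical `converged`.
#' @export
invert_normalized_position <- function(ml, dv, contour, max_iter = 60,
                                       tol = 1e-10) {
  v <- contour$vertices
  x <- mean(range(v[, 1])); y <- mean(range(v[, 2]))
  mlr <- ml * contour$lateral_dir      # raw-axis targets
  dvr <- dv * contour$dorsal_dir
  ok <- FALSE
  for (i in seq_len(max_iter)) {
    cx <- axis_crossings(contour, x, y, "x")
    lo <- cx[cx < x]; hi <- cx[cx > x]
    if (!length(lo) || !length(hi)) break
    x_new <- max(lo) + (mlr + 1) / 2 * (min(hi) - max(lo))
    cy <- axis_crossings(contour, x_new, y, "y")
    lo <- cy[cy < y]; hi <- cy[cy > y]
    if (!length(lo) || !length(hi)) break
    y_new <- max(lo) + (dvr + 1) / 2 * (min(hi) - max(lo))
    if (abs(x_new - x) < tol && abs(y_new - y) < tol) {
      x <- x_new; y <- y_new; ok <- TRUE; break
    }
    x <- x_new; y <- y_new
  }
  list(x = x, y = y, converged = ok && all(point_in_contour(contour, x, y)))
}

#' Per-plane spatial-bias test
#'
#' Wilcoxon signed-rank test of whether the normalized positions along one
#' axis differ from 0 (an unbiased distribution). Planes containing 5 or
#' fewer neurons are skipped with an explicit skip record, as positional
#' averages become too variable to be meaningful.
#'
#' @param positions data frame from [normalize_position()], or a numeric
#'   vector of per-neuron axis values.
#' @param axis `"ml"` or `"dv"` (ignored for a numeric vector).
#' @param min_n smallest analyzable count (tests run when n > `min_n`).
#' @return A [test_result()], or a skip record (class `pv_skip`) listing
#'   the reason.
#' @export
plane_bias_test <- function(positions, axis = c("ml", "dv"), min_n = 5L) {
  vals <- if (is.data.frame(positions)) positions[[match.arg(axis)]] else as.numeric(positions)
  if (length(vals) <= min_n) {
    return(structure(list(skipped = TRUE, n = length(vals),
                          reason = sprintf("<= %d neurons in plane", min_n)),
                     class = "pv_skip"))
  }
  wilcoxon_signed_vs_zero(vals)
}

#' Compare the positions of two populations within a plane
#'
#' Mann-Whitney U test on one axis of the normalized positions of two
#' populations counted in the same plane. Either population with 5 or
#' fewer neurons produces a skip record. Across planes, the caller pools
#' the resulting p-values through [fdr_adjust()].
#'
#' @param pop_a,pop_b data frames from [normalize_position()] or numeric
#'   axis values.
#' @param axis `"ml"` or `"dv"`.
#' @param min_n smallest analyzable count per population.
#' @return A [test_result()] or a skip record.
#' @export
compare_populations <- function(pop_a, pop_b, axis = c("ml", "dv"), min_n = 5L) {
  axis <- match.arg(axis)
  a <- if (is.data.frame(pop_a)) pop_a[[axis]] else as.numeric(pop_a)
  b <- if (is.data.frame(pop_b)) pop_b[[axis]] else as.numeric(pop_b)
  if (length(a) <= min_n || length(b) <= min_n) {
    return(structure(list(skipped = TRUE, n = c(length(a), length(b)),
                          reason = sprintf("<= %d neurons in a population", min_n)),
                     class = "pv_skip"))
  }
  mann_whitney(a, b)
}

#' Cross-plane variability of mean positions
#'
#' For each coronal plane s with mean normalized position m_s, the
#' statistic is the average difference to every other plane. The default
#' takes the mean of absolute pairwise differences,
#' `d_s = mean over s' != s of |m_s - m_s'|`; `mode = "abs_mean"` instead
#' takes the absolute value of the mean signed difference. The statistic is
#' sensitive to means that change across planes but stays low for a
#' consistent bias shared by all planes.
#'
#' @param per_plane_means numeric vector of plane means (>= 3 planes).
#' @param mode `"mean_abs"` (default) or `"abs_mean"`.
#' @return numeric vector d, one value per plane.
#' @export
cross_plane_variability <- function(per_plane_means,
                                    mode = c("mean_abs", "abs_mean")) {
  mode <- match.arg(mode)
  m <- as.numeric(per_plane_means)
  if (length(m) < 3L) stop("need >= 3 planes with defined means")
  if (anyNA(m)) stop("plane means must be defined")
  vapply(seq_along(m), function(s) {
    d <- m[s] - m[-s]
    if (mode == "mean_abs") mean(abs(d)) else abs(mean(d))
  }, numeric(1))
}

#' Compare cross-plane variability between groups
#'
#' Computes [cross_plane_variability()] for each group's per-plane means
#' and compares the groups with [kruskal_wallis_dunn()].
#'
#' @param groups named list of per-plane mean vectors, one per group.
#' @param mode passed to [cross_plane_variability()].
#' @return A [test_result()] with `$d`, the per-group variability vectors.
#' @export
compare_cross_plane_variability <- function(groups, mode = "mean_abs") {
  d <- lapply(groups, cross_plane_variability, mode = mode)
  res <- kruskal_wallis_dunn(d)
  res$d <- d
  res
}
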