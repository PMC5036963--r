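# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive results from first principles and never call
# the code paths they verify.

# Brute-force Ward agglomeration: at every step merge the pair of clusters
# whose centroid-based Ward cost (2 * na*nb/(na+nb) * ||mean_a - mean_b||^2,
# the scale hclust ward.D uses on squared Euclidean input) is smallest.
brute_ward_heights <- function(X) {
  X <- as.matrix(X)
  members <- lapply(seq_len(nrow(X)), identity)
  heights <- numeric(0)
  while (length(members) > 1L) {
    best <- c(NA_integer_, NA_integer_); best_cost <- Inf
    for (i in seq_along(members)) {
      for (j in seq_along(members)) {
        if (j <= i) next
        ca <- colMeans(X[members[[i]], , drop = FALSE])
        cb <- colMeans(X[members[[j]], , drop = FALSE])
        na <- length(members[[i]]); nb <- length(members[[j]])
        cost <- 2 * na * nb / (na + nb) * sum((ca - cb)^2)
        if (cost < best_cost) { best_cost <- cost; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_cost)
    members[[best[1]]] <- c(members[[best[1]]], members[[best[2]]])
    members[[best[2]]] <- NULL
  }
  heights
}

# Brute-force contour normalization: scan every polygon edge for strict
# crossings with the horizontal/vertical line through the point, then map
# the point within the nearest bracketing crossings to [-1, 1].
brute_normalize <- function(verts, x0, y0) {
  m <- nrow(verts)
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(m)) {
    p <- verts[i, ]; q <- verts[if (i == m) 1L else i + 1L, ]
    if ((p[2] - y0) * (q[2] - y0) < 0) {
      xs <- c(xs, p[1] + (y0 - p[2]) / (q[2] - p[2]) * (q[1] - p[1]))
    }
    if ((p[1] - x0) * (q[1] - x0) < 0) {
      ys <- c(ys, p[2] + (x0 - p[1]) / (q[1] - p[1]) * (q[2] - p[2]))
    }
  }
  x_med <- max(xs[xs < x0]); x_lat <- min(xs[xs > x0])
  y_ven <- max(ys[ys < y0]); y_dor <- min(ys[ys > y0])
  c(ml = 2 * (x0 - x_med) / (x_lat - x_med) - 1,
    dv = 2 * (y0 - y_ven) / (y_dor - y_ven) - 1)
}

# von Mises sampler (Best & Fisher 1979 rejection scheme)
rvm <- function(n, mu = 0, kappa = 1) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    u <- stats::runif(3 * n)
    u1 <- u[seq_len(n)]; u2 <- u[n + seq_len(n)]; u3 <- u[2 * n + seq_len(n)]
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3 - 0.5)[ok] * acos(f[ok])
    out <- c(out, th)
  }
  Arg(exp(1i * (out[seq_len(n)] + mu)))
}

# analytic probability mass of an Exponential(rate) ISI in [lo, hi]
exp_bin_mass <- function(rate, lo, hi) {
  stats::pexp(hi, rate) - stats::pexp(lo, rate)
}
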