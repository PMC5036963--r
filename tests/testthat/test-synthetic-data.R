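test_that("contour generator produces valid, optionally non-convex polygons", {
  ctrs <- make_contours()
  expect_length(ctrs, 13)
  for (ct in ctrs) expect_s3_class(ct, "plane_contour")

  sym <- make_contours(1)[[1]]
  v <- sym$vertices
  # mirror symmetry about the vertical axis: the reflected vertex set matches
  refl <- cbind(-v[, 1], v[, 2])
  for (i in seq_len(nrow(v))) {
    expect_lt(min(sqrt(rowSums(sweep(refl, 2, v[i, ])^2))), 1e-6)
  }

  notched <- make_contours(1, notch_depth = 0.5)[[1]]
  # non-convex: the medial dent makes some vertical rays cross > 2 times
  cross_counts <- vapply(seq(-1700, -400, by = 25), function(x) {
    length(pvscgn:::axis_crossings(notched, x, 0, "y"))
  }, numeric(1))
  expect_gt(max(cross_counts), 2)

  expect_error(make_contours(1, a_um = -5), "degenerate")
})

test_that("biased neuron sampling hits its target means inside the polygon", {
  ctr <- make_contours(1, seed = 90)[[1]]
  pts <- sample_biased_neurons(ctr, 1000, ml_bias = 0.3, dv_bias = 0, seed = 91)
  expect_true(all(point_in_contour(ctr, pts$x, pts$y)))
  np <- normalize_position(pts$x, pts$y, ctr)
  expect_lt(abs(mean(np$ml) - 0.3), 0.05)
  expect_lt(abs(mean(np$dv)), 0.05)
  expect_error(sample_biased_neurons(ctr, 0), "positive")
})

test_that("field simulation concentrates power at the slow frequency", {
  s <- simulate_field(60, fs = 250, amplitudes = c(slow = 1, spindle = 0,
                                                   gamma = 0, noise = 0),
                      skew = 0, seed = 92)
  sp <- Mod(fft(s$samples))^2
  freqs <- (seq_along(sp) - 1) * s$fs / length(sp)
  peak_f <- freqs[which.max(sp[freqs > 0.1 & freqs < 100])
                  + sum(freqs <= 0.1)]
  expect_lt(abs(peak_f - 1), 0.1)

  # skew makes the harmonic-spanning band's phase samples non-uniform
  sk <- simulate_field(60, fs = 250, amplitudes = c(slow = 1, spindle = 0,
                                                    gamma = 0, noise = 0.05),
                       skew = 6, seed = 93)
  ph <- analytic_phase(sk, 1.0, 2.25)$phase
  expect_gt(circular_stats(ph[seq(1, length(ph), by = 25)])$R, 0.1)

  expect_error(simulate_field(-5, 250), "positive")
  expect_error(simulate_field(10, 100), "exceed 200")
})

test_that("locked-train generator matches its von Mises ground truth", {
  s <- simulate_field(240, fs = 250, amplitudes = c(slow = 1, spindle = 0,
                                                    gamma = 0, noise = 0.05),
                      seed = 94)
  ap <- analytic_phase(s, 0.67, 1.5)

  st0 <- simulate_locked_train(s, rate = 5, kappa = 0, seed = 95)
  expect_lt(circular_stats(spike_phases(st0, ap))$R, 0.1)

  st <- simulate_locked_train(s, band = c(0.67, 1.5), rate = 8, kappa = 2,
                              mu = pi, seed = 96)
  cs <- circular_stats(spike_phases(st, ap))
  expect_lt(abs(cs$R - besselI(2, 1) / besselI(2, 0)), 0.05)
  expect_lt(abs(abs(cs$mean_phase) - pi), 0.15)

  expect_error(simulate_locked_train(s, band = c(10, 200)), "Nyquist")
  expect_error(simulate_locked_train(s, rate = -1), "positive")
})

test_that("generators are deterministic under a fixed seed", {
  a <- simulate_field(10, fs = 250, seed = 97)
  b <- simulate_field(10, fs = 250, seed = 97)
  expect_identical(a$samples, b$samples)

  s <- simulate_field(60, fs = 250, seed = 98)
  t1 <- simulate_locked_train(s, rate = 5, kappa = 1, seed = 99)
  t2 <- simulate_locked_train(s, rate = 5, kappa = 1, seed = 99)
  expect_identical(t1$times, t2$times)

  f1 <- simulate_feature_clusters(seed = 100)
  f2 <- simulate_feature_clusters(seed = 100)
  expect_identical(f1$features, f2$features)

  g1 <- simulate_point_grid(seed = 101)
  g2 <- simulate_point_grid(seed = 101)
  expect_identical(g1$P, g2$P)

  n1 <- simulate_nucleus_stack(2000, 50, seed = 102)
  n2 <- simulate_nucleus_stack(2000, 50, seed = 102)
  expect_identical(n1$depths, n2$depths)

  c1 <- make_contours(3, seed = 103)
  c2 <- make_contours(3, seed = 103)
  expect_identical(c1[[2]]$vertices, c2[[2]]$vertices)
})

test_that("feature-cluster generator controls separation and identity coupling", {
  fc <- simulate_feature_clusters(k = 3, n_per_cluster = 10, separation = 5,
                                  dims = 6, seed = 104)
  ctr <- do.call(rbind, lapply(1:3, function(k) {
    colMeans(fc$features[fc$labels == k, ])
  }))
  d12 <- sqrt(sum((ctr[1, ] - ctr[2, ])^2))
  d13 <- sqrt(sum((ctr[1, ] - ctr[3, ])^2))
  expect_lt(abs(d12 - 5), 1.2)   # sample centroids around the design distance
  expect_lt(abs(d13 - 5), 1.2)

  expect_true(all(fc$identities == paste0("type", fc$labels)))

  half <- simulate_feature_clusters(k = 2, n_per_cluster = 200,
                                    identity_correlation = 0.5, seed = 105)
  agree <- mean(half$identities == paste0("type", half$labels))
  expect_lt(abs(agree - 0.5), 0.1)

  expect_error(simulate_feature_clusters(separation = -1), "non-negative")
})

test_that("peak-timed trains degenerate correctly as sigma shrinks", {
  s <- simulate_field(60, fs = 250, amplitudes = c(slow = 1, spindle = 0,
                                                   gamma = 0, noise = 0.05),
                      seed = 106, channel = "LFP")
  fi <- invert_and_filter(sampled_signal(-s$samples, s$fs, "LFP"))
  pk <- segment_peaks(fi)
  st <- simulate_peak_timed_train(pk, mu_star = 0.2, sigma_star = 1e-4,
                                  spikes_per_peak = 3, seed = 107)
  h <- normalized_histogram(st, pk)
  expect_lte(length(which(h$counts > 0)), 2)
  expect_error(simulate_peak_timed_train(pk[0, ], -0.3, 0.1), "no peaks")
})

test_that("signal and spike files round-trip through the text formats", {
  dir <- tempfile("io")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  s <- simulate_field(5, fs = 250, seed = 108)
  fp <- file.path(dir, "ecog.txt")
  write_signal(s, fp)
  s2 <- read_signal(fp)
  expect_equal(s2$fs, 250)
  expect_equal(s2$samples, s$samples, tolerance = 1e-6)

  st <- spike_train(c(0.5, 1.2, 3.4), epoch = c(0, 5))
  sp <- file.path(dir, "cell.txt")
  writeLines(format(st$times), sp)
  st2 <- read_spike_times(sp, epoch = c(0, 5))
  expect_equal(st2$times, st$times)
})
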